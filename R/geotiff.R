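# Minimal GeoTIFF IO: uncompressed, little-endian, single-band IEEE float,
# with ModelPixelScale/ModelTiepoint georeferencing and the GDAL nodata tag.
# Only the subset of TIFF 6.0 needed for elevation products is supported;
# anything else is rejected with an explicit format error.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               planar = 284L, sample_format = 339L,
               model_pixel_scale = 33550L, model_tiepoint = 33922L,
               geo_keys = 34735L, gdal_nodata = 42113L)

#' Write an elevation grid as GeoTIFF
#'
#' Writes a single-band float32 GeoTIFF (uncompressed, little-endian,
#' one strip) with georeferencing stored as ModelPixelScale + ModelTiepoint
#' and missing cells encoded as the grid's nodata sentinel (also recorded in
#' the GDAL_NODATA tag). Round-trips losslessly through
#' \code{\link{read_elevation_raster}} at float32 precision.
#'
#' @param grid an \code{\link{elevation_grid}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_elevation_raster <- function(grid, path) {
  stopifnot(inherits(grid, "elevation_grid"))
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  nr <- nrow(v); nc <- ncol(v)
  data_bytes <- nr * nc * 4
  if (data_bytes >= 2^31) stop("raster too large for single-strip GeoTIFF writer")

  nodata_ascii <- c(charToRaw(format(grid$nodata, scientific = FALSE)), as.raw(0))
  # GeoKey directory: version 1.1.0; GTModelType=1 (projected), GTRasterType=1
  # (pixel-is-area), citation omitted
  geokeys <- as.integer(c(1, 1, 0, 2,
                          1024, 0, 1, 1,
                          1025, 0, 1, 1))

  entries <- list(
    list(tag = TIFF_TAGS[["width"]], type = 3L, values = nc),
    list(tag = TIFF_TAGS[["length"]], type = 3L, values = nr),
    list(tag = TIFF_TAGS[["bits"]], type = 3L, values = 32L),
    list(tag = TIFF_TAGS[["compression"]], type = 3L, values = 1L),
    list(tag = TIFF_TAGS[["photometric"]], type = 3L, values = 1L),
    list(tag = TIFF_TAGS[["strip_offsets"]], type = 4L, values = 8L),
    list(tag = TIFF_TAGS[["spp"]], type = 3L, values = 1L),
    list(tag = TIFF_TAGS[["rows_per_strip"]], type = 3L, values = min(nr, 65535L)),
    list(tag = TIFF_TAGS[["strip_bytes"]], type = 4L, values = data_bytes),
    list(tag = TIFF_TAGS[["planar"]], type = 3L, values = 1L),
    list(tag = TIFF_TAGS[["sample_format"]], type = 3L, values = 3L),
    list(tag = TIFF_TAGS[["model_pixel_scale"]], type = 12L,
         values = c(grid$cell_x, grid$cell_y, 0)),
    list(tag = TIFF_TAGS[["model_tiepoint"]], type = 12L,
         values = c(0, 0, 0, grid$xmin, grid$ymax, 0)),
    list(tag = TIFF_TAGS[["geo_keys"]], type = 3L, values = geokeys),
    list(tag = TIFF_TAGS[["gdal_nodata"]], type = 2L, values = nodata_ascii)
  )

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  ifd_offset <- 8 + data_bytes + (data_bytes %% 2)  # word-align the IFD
  n_entries <- length(entries)
  ext_offset <- ifd_offset + 2 + 12 * n_entries + 4  # external values follow IFD

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data, row-major, top row first
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  if (data_bytes %% 2) writeBin(raw(1), con)

  writeBin(as.integer(n_entries), con, size = 2, endian = "little")
  ext_queue <- list()
  for (e in entries) {
    count <- length(e$values)
    nbytes <- count * type_size[[as.character(e$type)]]
    writeBin(as.integer(e$tag), con, size = 2, endian = "little")
    writeBin(as.integer(e$type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (nbytes <= 4) {
      # pack inline, left-justified
      val_raw <- .tiff_encode(e$values, e$type)
      writeBin(c(val_raw, raw(4 - nbytes)), con)
    } else {
      writeBin(as.integer(ext_offset), con, size = 4, endian = "little")
      ext_queue[[length(ext_queue) + 1]] <- .tiff_encode(e$values, e$type)
      ext_offset <- ext_offset + nbytes + (nbytes %% 2)
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  for (r in ext_queue) {
    writeBin(r, con)
    if (length(r) %% 2) writeBin(raw(1), con)
  }
  invisible(path)
}

.tiff_encode <- function(values, type) {
  switch(as.character(type),
    `2` = as.raw(values),
    `3` = writeBin(as.integer(values), raw(), size = 2, endian = "little"),
    `4` = writeBin(as.integer(values), raw(), size = 4, endian = "little"),
    `12` = writeBin(as.numeric(values), raw(), size = 8, endian = "little"),
    stop("unsupported TIFF type ", type))
}

#' Read a GeoTIFF elevation raster
#'
#' Reads single-band, uncompressed, little-endian GeoTIFFs with IEEE float or
#' integer samples, as produced by \code{\link{write_elevation_raster}} (and
#' by common geospatial tools when exporting uncompressed float rasters).
#' Multi-band, compressed, tiled or non-georeferenced files raise a format
#' error. Cells equal to the nodata sentinel become \code{NA}.
#'
#' @param path file path.
#' @param nodata nodata sentinel override; default uses the file's GDAL_NODATA
#'   tag, falling back to -9999.
#' @return an \code{\link{elevation_grid}}.
#' @export
read_elevation_raster <- function(path, nodata = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II"))
    stop("not a little-endian TIFF (big-endian and non-TIFF files unsupported): ", path)
  if (readBin(con, "integer", 1, size = 2, endian = "little") != 42L)
    stop("not a TIFF file: ", path)
  ifd_offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, ifd_offset)
  n_entries <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (n_entries <= 0) stop("empty TIFF directory: ", path)

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  tags <- list()
  for (k in seq_len(n_entries)) {
    seek(con, ifd_offset + 2 + (k - 1) * 12)
    tag <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
    type <- readBin(con, "integer", 1, size = 2, endian = "little")
    count <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!as.character(type) %in% names(type_size)) next  # skip exotic types
    nbytes <- count * type_size[[as.character(type)]]
    if (nbytes > 4) {
      off <- readBin(con, "integer", 1, size = 4, endian = "little")
      seek(con, off)
    }
    vals <- switch(as.character(type),
      `1` = as.integer(readBin(con, "raw", count)),
      `2` = readBin(con, "raw", count),
      `3` = readBin(con, "integer", count, size = 2, endian = "little", signed = FALSE),
      `4` = readBin(con, "integer", count, size = 4, endian = "little"),
      `12` = readBin(con, "numeric", count, size = 8, endian = "little"))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v) && is.null(default)) stop("GeoTIFF missing required tag: ", tag)
    if (is.null(v)) default else v
  }
  nc <- need("width"); nr <- need("length")
  if (need("compression", 1L) != 1L) stop("compressed TIFFs are unsupported")
  if (need("spp", 1L) != 1L) stop("multi-band rasters are unsupported (single-band elevation expected)")
  fmt <- need("sample_format", 1L)
  bits <- need("bits", 32L)
  scale <- tags[[as.character(TIFF_TAGS[["model_pixel_scale"]])]]
  tie <- tags[[as.character(TIFF_TAGS[["model_tiepoint"]])]]
  if (is.null(scale) || is.null(tie))
    stop("file is not georeferenced (no ModelPixelScale/ModelTiepoint)")
  offsets <- need("strip_offsets")
  counts <- need("strip_bytes")

  sample_bytes <- bits / 8
  what <- if (fmt == 3L) "numeric" else "integer"
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    n_samp <- counts[s] / sample_bytes
    vals <- c(vals, readBin(con, what, n_samp, size = sample_bytes,
                            endian = "little"))
  }
  if (length(vals) != nr * nc) stop("pixel data truncated")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)

  if (is.null(nodata)) {
    nd_raw <- tags[[as.character(TIFF_TAGS[["gdal_nodata"]])]]
    nodata <- if (!is.null(nd_raw))
      suppressWarnings(as.numeric(rawToChar(nd_raw[nd_raw != as.raw(0)])))
    else -9999
    if (is.na(nodata)) nodata <- -9999
  }
  # float32 storage perturbs the sentinel's least bits; compare at float32 tol
  m[abs(m - nodata) <= 1e-6 * max(1, abs(nodata))] <- NA_real_
  # tiepoint maps raster (i=0, j=0) corner to model (x, y)
  xmin <- tie[4] - tie[1] * scale[1]
  ymax <- tie[5] + tie[2] * scale[2]
  elevation_grid(m, xmin = xmin, ymax = ymax,
                 cell_x = scale[1], cell_y = scale[2], nodata = nodata)
}
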
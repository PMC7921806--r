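#' Field layout: plot polygons plus experimental-design attributes
#'
#' @param plots data.frame with one row per plot: \code{plot_id},
#'   \code{genotype}, \code{rep}, \code{block} and the rectangle bounds
#'   \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax} (meters).
#' @param polygons named list of vertex matrices, one per plot, names matching
#'   \code{plot_id}.
#' @param geometry named list of the trial's bed geometry (bed_width_m,
#'   inter_row_m, inter_bed_m, plot_length_m).
#' @return object of class \code{field_layout}.
#' @export
field_layout <- function(plots, polygons, geometry = list()) {
  stopifnot(is.data.frame(plots),
            all(c("plot_id", "genotype", "rep", "block") %in% names(plots)),
            length(polygons) == nrow(plots))
  structure(list(plots = plots, polygons = polygons, geometry = geometry),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  p <- x$plots
  cat(sprintf("<field_layout> %d plots, %d genotypes, %d reps, %d blocks/rep\n",
              nrow(p), length(unique(p$genotype)), length(unique(p$rep)),
              length(unique(p$block[p$rep == p$rep[1]]))))
  invisible(x)
}

#' Simulate a resolvable alpha-lattice field layout
#'
#' Lays out a two-bed-plot wheat trial: genotypes are assigned to incomplete
#' blocks nested within complete replicates (each genotype exactly once per
#' replicate) using a cyclic generating permutation per replicate, and plots
#' are tiled on a rectangular grid of beds and alleys. Plot width spans two
#' beds plus the inter-bed furrow.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{field_layout}}; plot polygons never overlap, and each
#'   genotype appears exactly \code{n_replicates} times.
#' @export
simulate_layout <- function(config) {
  cf <- config
  v <- cf$n_genotypes; r <- cf$n_replicates; s <- cf$n_blocks_per_rep
  if (v %% s != 0)
    stop("n_genotypes (", v, ") must divide into n_blocks_per_rep (", s,
         ") equal-size blocks; pad the genotype list or change the block count")
  k <- v %/% s  # plots per block

  plot_w <- 2 * cf$bed_width_m + cf$inter_bed_m
  pitch_x <- plot_w + cf$alley_m
  pitch_y <- cf$plot_length_m + cf$alley_m

  # blocks laid out in a grid roughly square in plot counts
  n_block_cols <- max(1L, as.integer(ceiling(sqrt(r * s * k * pitch_y /
                                                    (k * pitch_x) ))))
  n_block_cols <- min(n_block_cols, s)
  n_block_rows_per_rep <- as.integer(ceiling(s / n_block_cols))

  asg <- with_seed(derive_seed(cf$seed, "layout"), {
    cand <- which(vapply(seq_len(max(v - 1, 1)), function(x) gcd(x, v) == 1L,
                         logical(1)))
    rows <- lapply(seq_len(r), function(j) {
      # cyclic generating permutation: position = (a*g + b) mod v, a coprime to v
      if (j == 1) { a <- 1L; b <- 0L } else {
        a <- cand[sample.int(length(cand), 1)]
        b <- sample.int(v, 1) - 1L
      }
      pos <- ((a * (seq_len(v) - 1L) + b) %% v)
      data.frame(genotype = sprintf("G%03d", seq_len(v)),
                 rep = j, block = pos %/% k + 1L, unit = pos %% k + 1L)
    })
    do.call(rbind, rows)
  })

  # map (rep, block, unit) to field position: reps stacked north to south,
  # blocks wrap into n_block_cols columns, plots run west to east in a block
  margin <- cf$margin_m
  asg$block_row <- (asg$block - 1L) %/% n_block_cols +
    (asg$rep - 1L) * n_block_rows_per_rep
  asg$block_col <- (asg$block - 1L) %% n_block_cols
  asg$col <- asg$block_col * k + (asg$unit - 1L)
  asg$xmin <- margin + asg$col * pitch_x
  asg$xmax <- asg$xmin + plot_w
  ymax_field <- cf$extent_m[2]
  asg$ymax <- ymax_field - margin - asg$block_row * pitch_y
  asg$ymin <- asg$ymax - cf$plot_length_m

  ext <- cf$extent_m
  if (any(asg$xmax > ext[1] - margin + 1e-9) || any(asg$ymin < margin - 1e-9))
    stop("layout does not fit the extent: need at least ",
         sprintf("%.1f x %.1f m", max(asg$xmax) + margin,
                 ymax_field - min(asg$ymin) + margin))

  asg <- asg[order(asg$rep, asg$block, asg$unit), ]
  asg$plot_id <- sprintf("P%04d", seq_len(nrow(asg)))
  plots <- asg[, c("plot_id", "genotype", "rep", "block",
                   "xmin", "xmax", "ymin", "ymax")]
  rownames(plots) <- NULL
  polygons <- lapply(seq_len(nrow(plots)), function(i)
    rect_polygon(plots$xmin[i], plots$ymin[i], plots$xmax[i], plots$ymax[i]))
  names(polygons) <- plots$plot_id
  field_layout(plots, polygons,
               geometry = list(bed_width_m = cf$bed_width_m,
                               inter_row_m = cf$inter_row_m,
                               inter_bed_m = cf$inter_bed_m,
                               plot_length_m = cf$plot_length_m,
                               plot_width_m = plot_w))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Write / read a field layout as GeoJSON
#'
#' Plots become a FeatureCollection of Polygon features with properties
#' \code{plot_id}, \code{genotype}, \code{rep}, \code{block}.
#'
#' @param layout a \code{field_layout}.
#' @param path file path.
#' @return \code{path} (write) or a \code{field_layout} (read).
#' @export
write_layout_geojson <- function(layout, path) {
  feats <- lapply(seq_len(nrow(layout$plots)), function(i) {
    p <- layout$plots[i, ]
    poly <- layout$polygons[[p$plot_id]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, genotype = p$genotype,
                           rep = p$rep, block = p$block),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(k)
                           c(ring[k, 1], ring[k, 2])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a GeoJSON FeatureCollection")
  rows <- list(); polygons <- list()
  for (f in fc$features) {
    pr <- f$properties
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    bb <- polygon_bbox(m)
    rows[[length(rows) + 1]] <- data.frame(
      plot_id = pr$plot_id, genotype = pr$genotype,
      rep = as.integer(pr$rep), block = as.integer(pr$block),
      xmin = bb["xmin"], xmax = bb["xmax"], ymin = bb["ymin"], ymax = bb["ymax"])
    polygons[[pr$plot_id]] <- m
  }
  plots <- do.call(rbind, rows)
  rownames(plots) <- NULL
  field_layout(plots, polygons)
}
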
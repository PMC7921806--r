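#' Trial simulation configuration
#'
#' Bundles every knob of the synthetic wheat-trial generator. Defaults emulate
#' a two-bed alpha-lattice spring-wheat yield trial flown with a UAV at fine
#' ground sampling distance: 150 genotypes in 2 replicates of 30 incomplete
#' blocks, 0.8 m beds with 0.24 m inter-row and 0.36 m inter-bed spacing, 4 m
#' plots, 1.7 cm pixels, canopy heights measured at four growth stages
#' (E+40 = 40 days after emergence, B = booting, A+7 = 7 days after anthesis,
#' M = physiological maturity) and ground truth taken as the mean of 4 culms
#' per plot.
#'
#' @param seed root integer seed; every simulator output is a pure function
#'   of the config including this seed.
#' @param n_genotypes,n_replicates,n_blocks_per_rep design size; genotypes
#'   must split into equal blocks of size n_genotypes / n_blocks_per_rep.
#' @param plot_length_m,bed_width_m,inter_row_m,inter_bed_m plot geometry
#'   (meters); plot width is 2 * bed_width_m + inter_bed_m.
#' @param alley_m gap between neighboring plots (meters).
#' @param cell_size_m raster resolution in meters/pixel (GSD).
#' @param extent_m field extent c(width, height) in meters; NULL sizes the
#'   extent to fit the layout plus margins.
#' @param margin_m bare margin around the trial where ground targets sit.
#' @param base_elevation_m mean terrain elevation above sea level.
#' @param terrain_relief_cm peak-to-peak amplitude of the low-frequency
#'   terrain undulation.
#' @param stage_mean_cm named vector of canopy-top means per growth stage.
#' @param genotype_sd_cm,replicate_sd_cm,block_sd_cm SDs of the additive
#'   genotype / replicate / block effects (cm).
#' @param culm_sd_cm within-plot culm-height SD (cm); also scales the
#'   canopy-surface texture depth.
#' @param measurement_sd_cm ruler measurement error SD (cm).
#' @param surface_noise_sd_cm photogrammetric elevation noise SD (cm).
#' @param n_culms culms averaged per ground measurement.
#' @param wind_smear_px lateral blur radius (pixels) applied to the canopy,
#'   mimicking plant movement between overlapping images; 0 disables.
#' @param n_gcp,n_checkpoints ground targets used in bundle adjustment vs
#'   held out for accuracy checking.
#' @param target_side_m side of the square target pillars (meters).
#' @param georef_shift_cm,georef_noise_sd_cm systematic and random horizontal
#'   georeferencing error injected into measured target coordinates.
#' @return object of class \code{simulation_config} (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_genotypes = 150L,
                              n_replicates = 2L,
                              n_blocks_per_rep = 30L,
                              plot_length_m = 4,
                              bed_width_m = 0.8,
                              inter_row_m = 0.24,
                              inter_bed_m = 0.36,
                              alley_m = 0.6,
                              cell_size_m = 0.017,
                              extent_m = NULL,
                              margin_m = 3,
                              base_elevation_m = 38,
                              terrain_relief_cm = 10,
                              stage_mean_cm = c("E+40" = 55, "B" = 85,
                                                "A+7" = 95, "M" = 90),
                              genotype_sd_cm = 5,
                              replicate_sd_cm = 1,
                              block_sd_cm = 2,
                              culm_sd_cm = 4,
                              measurement_sd_cm = 1,
                              surface_noise_sd_cm = 1,
                              n_culms = 4L,
                              wind_smear_px = 0L,
                              n_gcp = 9L,
                              n_checkpoints = 11L,
                              target_side_m = 0.4,
                              georef_shift_cm = 0,
                              georef_noise_sd_cm = 1) {
  cf <- list(seed = as.integer(seed), n_genotypes = as.integer(n_genotypes),
             n_replicates = as.integer(n_replicates),
             n_blocks_per_rep = as.integer(n_blocks_per_rep),
             plot_length_m = plot_length_m, bed_width_m = bed_width_m,
             inter_row_m = inter_row_m, inter_bed_m = inter_bed_m,
             alley_m = alley_m, cell_size_m = cell_size_m,
             extent_m = extent_m, margin_m = margin_m,
             base_elevation_m = base_elevation_m,
             terrain_relief_cm = terrain_relief_cm,
             stage_mean_cm = stage_mean_cm,
             genotype_sd_cm = genotype_sd_cm, replicate_sd_cm = replicate_sd_cm,
             block_sd_cm = block_sd_cm, culm_sd_cm = culm_sd_cm,
             measurement_sd_cm = measurement_sd_cm,
             surface_noise_sd_cm = surface_noise_sd_cm,
             n_culms = as.integer(n_culms), wind_smear_px = as.integer(wind_smear_px),
             n_gcp = as.integer(n_gcp), n_checkpoints = as.integer(n_checkpoints),
             target_side_m = target_side_m,
             georef_shift_cm = georef_shift_cm,
             georef_noise_sd_cm = georef_noise_sd_cm)
  validate_config(cf)
}

#' Validate (and complete) a simulation configuration
#'
#' Fills the derived extent when missing and checks every invariant: SDs
#' non-negative, positive cell size, the plot footprint fits the extent, the
#' raster stays below a hundred million cells.
#'
#' @param cf a \code{simulation_config} or a plain named list of its fields
#'   (unknown fields are rejected).
#' @return the validated \code{simulation_config}.
#' @export
validate_config <- function(cf) {
  template <- formals(simulation_config)
  unknown <- setdiff(names(cf), names(template))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))

  sds <- c("genotype_sd_cm", "replicate_sd_cm", "block_sd_cm", "culm_sd_cm",
           "measurement_sd_cm", "surface_noise_sd_cm", "georef_noise_sd_cm")
  for (f in sds) if (cf[[f]] < 0) stop(f, " must be >= 0")
  if (cf$cell_size_m <= 0) stop("cell_size_m must be > 0")
  if (cf$terrain_relief_cm < 0) stop("terrain_relief_cm must be >= 0")
  for (f in c("plot_length_m", "bed_width_m", "inter_row_m", "inter_bed_m"))
    if (cf[[f]] <= 0) stop(f, " must be > 0")
  if (cf$alley_m < 0) stop("alley_m must be >= 0")
  if (is.null(cf$stage_mean_cm) || is.null(names(cf$stage_mean_cm)))
    stop("stage_mean_cm must be a named vector of growth-stage means")

  if (is.null(cf$extent_m)) {
    v <- cf$n_genotypes; s <- cf$n_blocks_per_rep
    k <- max(1L, v %/% s)
    plot_w <- 2 * cf$bed_width_m + cf$inter_bed_m
    pitch_x <- plot_w + cf$alley_m
    pitch_y <- cf$plot_length_m + cf$alley_m
    n_block_cols <- max(1L, as.integer(ceiling(sqrt(
      cf$n_replicates * s * k * pitch_y / (k * pitch_x)))))
    n_block_cols <- min(n_block_cols, s)
    n_rows <- as.integer(ceiling(s / n_block_cols)) * cf$n_replicates
    cf$extent_m <- c(2 * cf$margin_m + n_block_cols * k * pitch_x,
                     2 * cf$margin_m + n_rows * pitch_y)
  }
  plot_w <- 2 * cf$bed_width_m + cf$inter_bed_m
  if (plot_w > cf$extent_m[1] - 2 * cf$margin_m ||
      cf$plot_length_m > cf$extent_m[2] - 2 * cf$margin_m)
    stop("a single plot footprint does not fit the extent")
  n_cells <- prod(ceiling(cf$extent_m / cf$cell_size_m))
  if (n_cells > 1e8)
    stop(sprintf("extent/cell_size imply %.3g cells (> 1e8); coarsen cell_size_m or shrink extent_m",
                 n_cells))
  class(cf) <- "simulation_config"
  cf
}

#' Read a simulation config from a YAML file
#'
#' Missing fields take the package defaults; unknown fields are an error; an
#' empty file yields the full default config.
#'
#' @param path YAML file whose keys mirror \code{\link{simulation_config}}
#'   arguments.
#' @return a validated \code{simulation_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$stage_mean_cm)) raw$stage_mean_cm <- unlist(raw$stage_mean_cm)
  if (!is.null(raw$extent_m)) raw$extent_m <- as.numeric(unlist(raw$extent_m))
  do.call(simulation_config, raw)
}
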
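#!/usr/bin/env Rscript
# Simulate the demo wheat trial: terrain (DTM), per-stage canopy surfaces
# (DSMs) with ground-target pillars, the alpha-lattice layout, manual ground
# measurements and the underlying truth. Everything downstream works from
# the files this script writes.

suppressPackageStartupMessages(library(phenoheight))

cf <- read_config(file.path("analysis", "config.yaml"))
out <- file.path("results", "trial")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("Simulating trial:", cf$n_genotypes, "genotypes x", cf$n_replicates,
    "reps,", cf$n_blocks_per_rep, "blocks/rep, GSD",
    cf$cell_size_m * 100, "cm\n")
trial <- simulate_trial(cf)

write_elevation_raster(trial$terrain, file.path(out, "dtm.tif"))
for (st in names(trial$dsm))
  write_elevation_raster(trial$dsm[[st]],
                         file.path(out, sprintf("dsm_%s.tif",
                                                gsub("[^A-Za-z0-9]", "", st))))
write_layout_geojson(trial$layout, file.path(out, "layout.geojson"))
write.csv(trial$targets, file.path(out, "targets.csv"), row.names = FALSE)
write.csv(trial$ground, file.path(out, "ground_heights.csv"), row.names = FALSE)
write.csv(trial$truth$plot_true_height_cm, file.path(out, "truth.csv"),
          row.names = FALSE)

ext <- grid_extent(trial$terrain)
cat(sprintf("Field: %.1f x %.1f m, %d plots, %d ground targets (%d GCP + %d CP)\n",
            ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"],
            nrow(trial$layout$plots), nrow(trial$targets),
            sum(trial$targets$role == "gcp"),
            sum(trial$targets$role == "checkpoint")))
cat("Stages simulated:", paste(names(trial$dsm), collapse = ", "), "\n")
cat("Wrote rasters, layout, targets, ground truth to", out, "\n")
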
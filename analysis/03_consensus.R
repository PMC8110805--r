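#!/usr/bin/env Rscript
# Stage 3 — harmonization and consensus categories per timeframe.
#
# Binarizes every surface at its model's threshold, harmonizes the binary
# maps onto the common 25-km grid (intersection of all model extents,
# area-weighted majority rule), sums them into agreement maps and classifies
# the three consensus categories: at least 5 of 7 agreeing models for the
# present day, at least 4 of 5 for the future. Rasters to scratch/pipeline/,
# category composition table to results/.

suppressPackageStartupMessages(library(sdmconsensus))

sim_dir <- "scratch/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")
out_dir <- "scratch/pipeline"

occ <- read_occurrences_csv(file.path(sim_dir, "occurrences.csv"))
zones <- read_zones_geojson(file.path(sim_dir, "zones.geojson"))
present_files <- sort(list.files(sim_dir, "_present\\.asc$", full.names = TRUE))
models <- lapply(present_files, function(f) {
  id <- sub("_present\\.asc$", "", basename(f))
  fut <- file.path(sim_dir, paste0(id, "_future.asc"))
  list(
    model_id = id,
    present = read_suitability_asc(f),
    future = if (file.exists(fut)) read_suitability_asc(fut)
  )
})

bundle <- run_all(models, occ, zones, omission = c(0.05, 0.10))
save_bundle(bundle, out_dir)

cg <- bundle$common_grid
message(sprintf("Common grid: %d x %d cells of %g km (%d cells)",
                cg$n_rows, cg$n_cols, cg$cell_size, cg$n_rows * cg$n_cols))

comp <- do.call(rbind, lapply(c("p05", "p10"), function(key) {
  res <- bundle[[key]]
  do.call(rbind, lapply(c("present", "future"), function(tf) {
    f <- category_fractions(res[[paste0("category_", tf)]])
    data.frame(omission = res$omission, timeframe = tf,
               unsuitable = f[["1"]], uncertain = f[["2"]],
               suitable = f[["3"]])
  }))
}))
write.csv(comp, "results/category_fractions.csv", row.names = FALSE)
message("Category composition (fractions of the common grid):")
print(comp, row.names = FALSE, digits = 3)
message(sprintf(
  "At the 5%% threshold, consensually suitable area grows from %.0f%% (present) to %.0f%% (future).",
  100 * comp$suitable[comp$omission == 0.05 & comp$timeframe == "present"],
  100 * comp$suitable[comp$omission == 0.05 & comp$timeframe == "future"]
))
message("Wrote results/category_fractions.csv and rasters under ", out_dir)
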
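#!/usr/bin/env Rscript
# Stage 1 — materialize the synthetic study system.
#
# Generates the ensemble the rest of the workflow analyses: seven present-day
# suitability surfaces (five with a warmed-future counterpart) built from one
# latent field, occurrence points biased toward suitable conditions, and 65
# urban-area polygons. Everything is written to disk in the same formats the
# pipeline reads (ASCII grids, CSV, GeoJSON), so stages 2-5 run purely from
# files. Rasters go to scratch/ (they are bulky and regenerable); small
# tables to results/.

suppressPackageStartupMessages(library(sdmconsensus))

seed <- 1L
sim_dir <- "scratch/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
message(sprintf("Generating ensemble (seed %d): %d models, %d with futures",
                seed, cfg$n_models, sum(cfg$has_future)))
ens <- generate_ensemble(cfg)

for (m in ens$models) {
  write_suitability_asc(m$present,
                        file.path(sim_dir, paste0(m$model_id, "_present.asc")))
  if (!is.null(m$future)) {
    write_suitability_asc(m$future,
                          file.path(sim_dir, paste0(m$model_id, "_future.asc")))
  }
}
write_suitability_asc(ens$latent_present, file.path(sim_dir, "latent.asc"))
write_occurrences_csv(ens$occurrences, file.path(sim_dir, "occurrences.csv"))
write_zones_geojson(ens$zones, file.path(sim_dir, "zones.geojson"))
jsonlite::write_json(list(seed = seed), file.path(sim_dir, "seed.json"),
                     auto_unbox = TRUE)

# a small per-model inventory table for the record
inv <- do.call(rbind, lapply(ens$models, function(m) {
  s <- m$present$spec
  data.frame(model_id = m$model_id, cell_size = s$cell_size,
             n_rows = s$n_rows, n_cols = s$n_cols, scale = m$present$scale,
             has_future = !is.null(m$future))
}))
write.csv(inv, "results/model_inventory.csv", row.names = FALSE)
message("Model inventory (native resolutions span ",
        min(inv$cell_size), "-", max(inv$cell_size), " km):")
print(inv, row.names = FALSE)
message("Wrote rasters to ", sim_dir, " and results/model_inventory.csv")
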
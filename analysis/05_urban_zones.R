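#!/usr/bin/env Rscript
# Stage 5 — suitability trends over urban-area polygons.
#
# Summarizes the category maps over the 65 zone polygons: per-zone category
# area fractions (exact polygon-cell intersection), the baseline
# (widest-coverage) category per timeframe, the precautionary worst-case
# override (second category covering at least a third of the zone and
# worsening the trajectory), and cohort percentages. Tables to results/.

suppressPackageStartupMessages(library(sdmconsensus))

sim_dir <- "scratch/sim"
pipe_dir <- "scratch/pipeline"
if (!dir.exists(pipe_dir)) stop("run analysis/03_consensus.R first")

zones <- read_zones_geojson(file.path(sim_dir, "zones.geojson"))
pres <- read_category_asc(file.path(pipe_dir, "p05", "category_present.asc"))
fut <- read_category_asc(file.path(pipe_dir, "p05", "category_future.asc"))

s <- summarize_zones(zones, pres, fut)
write.csv(s$zones, "results/zone_summary.csv", row.names = FALSE)
write.csv(s$cohort, "results/zone_cohort.csv", row.names = FALSE)

n <- nrow(s$zones)
message(sprintf("Summarized %d urban zones (5%% omission threshold):", n))
for (tf in c("present", "future")) {
  p <- s$cohort$pct_zones[s$cohort$timeframe == tf]
  message(sprintf(
    "  %s: %.0f%% unsuitable, %.0f%% uncertain, %.0f%% suitable",
    tf, p[1], p[2], p[3]
  ))
}
message(sprintf(
  "Worst-case override applied in %d of %d zones; no zone's trajectory became more favourable than its baseline.",
  sum(s$zones$worst_case_applied), n
))
severest <- s$zones[s$zones$baseline_present == 1 & s$zones$final_future == 3, ]
if (nrow(severest)) {
  message("Zones going from consensually unsuitable to consensually suitable: ",
          paste(severest$zone_id, collapse = ", "))
}
message("Wrote results/zone_summary.csv and results/zone_cohort.csv")
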
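#!/usr/bin/env Rscript
# Stage 4 — nine-class suitability-change trajectories.
#
# Crosses the present-day and future category maps written by stage 3 into
# the trajectory raster (code = 10*present + future), reports area fractions
# per class and the named aggregates on both bases (share of the study area,
# and share of the newly suitable area for its subsets), and records the
# traffic-light-derived palette. Tables to results/.

suppressPackageStartupMessages(library(sdmconsensus))

pipe_dir <- "scratch/pipeline"
if (!dir.exists(pipe_dir)) stop("run analysis/03_consensus.R first")

rows <- list()
for (key in c("p05", "p10")) {
  pres <- read_category_asc(file.path(pipe_dir, key, "category_present.asc"))
  fut <- read_category_asc(file.path(pipe_dir, key, "category_future.asc"))
  traj <- classify_trajectory(pres, fut)
  rep <- area_report(traj)
  tab <- rep$table
  tab$omission <- if (key == "p05") 0.05 else 0.10
  rows[[key]] <- tab
  if (key == "p05") {
    ag <- rep$aggregates
    message("Trajectory aggregates at the 5% threshold:")
    message(sprintf("  remains suitable: %.1f%% of the study area",
                    100 * ag$remain_suitable$fraction_of_study_area))
    message(sprintf("  newly suitable:   %.1f%% of the study area",
                    100 * ag$newly_suitable$fraction_of_study_area))
    message(sprintf(
      "    of which %.1f%% starts from consensually unsuitable (%.1f%% of the study area)",
      100 * ag$newly_suitable_from_unsuitable$share_of_newly_suitable,
      100 * ag$newly_suitable_from_unsuitable$fraction_of_study_area))
    message(sprintf("  remains unsuitable: %.2f%% of the study area",
                    100 * ag$remain_unsuitable$fraction_of_study_area))
    message(sprintf("  uncertain in the future: %.1f%% of the study area",
                    100 * ag$uncertain_future$fraction_of_study_area))
    jsonlite::write_json(ag, "results/trajectory_aggregates.json",
                         auto_unbox = TRUE, digits = NA)
  }
}
out <- do.call(rbind, rows)
out$color <- trajectory_palette()[as.character(out$code)]
write.csv(out, "results/trajectory_areas.csv", row.names = FALSE)
message("Wrote results/trajectory_areas.csv and results/trajectory_aggregates.json")
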
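#!/usr/bin/env Rscript
# Step 2: flight-performance metrics over the processed cohort: the
# population activity curve (proportion flying per minute, which should decay
# roughly exponentially from ~78% to ~8%), the flight-initiation statistic by
# morph and condition, and summary distributions of distance and speed.

suppressPackageStartupMessages(library(hovermill))

in_dir <- "results/cohort"
stopifnot(file.exists(file.path(in_dir, "transect.csv")))
# fly_summary.csv already carries the metadata columns (step 1 joins them)
transect <- utils::read.csv(file.path(in_dir, "transect.csv"))
summaries <- utils::read.csv(file.path(in_dir, "fly_summary.csv"))
summaries$condition <- factor(summaries$condition,
                              levels = c("thin", "medium", "fat"))

ac <- activity_curve(transect)
utils::write.csv(ac, "results/activity_curve.csv", row.names = FALSE)
message(sprintf("Activity: %.1f%% flying in minute 1, %.1f%% in minute 240.",
                100 * ac$proportion_flying[1],
                100 * ac$proportion_flying[240]))

# initiation statistic by morph x condition (flies with >= 1 flight)
ok <- summaries$n_flights >= 1
init <- aggregate(mean_time_to_initiate ~ morph + condition,
                  data = summaries[ok, ], FUN = median)
utils::write.csv(init, "results/initiation_by_group.csv", row.names = FALSE)
message("Median seconds to initiate a flight, by morph and condition:")
print(init)

dist_rng <- range(summaries$total_distance)
message(sprintf(
  "Distance range %.0f m - %.1f km; flights per fly %d - %d; mean speed %.2f - %.2f m/s.",
  dist_rng[1], dist_rng[2] / 1000, min(summaries$n_flights),
  max(summaries$n_flights), min(summaries$mean_speed, na.rm = TRUE),
  max(summaries$mean_speed, na.rm = TRUE)))
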
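#!/usr/bin/env Rscript
# 2D migration analysis: speed and penalized persistence of synthetic
# persistent-random-walk tracks, untreated vs growth-factor treated (planted
# 1.5x speed and 2x persistence-time shift), sampled every 30 min for 48 h.
#
# Writes: results/migration_metrics.tsv, results/migration_boxes.json,
#         results/migration_comparison.csv, results/migration_boxes.pdf,
#         results/migration_timecourse.csv

suppressPackageStartupMessages(library(mechpheno))
dir.create("results", showWarnings = FALSE)
seed <- 20260919

ctrl <- simulate_tracks(300, mean_speed = 20, persistence_time = 2,
                        t_max = 48, dropout_hazard = 0.02,
                        sampling_interval = 0.5, seed = seed + 1)
trt <- simulate_tracks(300, mean_speed = 30, persistence_time = 4,
                       t_max = 48, dropout_hazard = 0.02,
                       sampling_interval = 0.5, seed = seed + 2)

mc <- track_metrics(ctrl$tracks, t_max = 48)
mt <- track_metrics(trt$tracks, t_max = 48)
metrics <- rbind(cbind(condition = "control", mc),
                 cbind(condition = "treated", mt))
write.table(metrics, "results/migration_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- compare_migration(mc, mt)
write.csv(cmp, "results/migration_comparison.csv", row.names = FALSE)

boxes <- list(
  speed = lapply(list(control = mc$speed, treated = mt$speed),
                 function(v) unclass(summarize_condition(v, "p5p95"))),
  persistence = lapply(list(control = mc$persistence, treated = mt$persistence),
                       function(v) unclass(summarize_condition(v, "p5p95")))
)
jsonlite::write_json(boxes, "results/migration_boxes.json", auto_unbox = TRUE,
                     digits = NA)

ggplot2::ggsave(
  "results/migration_boxes.pdf",
  plot_notched_box(list(control = mc$speed, treated = mt$speed),
                   whisker_mode = "p5p95", ylab = "speed (um/h)"),
  width = 4, height = 4)

tc <- rbind(cbind(condition = "control",
                  migration_timecourse(ctrl$tracks, window = 12, step = 6)),
            cbind(condition = "treated",
                  migration_timecourse(trt$tracks, window = 12, step = 6)))
write.csv(tc, "results/migration_timecourse.csv", row.names = FALSE)

cat("Migration comparison (treated vs control):\n")
print(cmp, row.names = FALSE)
cat("\nBoth metrics should shift up and reach Mann-Whitney p < 0.001.\n")
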
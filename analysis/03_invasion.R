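#!/usr/bin/env Rscript
# 3D collagen-invasion analysis. Two synthetic assays (30% vs 60% planted
# invaded fraction, mean depth 40 um below the invasion front) are rendered
# as confocal-like nucleus stacks; nuclei are re-detected with the
# Gaussian-smoothed local-maxima spot detector, classified by z-threshold
# and summarized as invaded percentage + depth histogram.
#
# Writes: results/invasion_summaries.csv, results/invasion_depths.csv,
#         results/invasion_depth_hist.pdf

suppressPackageStartupMessages(library(mechpheno))
dir.create("results", showWarnings = FALSE)
seed <- 20260919

run_assay <- function(label, invaded_fraction, sd) {
  sim <- simulate_invasion_spots(500, invaded_fraction = invaded_fraction,
                                 depth_scale = 40, min_separation = 18,
                                 seed = sd)
  stack <- render_invasion_stack(sim$spots, voxel_size = c(2, 2, 2),
                                 snr = 10, seed = sd)
  det <- detect_nuclei_3d(stack, voxel_size = c(2, 2, 2), sigma = 4)
  # classify halfway between surface jitter and the invasion front
  summ <- invasion_summary(det, z_threshold = sim$truth$invasion_front / 2)
  list(label = label, planted = 100 * invaded_fraction, sim = sim,
       detected = det, summary = summ)
}

a <- run_assay("control", 0.30, seed + 1)
b <- run_assay("treated", 0.60, seed + 2)

cmp <- compare_invasion(a$summary, b$summary)

summaries <- data.frame(
  condition = c(a$label, b$label),
  planted_percent = c(a$planted, b$planted),
  n_detected = c(a$summary$n_total, b$summary$n_total),
  percent_invaded = c(a$summary$percent_invaded, b$summary$percent_invaded),
  mean_depth_um = c(mean(a$summary$depths), mean(b$summary$depths))
)
write.csv(summaries, "results/invasion_summaries.csv", row.names = FALSE)

depths <- rbind(data.frame(condition = a$label, depth_um = a$summary$depths),
                data.frame(condition = b$label, depth_um = b$summary$depths))
write.csv(depths, "results/invasion_depths.csv", row.names = FALSE)

ggplot2::ggsave("results/invasion_depth_hist.pdf",
                plot_depth_histogram(b$summary), width = 5, height = 3.5)

cat("Invasion summaries (detected from rendered stacks):\n")
print(summaries, row.names = FALSE)
cat(sprintf("\nTwo-proportion test control vs treated: diff = %.1f points, p = %.3g\n",
            cmp$difference, cmp$p_value))
cat("Detected percentages should sit within a few points of the plants\n")
cat("(500 cells, binomial sampling + rare detector misses) and the mean\n")
cat("depth near the 40 um exponential scale plus the 10 um front offset.\n")
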
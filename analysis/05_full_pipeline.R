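#!/usr/bin/env Rscript
# End-to-end driver: runs all four stages through the config-driven pipeline
# and writes the consolidated human-readable report.
#
# Writes: results/pipeline_run/ (per-stage artifacts + manifest.json),
#         results/pipeline_report.txt

suppressPackageStartupMessages(library(mechpheno))
dir.create("results", showWarnings = FALSE)

bundle <- run_pipeline(list(
  stages = c("stretcher", "migration", "invasion", "expression"),
  seed = 20260919,
  out_dir = "results/pipeline_run",
  stretcher = list(n_cells = 300, effect = 34, n_bootstrap = 1000),
  migration = list(n_cells = 300, speed_ratio = 1.5),
  invasion = list(n_cells = 500, invaded_fraction = 0.3),
  expression = list(n_genes = 1000, de_fraction = 0.05, effect_log2fc = 2)
))

report <- write_report(bundle, "results/pipeline_report.txt")
cat(report, sep = "\n")
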
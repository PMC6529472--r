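#!/usr/bin/env Rscript
# Optical-stretcher rigidity analysis on synthetic creep-and-recovery data.
#
# Simulates four cell populations (untreated control plus three growth-factor
# treatments planted at 21% / 34% / 37% reductions of equilibrium strain,
# n = 300 cells each), runs the bootstrap-averaged strain-curve analysis and
# asks how well the pipeline recovers each planted rigidity shift.
#
# Writes: results/stretcher_curves.csv, results/stretcher_comparisons.csv,
#         results/stretcher_curves.pdf

suppressPackageStartupMessages(library(mechpheno))
dir.create("results", showWarnings = FALSE)
seed <- 20260919

prm <- creep_params(cv_between_cells = 0.4)
pro <- stretch_protocol()
effects <- c(control = 0, HGF = 21, TGFb = 34, `TGFb+HGF` = 37)

pops <- lapply(seq_along(effects), function(i) {
  eff <- if (effects[i] == 0) NULL else effects[i]
  simulate_creep_population(prm, pro, 300, effect = eff,
                            seed = seed + i)
})
names(pops) <- names(effects)

curves <- lapply(seq_along(pops), function(i) {
  bootstrap_mean_curve(pops[[i]]$curves, n_bootstrap = 1000, seed = seed + 10 + i)
})
names(curves) <- names(pops)

curve_df <- do.call(rbind, lapply(names(curves), function(nm) {
  cu <- curves[[nm]]
  data.frame(condition = nm, t_s = cu$t, eps_bs = cu$epsilon_bs,
             ci_halfwidth = cu$ci_halfwidth)
}))
write.csv(curve_df, "results/stretcher_curves.csv", row.names = FALSE)

cmp_df <- do.call(rbind, lapply(names(effects)[-1], function(nm) {
  cmp <- compare_rigidity(pops$control$curves, pops[[nm]]$curves,
                          n_bootstrap = 1000,
                          seed = seed + 20 + match(nm, names(effects)),
                          labels = c("control", nm))
  data.frame(treatment = nm, planted_percent = effects[nm],
             eps_max_control = cmp$epsilon_max_control,
             eps_max_treated = cmp$epsilon_max_treated,
             recovered_percent = cmp$percent_reduction,
             mw_p_value = cmp$mw_p_value,
             frames_band_separated = sum(cmp$ci_separated))
}))
write.csv(cmp_df, "results/stretcher_comparisons.csv", row.names = FALSE)

ggplot2::ggsave("results/stretcher_curves.pdf", plot_creep_curves(curves),
                width = 7, height = 4.5)

cat("Rigidity recovery (percent reduction of bootstrap-averaged max strain):\n")
print(cmp_df[, c("treatment", "planted_percent", "recovered_percent",
                 "mw_p_value")], row.names = FALSE)
cat("\nEvery planted effect should be recovered within ~4 percentage points\n")
cat("and separate from control at Mann-Whitney p << 0.001.\n")
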
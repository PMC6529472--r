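#' Publication-style creep-and-recovery plot
#'
#' Bootstrap-averaged strain curves with their 95% confidence bands
#' (two-fold SD of bootstrap sample means), one ribbon per condition.
#'
#' @param curves Named list of `bootstrap_curve` objects.
#' @return A ggplot object.
#' @export
plot_creep_curves <- function(curves) {
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cu <- curves[[nm]]
    data.frame(condition = nm, t = cu$t, eps = cu$epsilon_bs,
               lo = cu$epsilon_bs - cu$ci_halfwidth,
               hi = cu$epsilon_bs + cu$ci_halfwidth)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$eps,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (s)", y = "strain",
                  title = "Creep-and-recovery (bootstrap mean +/- 2 SD)") +
    ggplot2::theme_minimal()
}

#' Notched box plot of per-condition metric samples
#'
#' Boxes follow [summarize_condition()]: type-7 quartiles, notches at
#' median +/- 1.58 IQR / sqrt(n), whiskers per the chosen mode.
#'
#' @param samples Named list of numeric vectors (one per condition).
#' @param whisker_mode `"iqr15"` or `"p5p95"`.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_notched_box <- function(samples, whisker_mode = "p5p95", ylab = "value") {
  df <- do.call(rbind, lapply(names(samples), function(nm) {
    s <- summarize_condition(samples[[nm]], whisker_mode)
    data.frame(condition = nm, median = s$median, q25 = s$q25, q75 = s$q75,
               notch_lo = s$median - s$notch_halfwidth,
               notch_hi = s$median + s$notch_halfwidth,
               w_lo = s$whisker_low, w_hi = s$whisker_high)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$w_lo, ymax = .data$w_hi),
                           width = 0.2) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$w_lo, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$w_hi),
      stat = "identity", fill = "grey85", width = 0.5) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$notch_lo,
                   ymax = .data$notch_hi),
      width = 0.25, fill = "grey60", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Frequency diagram of invasion depths
#'
#' @param summary An `invasion_summary`.
#' @return A ggplot object.
#' @export
plot_depth_histogram <- function(summary) {
  mids <- head(summary$breaks, -1) + summary$bin_width / 2
  df <- data.frame(depth = mids, count = summary$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$count)) +
    ggplot2::geom_col(width = summary$bin_width * 0.9, fill = "steelblue") +
    ggplot2::labs(x = "invasion depth (um)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Single-gene expression dynamics plot
#'
#' Raw log2 fold changes (points) with the Gaussian-process smoothed curve
#' (line) for selected genes.
#'
#' @param fc A smoothed `fold_change_set`.
#' @param genes Character vector of gene ids to display.
#' @return A ggplot object.
#' @export
plot_gene_dynamics <- function(fc, genes) {
  genes <- intersect(genes, rownames(fc$log2fc))
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, t = fc$timepoints, raw = fc$log2fc[g, ],
               smoothed = (fc$smoothed %||% fc$log2fc)[g, ])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), size = 1.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "firebrick") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
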
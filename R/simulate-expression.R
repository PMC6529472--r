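#' Simulate a log2 expression time course with planted DE genes
#'
#' Generates log2 intensities for `n_genes` over the given timepoints with
#' `n_replicates` replicates each. Non-DE genes are flat in expectation; a
#' planted fraction follows a smooth saturating response
#' `effect * (1 - exp(-t / t_half))` (random sign and per-gene response time)
#' reaching `effect_log2fc` at late times. Replicate noise is Gaussian on the
#' log2 scale.
#'
#' @param n_genes Number of genes.
#' @param timepoints Hours; default the 11-point design
#'   0, 0.5, 1, 2, 4, 6, 8, 12, 18, 24, 48.
#' @param n_replicates Replicates per timepoint.
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param effect_log2fc Asymptotic |log2 fold change| of DE genes.
#' @param noise_sd_log2 Replicate noise SD (log2 scale).
#' @param seed RNG seed.
#' @return A list with `expr` (an `expression_matrix`: genes x
#'   `t<h>_rep<k>` numeric matrix plus the design) and `truth` (logical
#'   `is_de`, signs and response times).
#' @export
simulate_expression_timecourse <- function(n_genes,
                                           timepoints = c(0, 0.5, 1, 2, 4, 6, 8,
                                                          12, 18, 24, 48),
                                           n_replicates = 3,
                                           de_fraction = 0.05,
                                           effect_log2fc = 2,
                                           noise_sd_log2 = 0.1,
                                           seed = 1) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  stopifnot_scalar_number(de_fraction, "de_fraction", 0, 1)
  if (!0 %in% timepoints) stop("timepoints must include t = 0", call. = FALSE)
  timepoints <- sort(unique(timepoints))
  with_seed(seed, {
    n_de <- round(n_genes * de_fraction)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    sign <- ifelse(runif(n_genes) < 0.5, -1, 1)
    t_half <- runif(n_genes, 2, 12)
    base <- runif(n_genes, 6, 12)        # baseline log2 intensity
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    cols <- as.vector(outer(seq_len(n_replicates), timepoints,
                            function(r, t) sprintf("t%g_rep%d", t, r)))
    # per-gene expected log2fc profile
    prof <- outer(seq_len(n_genes), seq_along(timepoints), function(i, j) {
      ifelse(is_de[i],
             sign[i] * effect_log2fc * (1 - exp(-timepoints[j] / t_half[i])),
             0)
    })
    m <- matrix(NA_real_, n_genes, length(cols), dimnames = list(genes, cols))
    ci <- 1L
    for (j in seq_along(timepoints)) {
      for (r in seq_len(n_replicates)) {
        mu <- base + prof[, j]
        m[, ci] <- mu + if (noise_sd_log2 > 0) rnorm(n_genes, 0, noise_sd_log2) else 0
        ci <- ci + 1L
      }
    }
    expr <- expression_matrix(m, timepoints = rep(timepoints, each = n_replicates))
    list(
      expr = expr,
      truth = list(is_de = is_de, sign = sign, t_half = t_half,
                   effect_log2fc = effect_log2fc, seed = seed)
    )
  })
}
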
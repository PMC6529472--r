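#' Construct an expression matrix with a time-course design
#'
#' @param values Numeric matrix of log2 intensities, genes in rows, one
#'   column per (timepoint, replicate) sample; column names like
#'   `t<h>_rep<k>` are generated if absent.
#' @param timepoints Numeric vector, hours, one entry per column.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, timepoints) {
  stopifnot(is.matrix(values), ncol(values) == length(timepoints))
  if (!0 %in% timepoints) stop("design must include t = 0", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene_%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    rep_idx <- ave(seq_along(timepoints), timepoints, FUN = seq_along)
    colnames(values) <- sprintf("t%g_rep%d", timepoints, rep_idx)
  }
  structure(list(values = values, timepoints = as.numeric(timepoints)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples over %d timepoints\n",
              nrow(x$values), ncol(x$values), length(unique(x$timepoints))))
  invisible(x)
}

#' Per-gene log2 fold changes versus the t = 0 baseline
#'
#' Replicates are mean-averaged per timepoint on the log2 scale, then
#' `log2fc(t) = mean(t) - mean(0)`. Timepoints with no finite replicate
#' value for a gene are filled by linear interpolation over the time axis
#' and flagged in the `interpolated` matrix.
#'
#' @param expr An [expression_matrix()].
#' @return A list of class `fold_change_set`: `timepoints` (unique hours),
#'   `log2fc` (genes x timepoints matrix, first column 0 by construction),
#'   `interpolated` (logical matrix), and `smoothed` (NULL until
#'   [gp_smooth_timecourse()] is applied).
#' @export
fold_change_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  tps <- sort(unique(expr$timepoints))
  means <- sapply(tps, function(tp) {
    cols <- expr$timepoints == tp
    rowMeans(expr$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  colnames(means) <- sprintf("t%g", tps)
  if (any(is.nan(means[, 1]))) {
    bad <- rownames(expr$values)[is.nan(means[, 1])]
    stop("genes missing a t = 0 value: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  interpolated <- is.nan(means)
  if (any(interpolated)) {
    for (i in which(rowSums(interpolated) > 0)) {
      ok <- !interpolated[i, ]
      means[i, !ok] <- approx(tps[ok], means[i, ok], xout = tps[!ok],
                              rule = 2)$y
    }
  }
  lfc <- means - means[, 1]
  structure(
    list(timepoints = tps, log2fc = lfc, interpolated = interpolated,
         smoothed = NULL),
    class = "fold_change_set"
  )
}

# Negative log marginal likelihood of a zero-mean GP with RBF kernel,
# parameterized by log(signal variance), log(length scale), log(noise
# variance). `d2` is the squared time-distance matrix.
gp_nll <- function(par, d2, y, noise_floor) {
  s2 <- exp(par[1])
  l2 <- exp(2 * par[2])
  n2 <- max(exp(par[3]), noise_floor^2)
  K <- s2 * exp(-0.5 * d2 / l2) + diag(n2, length(y))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

gp_posterior_mean <- function(t, y, s2, l, n2) {
  d2 <- outer(t, t, function(a, b) (a - b)^2)
  K <- s2 * exp(-0.5 * d2 / l^2)
  Ky <- K + diag(n2, length(y))
  K %*% solve(Ky, y)
}

#' Gaussian-process smoothing of a fold-change time course
#'
#' Fits a zero-mean Gaussian process with an RBF (squared-exponential)
#' kernel to each gene's log2 fold-change series. Hyperparameters (signal
#' variance, length scale, noise variance) are set by marginal-likelihood
#' maximization (`L-BFGS-B` on log parameters) with the noise SD bounded
#' below by `noise_floor`; the smoothed series is the posterior mean at the
#' observed timepoints. If the optimizer fails the length scale falls back
#' to half the time span, with a warning.
#'
#' @param fc A `fold_change_set` from [fold_change_matrix()] (needs >= 4
#'   timepoints), or a single numeric series via `timepoints`.
#' @param kernel Only `"rbf"` is implemented.
#' @param noise_floor Lower bound on the noise SD (log2 units).
#' @return The `fold_change_set` with the `smoothed` matrix filled in and
#'   `smoothing_params` recording the per-gene hyperparameters.
#' @export
gp_smooth_timecourse <- function(fc, kernel = "rbf", noise_floor = 0.05) {
  kernel <- match.arg(kernel, "rbf")
  stopifnot(inherits(fc, "fold_change_set"))
  t <- fc$timepoints
  if (length(t) < 4) stop("need at least 4 timepoints", call. = FALSE)
  ts <- t / max(t)                        # scale time to [0, 1] for stable optimization
  d2 <- outer(ts, ts, function(a, b) (a - b)^2)
  sm <- fc$log2fc
  hp <- matrix(NA_real_, nrow(sm), 3,
               dimnames = list(rownames(sm), c("signal_var", "length_scale",
                                               "noise_var")))
  for (i in seq_len(nrow(sm))) {
    y <- fc$log2fc[i, ]
    if (sd(y) == 0) {
      sm[i, ] <- y                         # constant series: GP mean is itself
      hp[i, ] <- c(0, 0.5, noise_floor^2)
      next
    }
    init <- c(log(max(var(y), 1e-4)), log(0.25), log(max(var(y) / 4, noise_floor^2)))
    fit <- tryCatch(
      optim(init, gp_nll, d2 = d2, y = y, noise_floor = noise_floor,
            method = "L-BFGS-B", lower = c(-12, -4, 2 * log(noise_floor)),
            upper = c(8, 2, 8)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning(sprintf("GP optimizer failed for %s; fixed length-scale fallback",
                      rownames(sm)[i]))
      par <- c(log(max(var(y), 1e-4)), log(0.5), log(max(noise_floor^2, var(y) / 10)))
    } else {
      par <- fit$par
    }
    s2 <- exp(par[1])
    l <- exp(par[2])
    n2 <- max(exp(par[3]), noise_floor^2)
    sm[i, ] <- gp_posterior_mean(ts, y, s2, l, n2)
    hp[i, ] <- c(s2, l * max(t), n2)
  }
  fc$smoothed <- sm
  fc$smoothing_params <- list(kernel = kernel, noise_floor = noise_floor,
                              hyperparameters = hp)
  fc
}

#' Call up- and downregulated genes from smoothed fold changes
#'
#' A gene is called up if its smoothed log2 fold change reaches
#' `log2fc_threshold` at any timepoint, down if it reaches the negative
#' threshold; a gene with excursions beyond both thresholds appears in both
#' lists. Falls back to the raw fold changes when no smoothing has been
#' applied.
#'
#' @param fc A `fold_change_set`.
#' @param log2fc_threshold Positive threshold on |log2 fold change|.
#' @return A list with character vectors `up` and `down` and the threshold.
#' @export
call_differential_genes <- function(fc, log2fc_threshold = 1) {
  stopifnot(inherits(fc, "fold_change_set"))
  stopifnot_scalar_number(log2fc_threshold, "log2fc_threshold", 0,
                          strict_lower = TRUE)
  m <- fc$smoothed %||% fc$log2fc
  up <- rownames(m)[apply(m, 1, max) >= log2fc_threshold]
  down <- rownames(m)[apply(m, 1, min) <= -log2fc_threshold]
  list(up = up, down = down, threshold = log2fc_threshold)
}

# Upper-tail hypergeometric probability P(X >= k) for X ~ Hyper(N, K, n),
# by log-space summation of the exact terms (numerically stable for large
# counts; matches brute-force enumeration exactly for small N).
hypergeom_upper_tail <- function(k, N, K, n) {
  if (k <= max(0, n + K - N)) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- k:hi
  terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(1, exp(logsumexp(terms)))
}

#' Hypergeometric enrichment of a curated gene set in a DE list
#'
#' Tests whether the overlap between a curated gene set and a list of
#' differentially expressed genes is larger than expected under sampling
#' without replacement from the gene universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n_de)`, evaluated by
#' stable log-space summation. Genes outside the universe are dropped with
#' a warning; `fraction_of_set = 100 * k / K` mirrors reporting the hit
#' fraction of the curated set.
#'
#' @param set Character vector of curated set members (or a list with
#'   `name` and `members`).
#' @param de_genes Character vector of DE gene identifiers.
#' @param universe Character vector of all measured genes.
#' @param direction Label carried into the result (`"up"` or `"down"`).
#' @return An object of class `enrichment_result` with fields `set_size`
#'   (K), `universe_size` (N), `n_de`, `overlap` (k), `fraction_of_set`,
#'   `p_value`, `direction`.
#' @export
hypergeometric_enrichment <- function(set, de_genes, universe,
                                      direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.list(set)) set <- set$members
  set <- unique(set)
  universe <- unique(universe)
  outside <- setdiff(set, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d set members outside the universe were dropped",
                    length(outside)))
    set <- intersect(set, universe)
  }
  de_genes <- intersect(unique(de_genes), universe)
  N <- length(universe)
  K <- length(set)
  n_de <- length(de_genes)
  k <- length(intersect(set, de_genes))
  if (n_de == 0) {
    warning("no differentially expressed genes: p = 1 by convention")
    p <- 1
  } else {
    p <- hypergeom_upper_tail(k, N, K, n_de)
  }
  structure(
    list(set_size = K, universe_size = N, n_de = n_de, overlap = k,
         fraction_of_set = 100 * k / K, p_value = p, direction = direction),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s: %d/%d set genes DE (%.0f%%) of %d DE in universe %d; p = %.3g\n",
    x$direction, x$overlap, x$set_size, x$fraction_of_set, x$n_de,
    x$universe_size, x$p_value))
  invisible(x)
}
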
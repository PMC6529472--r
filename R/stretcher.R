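#' Extract the stretched-axis diameter series from a frame stack
#'
#' Segments each frame by Otsu thresholding, keeps the largest connected
#' component and measures its extent along the stretch (horizontal / laser)
#' axis in micrometres. Frames whose segmentation is empty raise an error
#' naming the offending frame.
#'
#' @param frames Numeric array `ny x nx x n_frames` with intensities in
#'   \[0, 1\] (the convention of [render_stretcher_frames()] and TIFF I/O:
#'   the second array dimension is the horizontal image axis).
#' @param protocol A [stretch_protocol()] matching the stack length.
#' @param pixel_size Micrometres per pixel.
#' @param axis Stretch axis; only `"horizontal"` is supported (the laser axis
#'   renders horizontally).
#' @param cell_id Identifier carried into the result.
#' @return An object of class `diameter_series` with fields `cell_id`, `t`
#'   (s), `L` (µm) and `protocol`.
#' @export
extract_diameter_series <- function(frames, protocol, pixel_size,
                                    axis = "horizontal", cell_id = "cell") {
  axis <- match.arg(axis, "horizontal")
  stopifnot(inherits(protocol, "stretch_protocol"))
  if (length(dim(frames)) != 3L || dim(frames)[3] != protocol$n_frames) {
    stop("frame stack does not match protocol$n_frames", call. = FALSE)
  }
  L <- numeric(protocol$n_frames)
  for (k in seq_len(protocol$n_frames)) {
    frame <- frames[, , k]
    thr <- tryCatch(EBImage::otsu(EBImage::Image(frame)),
                    error = function(e) NA_real_)
    mask <- if (is.na(thr)) frame > 0.5 else frame > thr
    if (!any(mask)) {
      stop(sprintf("segmentation failed: empty foreground at frame %d", k),
           call. = FALSE)
    }
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(lab)
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    cols <- which(apply(lab == keep, 2L, any))
    extent_px <- max(cols) - min(cols) + 1L
    if (extent_px <= 0) {
      stop(sprintf("segmentation failed: zero extent at frame %d", k),
           call. = FALSE)
    }
    L[k] <- extent_px * pixel_size
  }
  structure(
    list(cell_id = cell_id, t = protocol$t, L = L, protocol = protocol),
    class = "diameter_series"
  )
}

#' Construct a diameter series directly (e.g. from pre-extracted CSV data)
#'
#' @inheritParams extract_diameter_series
#' @param t Frame times (s), strictly increasing.
#' @param L Stretched-axis diameters (µm), all positive.
#' @export
diameter_series <- function(cell_id, t, L, protocol) {
  stopifnot(inherits(protocol, "stretch_protocol"),
            length(t) == protocol$n_frames, length(L) == length(t))
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing", call. = FALSE)
  if (any(L <= 0)) stop("diameters must be positive", call. = FALSE)
  structure(list(cell_id = cell_id, t = as.numeric(t), L = as.numeric(L),
                 protocol = protocol),
            class = "diameter_series")
}

#' Convert a diameter series into a dimensionless strain curve
#'
#' Strain is relative elongation of the stretched axis,
#' `epsilon_i(t) = L_i(t) / L_i(0) - 1`. The baseline `L_i(0)` is either the
#' literal first frame or, for noise robustness, the mean diameter over the
#' unloaded pre-load phase.
#'
#' @param d A `diameter_series`.
#' @param baseline `"preload_mean"` (default; mean of all frames before
#'   `t_load_on`) or `"first_frame"` (the literal `L(0)`).
#' @return A [strain_curve()].
#' @export
compute_strain_curve <- function(d, baseline = c("preload_mean", "first_frame")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(d, "diameter_series"))
  L0 <- switch(baseline,
    first_frame = d$L[1],
    preload_mean = mean(d$L[d$t < d$protocol$t_load_on])
  )
  if (!is.finite(L0) || L0 <= 0) stop("non-positive baseline diameter", call. = FALSE)
  strain_curve(d$cell_id, d$t, d$L / L0 - 1, baseline_L0 = L0)
}

#' Smooth a time series without shifting phase boundaries
#'
#' Centered smoothing used on raw diameter series before strain computation.
#' A constant series is returned unchanged and `window = 1` is the identity.
#'
#' @param x Numeric series.
#' @param method `"moving_average"` (centered, window shortened at the edges)
#'   or `"loess"` (via [stats::lowess()] with span `window / length(x)`).
#' @param window Window length in frames (odd values recommended).
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(x, method = c("moving_average", "loess"), window = 5) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot_scalar_number(window, "window", lower = 1)
  if (window > n) stop("window larger than series", call. = FALSE)
  if (window == 1) return(x)
  if (method == "moving_average") {
    half <- (window - 1) %/% 2
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      mean(x[lo:hi])
    }, numeric(1))
  } else {
    stats::lowess(seq_len(n), x, f = min(1, window / n))$y
  }
}

#' Bootstrap-averaged population strain curve with confidence band
#'
#' Resamples whole cells with replacement (`n_bootstrap` replicates of the
#' original sample size), takes the pointwise mean curve of each replicate,
#' and summarizes the replicate means: `epsilon_bs` is their pointwise mean,
#' `ci_halfwidth` is twice their pointwise standard deviation (an approximate
#' 95% band), and `epsilon_max` is the maximum of the averaged curve — the
#' rigidity statistic of the assay (stiffer cells stretch less).
#'
#' @param curves List of [strain_curve()] objects sharing one time grid.
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return An object of class `bootstrap_curve` with fields `t`,
#'   `epsilon_bs`, `ci_halfwidth`, `epsilon_max`, `n_cells`, `n_bootstrap`,
#'   `seed`.
#' @export
bootstrap_mean_curve <- function(curves, n_bootstrap = 1000, seed = 1) {
  if (length(curves) < 2) stop("need at least 2 curves", call. = FALSE)
  stopifnot_scalar_number(n_bootstrap, "n_bootstrap", lower = 1)
  t0 <- curves[[1]]$t
  for (cu in curves) {
    if (length(cu$t) != length(t0) || any(cu$t != t0)) {
      stop("all strain curves must share one time grid", call. = FALSE)
    }
  }
  eps <- do.call(rbind, lapply(curves, `[[`, "epsilon"))  # cells x frames
  n <- nrow(eps)
  with_seed(seed, {
    reps <- matrix(0, n_bootstrap, ncol(eps))
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b, ] <- colMeans(eps[idx, , drop = FALSE])
    }
    m <- colMeans(reps)
    s <- apply(reps, 2L, sd)
    structure(
      list(t = t0, epsilon_bs = m, ci_halfwidth = 2 * s,
           epsilon_max = max(m), n_cells = n, n_bootstrap = n_bootstrap,
           seed = seed),
      class = "bootstrap_curve"
    )
  })
}

#' @export
print.bootstrap_curve <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_curve> %d cells, B=%d: eps_max = %.4f (max band halfwidth %.4f)\n",
    x$n_cells, x$n_bootstrap, x$epsilon_max, max(x$ci_halfwidth)))
  invisible(x)
}

#' Compare rigidity of two strain-curve populations
#'
#' Computes the bootstrap-averaged curve of each condition, the percent
#' reduction in maximum strain
#' `100 * (1 - eps_max_treated / eps_max_control)` (positive = treated cells
#' are stiffer), a two-sided Mann–Whitney test on the per-cell maximum
#' strains, and a per-frame flag marking where the two confidence bands do
#' not overlap.
#'
#' @param control,treated Lists of [strain_curve()] objects.
#' @param n_bootstrap Bootstrap replicates per condition.
#' @param seed RNG seed (treated condition uses a derived child seed).
#' @param labels Length-2 character vector of condition labels.
#' @return An object of class `rigidity_comparison`.
#' @export
compare_rigidity <- function(control, treated, n_bootstrap = 1000, seed = 1,
                             labels = c("control", "treated")) {
  if (length(control) < 1 || length(treated) < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  bs_c <- bootstrap_mean_curve(control, n_bootstrap, seed)
  bs_t <- bootstrap_mean_curve(treated, n_bootstrap, derive_seed(seed, 1L))
  max_c <- vapply(control, function(cu) max(cu$epsilon), numeric(1))
  max_t <- vapply(treated, function(cu) max(cu$epsilon), numeric(1))
  mw <- suppressWarnings(
    wilcox.test(max_c, max_t, alternative = "two.sided", exact = FALSE,
                correct = TRUE)
  )
  lo_c <- bs_c$epsilon_bs - bs_c$ci_halfwidth
  hi_c <- bs_c$epsilon_bs + bs_c$ci_halfwidth
  lo_t <- bs_t$epsilon_bs - bs_t$ci_halfwidth
  hi_t <- bs_t$epsilon_bs + bs_t$ci_halfwidth
  structure(
    list(
      label_control = labels[1], label_treated = labels[2],
      curve_control = bs_c, curve_treated = bs_t,
      epsilon_max_control = bs_c$epsilon_max,
      epsilon_max_treated = bs_t$epsilon_max,
      percent_reduction = 100 * (1 - bs_t$epsilon_max / bs_c$epsilon_max),
      mw_p_value = mw$p.value,
      ci_separated = (lo_c > hi_t) | (lo_t > hi_c)
    ),
    class = "rigidity_comparison"
  )
}

#' @export
print.rigidity_comparison <- function(x, ...) {
  cat(sprintf(
    "<rigidity_comparison> %s vs %s\n  eps_max: %.4f vs %.4f -> %.1f%% reduction\n  Mann-Whitney p = %.3g; bands separated at %d/%d frames\n",
    x$label_control, x$label_treated,
    x$epsilon_max_control, x$epsilon_max_treated, x$percent_reduction,
    x$mw_p_value, sum(x$ci_separated), length(x$ci_separated)))
  invisible(x)
}
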
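#' Construct a set of 3D nucleus spots
#'
#' @param spots A data.frame with numeric columns `x_um`, `y_um`, `z_um`
#'   (z = 0 at the gel surface, positive = deeper).
#' @param source `"detected"` or `"provided"`.
#' @return An object of class `spot_set`.
#' @export
spot_set <- function(spots, source = c("provided", "detected")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(spots),
            all(c("x_um", "y_um", "z_um") %in% names(spots)))
  if (!all(vapply(spots[c("x_um", "y_um", "z_um")],
                  function(v) all(is.finite(v)), logical(1)))) {
    stop("spot coordinates must be finite", call. = FALSE)
  }
  structure(list(spots = spots, source = source), class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spots (%s), z range [%.1f, %.1f] um\n",
              nrow(x$spots), x$source, min(x$spots$z_um), max(x$spots$z_um)))
  invisible(x)
}

# Separable 3D Gaussian smoothing: one 1D convolution (reflected edges) per
# axis, applied via banded kernel matrices.
gaussian_smooth_3d <- function(stack, sigma_vox) {
  smooth_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    n <- dim(a)[axis]
    r <- max(1L, ceiling(3 * sigma))
    kern <- dnorm(-r:r, sd = sigma)
    kern <- kern / sum(kern)
    K <- matrix(0, n, n)
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      idx <- seq_len(n)
      src <- idx + off
      src <- ifelse(src < 1L, 2L - src, src)          # reflect at the edges
      src <- ifelse(src > n, 2L * n - src, src)
      K[cbind(idx, src)] <- K[cbind(idx, src)] + kern[j]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- K %*% matrix(ap, nrow = d[1])
    dim(m) <- d
    aperm(m, order(perm))
  }
  for (ax in 1:3) stack <- smooth_axis(stack, ax, sigma_vox[ax])
  stack
}

#' Detect nuclei in a 3D intensity stack
#'
#' Gaussian-smooths the stack (kernel width `sigma` in µm per axis), finds
#' voxels that are strict local maxima over their 26-neighborhood and exceed
#' `min_intensity` times the smoothed maximum, and applies greedy
#' non-maximum suppression with radius `2 * sigma` so each nucleus yields
#' one spot. Coordinates are returned in µm; if the stack carries a
#' `z_offset` attribute (µm of slices above the gel surface) it is
#' subtracted so that z = 0 is the surface.
#'
#' @param stack Numeric 3D array (x, y, z order).
#' @param voxel_size µm per voxel along each axis; must be given explicitly
#'   (length 3, or length 1 for isotropic voxels).
#' @param sigma Smoothing / nucleus radius scale in µm.
#' @param min_intensity Detection threshold as a fraction of the maximum
#'   smoothed intensity.
#' @return A `spot_set` with `source = "detected"`.
#' @export
detect_nuclei_3d <- function(stack, voxel_size, sigma = 4, min_intensity = 0.25) {
  if (missing(voxel_size) || is.null(voxel_size)) {
    stop("voxel_size must be given explicitly (anisotropy cannot be guessed)",
         call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (um)", call. = FALSE)
  }
  stopifnot_scalar_number(sigma, "sigma", 0, strict_lower = TRUE)
  if (length(dim(stack)) != 3L) stop("stack must be a 3D array", call. = FALSE)
  z_offset <- attr(stack, "z_offset") %||% 0
  sm <- gaussian_smooth_3d(stack, sigma / voxel_size)
  top <- max(sm)
  if (top <= 0) {
    return(spot_set(data.frame(x_um = numeric(0), y_um = numeric(0),
                               z_um = numeric(0)), source = "detected"))
  }
  d <- dim(sm)
  # strict local maxima over the 26-neighborhood, checked by array shifts
  is_max <- sm >= min_intensity * top
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  pad <- array(-Inf, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sm
  for (s in seq_len(nrow(shifts))) {
    nb <- pad[2:(d[1] + 1) + shifts$dx[s],
              2:(d[2] + 1) + shifts$dy[s],
              2:(d[3] + 1) + shifts$dz[s]]
    is_max <- is_max & (sm >= nb)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(spot_set(data.frame(x_um = numeric(0), y_um = numeric(0),
                               z_um = numeric(0)), source = "detected"))
  }
  vals <- sm[is_max]
  pos <- sweep(idx - 1, 2, voxel_size, `*`)  # µm, voxel origin at 0
  # greedy non-maximum suppression within 2 sigma
  ord <- order(vals, decreasing = TRUE)
  pos <- pos[ord, , drop = FALSE]
  keep <- logical(nrow(pos))
  r2 <- (2 * sigma)^2
  for (i in seq_len(nrow(pos))) {
    if (i == 1L) {
      keep[1] <- TRUE
      next
    }
    kept <- pos[keep, , drop = FALSE]
    d2 <- (kept[, 1] - pos[i, 1])^2 + (kept[, 2] - pos[i, 2])^2 +
      (kept[, 3] - pos[i, 3])^2
    keep[i] <- all(d2 > r2)
  }
  pos <- pos[keep, , drop = FALSE]
  spot_set(
    data.frame(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3] - z_offset),
    source = "detected"
  )
}

#' Estimate the gel surface from a spot z distribution
#'
#' The surface is taken as the mode of the z distribution (surface-seeded
#' cells dominate), estimated from a histogram with `bin_width` µm bins.
#'
#' @param spots A `spot_set`.
#' @param bin_width Histogram bin width in µm.
#' @return Estimated surface z in µm.
#' @export
estimate_gel_surface <- function(spots, bin_width = 5) {
  z <- spots$spots$z_um
  br <- seq(floor(min(z) / bin_width) * bin_width,
            ceiling(max(z) / bin_width) * bin_width + bin_width, by = bin_width)
  h <- hist(z, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Classify spots as invaded by z-threshold
#'
#' A spot is invaded iff its z position is strictly deeper than
#' `z_threshold` below the gel surface.
#'
#' @param spots A `spot_set`.
#' @param z_threshold Threshold depth in µm. The default, 10 µm (about two
#'   nucleus radii), requires a nucleus to have fully entered the gel.
#' @return Logical vector, one flag per spot.
#' @export
classify_invaded <- function(spots, z_threshold = 10) {
  stopifnot(inherits(spots, "spot_set"))
  spots$spots$z_um > z_threshold
}

#' Summarize an invasion assay
#'
#' Counts invaded cells, their percentage and the depth histogram of the
#' invaded subpopulation (fixed-width bins starting at the threshold).
#'
#' @param spots A `spot_set`.
#' @param z_threshold Invasion depth threshold (µm).
#' @param bin_width Histogram bin width (µm), default 20.
#' @return An object of class `invasion_summary` with fields `n_total`,
#'   `n_invaded`, `percent_invaded`, `depths`, `breaks`, `counts`,
#'   `z_threshold`, `bin_width`.
#' @export
invasion_summary <- function(spots, z_threshold = 10, bin_width = 20) {
  stopifnot(inherits(spots, "spot_set"))
  n_total <- nrow(spots$spots)
  if (n_total == 0) stop("no spots to summarize", call. = FALSE)
  inv <- classify_invaded(spots, z_threshold)
  depths <- spots$spots$z_um[inv]
  if (length(depths) > 0) {
    top <- max(depths)
    breaks <- seq(z_threshold,
                  z_threshold + bin_width * ceiling((top - z_threshold) / bin_width + 1e-9),
                  by = bin_width)
    if (length(breaks) < 2) breaks <- c(z_threshold, z_threshold + bin_width)
    counts <- hist(depths, breaks = breaks, plot = FALSE, right = TRUE)$counts
  } else {
    breaks <- c(z_threshold, z_threshold + bin_width)
    counts <- 0L
  }
  structure(
    list(n_total = n_total, n_invaded = sum(inv),
         percent_invaded = 100 * sum(inv) / n_total,
         depths = depths, breaks = breaks, counts = counts,
         z_threshold = z_threshold, bin_width = bin_width),
    class = "invasion_summary"
  )
}

#' @export
print.invasion_summary <- function(x, ...) {
  cat(sprintf("<invasion_summary> %d/%d invaded (%.1f%%) below %g um; mean depth %.1f um\n",
              x$n_invaded, x$n_total, x$percent_invaded, x$z_threshold,
              if (x$n_invaded) mean(x$depths) else NA_real_))
  invisible(x)
}

#' Compare two invasion summaries
#'
#' Two-proportion test (chi-squared with continuity correction) on the
#' invaded counts of two conditions.
#'
#' @param a,b `invasion_summary` objects.
#' @return A list with the two percentages, their difference (b - a) and the
#'   p-value.
#' @export
compare_invasion <- function(a, b) {
  stopifnot(inherits(a, "invasion_summary"), inherits(b, "invasion_summary"))
  tst <- suppressWarnings(
    prop.test(c(a$n_invaded, b$n_invaded), c(a$n_total, b$n_total))
  )
  list(percent_a = a$percent_invaded, percent_b = b$percent_invaded,
       difference = b$percent_invaded - a$percent_invaded,
       p_value = tst$p.value)
}
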
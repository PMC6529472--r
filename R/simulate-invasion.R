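#' Simulate nucleus positions of a collagen-invasion assay
#'
#' Cells are seeded on top of a collagen gel; after the invasion period a
#' fraction has entered the matrix. The generator plants
#' `ceiling(n_cells * invaded_fraction)` invaded cells at depths
#' `z = invasion_front + Exponential(depth_scale)` below the gel surface and
#' leaves the rest at the surface with Gaussian jitter. The invasion front
#' offset (default 10 µm, about one nucleus diameter) encodes that an
#' invaded cell has fully entered the gel; it makes the planted fraction
#' identifiable by z-thresholding at the front. Depth below the front is
#' exponential with mean `depth_scale`. The z convention is 0 at the gel
#' surface, positive downwards.
#'
#' @param n_cells Number of cells.
#' @param invaded_fraction Fraction of cells planted as invaded, in \[0, 1\].
#' @param depth_scale Mean invasion depth below the front, µm.
#' @param surface_jitter_sd SD (µm) of the z jitter of surface cells.
#' @param invasion_front Minimum depth (µm) of an invaded nucleus.
#' @param field_size Side length (µm) of the square x/y field of view.
#' @param min_separation Minimum pairwise 3D distance (µm) between nuclei
#'   (rejection-sampled); keeps rendered nuclei resolvable.
#' @param seed RNG seed.
#' @return A list with `spots` (a `spot_set`: data.frame `x_um, y_um, z_um`
#'   plus metadata) and `truth` (logical `invaded` labels and parameters).
#' @export
simulate_invasion_spots <- function(n_cells, invaded_fraction = 0.3,
                                    depth_scale = 40, surface_jitter_sd = 2,
                                    invasion_front = 10, field_size = 600,
                                    min_separation = 0, seed = 1) {
  stopifnot_scalar_number(n_cells, "n_cells", lower = 1)
  stopifnot_scalar_number(invaded_fraction, "invaded_fraction", 0, 1)
  stopifnot_scalar_number(depth_scale, "depth_scale", 0, strict_lower = TRUE)
  stopifnot_scalar_number(surface_jitter_sd, "surface_jitter_sd", lower = 0)
  with_seed(seed, {
    n_inv <- ceiling(n_cells * invaded_fraction)
    invaded <- c(rep(TRUE, n_inv), rep(FALSE, n_cells - n_inv))
    z <- numeric(n_cells)
    if (n_inv > 0) z[invaded] <- invasion_front + rexp(n_inv, rate = 1 / depth_scale)
    if (n_cells - n_inv > 0 && surface_jitter_sd > 0) {
      z[!invaded] <- rnorm(n_cells - n_inv, 0, surface_jitter_sd)
    }
    xy <- matrix(runif(2 * n_cells, 0, field_size), ncol = 2)
    if (min_separation > 0) {
      pts <- matrix(NA_real_, n_cells, 2)
      placed <- 0L
      attempts <- 0L
      while (placed < n_cells && attempts < 200L * n_cells) {
        cand <- runif(2, 0, field_size)
        attempts <- attempts + 1L
        ok <- TRUE
        if (placed > 0) {
          d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2 +
            (z[seq_len(placed)] - z[placed + 1L])^2
          ok <- all(d2 >= min_separation^2)
        }
        if (ok) {
          placed <- placed + 1L
          pts[placed, ] <- cand
        }
      }
      if (placed < n_cells) {
        stop("could not place all nuclei with the requested separation",
             call. = FALSE)
      }
      xy <- pts
    }
    spots <- spot_set(data.frame(x_um = xy[, 1], y_um = xy[, 2], z_um = z),
                      source = "provided")
    list(
      spots = spots,
      truth = list(invaded = invaded, invaded_fraction = invaded_fraction,
                   depth_scale = depth_scale, invasion_front = invasion_front,
                   surface_jitter_sd = surface_jitter_sd, seed = seed)
    )
  })
}

#' Render a confocal-like 3D nucleus stack from spot positions
#'
#' Each nucleus is painted as an isotropic 3D Gaussian intensity blob
#' (sigma `nucleus_sigma` µm) into a voxel grid. Slice 1 sits
#' `margin_above` µm above the gel surface so surface nuclei are fully
#' contained; the returned stack carries `voxel_size` and `z_offset`
#' attributes (`z_um = (slice - 1) * voxel_z - z_offset`).
#'
#' @param spots A `spot_set` (µm coordinates, z = 0 at gel surface).
#' @param voxel_size Numeric length-3 vector, µm per voxel along x, y, z.
#' @param field_size x/y extent (µm) of the rendered volume.
#' @param depth_below,margin_above z extent (µm) below / above the surface.
#' @param nucleus_sigma Gaussian radius (µm) of a rendered nucleus.
#' @param snr Peak amplitude over noise SD; `Inf` disables noise.
#' @param seed RNG seed for the noise.
#' @return Numeric array `nx x ny x nz`, intensities clipped to \[0, 1\].
#' @export
render_invasion_stack <- function(spots, voxel_size = c(2, 2, 2),
                                  field_size = 600, depth_below = 250,
                                  margin_above = 20, nucleus_sigma = 4,
                                  snr = 10, seed = 1) {
  stopifnot(inherits(spots, "spot_set"), length(voxel_size) == 3)
  df <- spots$spots
  nx <- ceiling(field_size / voxel_size[1])
  ny <- ceiling(field_size / voxel_size[2])
  nz <- ceiling((depth_below + margin_above) / voxel_size[3])
  stack <- array(0, dim = c(nx, ny, nz))
  # paint each blob on a local patch (4 sigma support)
  half <- ceiling(4 * nucleus_sigma / voxel_size)
  for (i in seq_len(nrow(df))) {
    cv <- c(df$x_um[i] / voxel_size[1],
            df$y_um[i] / voxel_size[2],
            (df$z_um[i] + margin_above) / voxel_size[3]) + 1
    lo <- round(cv) - half
    hi <- round(cv) + half
    dims <- c(nx, ny, nz)
    # nuclei outside the rendered volume (e.g. deeper than depth_below) are
    # simply not imaged
    if (any(hi < 1) || any(lo > dims)) next
    ix <- max(1, lo[1]):min(nx, hi[1])
    iy <- max(1, lo[2]):min(ny, hi[2])
    iz <- max(1, lo[3]):min(nz, hi[3])
    gx <- exp(-((ix - cv[1]) * voxel_size[1])^2 / (2 * nucleus_sigma^2))
    gy <- exp(-((iy - cv[2]) * voxel_size[2])^2 / (2 * nucleus_sigma^2))
    gz <- exp(-((iz - cv[3]) * voxel_size[3])^2 / (2 * nucleus_sigma^2))
    blob <- outer(outer(gx, gy), gz)
    stack[ix, iy, iz] <- stack[ix, iy, iz] + blob
  }
  if (is.finite(snr)) {
    with_seed(seed, {
      stack <- stack + rnorm(length(stack), 0, 1 / snr)
    })
  }
  stack <- pmin(pmax(stack, 0), 1)
  dim(stack) <- c(nx, ny, nz)
  attr(stack, "voxel_size") <- voxel_size
  attr(stack, "z_offset") <- margin_above
  stack
}
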
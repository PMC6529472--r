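#' Render an optical-stretcher frame stack from a strain curve
#'
#' Produces a grayscale image stack in which frame k depicts a cell as a
#' filled ellipse whose horizontal (laser-axis) diameter is
#' `base_diameter * (1 + epsilon(t_k))`. Cell area is conserved: the vertical
#' semi-axis shrinks by the same factor the horizontal one grows. Intended as
#' ground-truth input for the contour-extraction stage.
#'
#' @param curve A [strain_curve()].
#' @param base_diameter Unstretched cell diameter in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param image_size Image side length in pixels (square frames).
#' @param noise_sd SD of additive Gaussian intensity noise (intensities are
#'   on \[0, 1\]; foreground 1, background 0 before noise).
#' @param seed RNG seed for the noise.
#' @return A numeric array `image_size x image_size x n_frames` with values
#'   clipped to \[0, 1\]; suitable for [write_frame_stack()].
#' @export
render_stretcher_frames <- function(curve, base_diameter = 15, pixel_size = 0.2,
                                    image_size = 128, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(curve, "strain_curve"))
  stopifnot_scalar_number(base_diameter, "base_diameter", 0, strict_lower = TRUE)
  stopifnot_scalar_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  max_d <- base_diameter * (1 + max(curve$epsilon, 0))
  if (max_d >= image_size * pixel_size) {
    stop("cell touches the image border: enlarge image_size or shrink the cell",
         call. = FALSE)
  }
  n <- length(curve$epsilon)
  cx <- (image_size + 1) / 2
  px <- seq_len(image_size)
  xg <- matrix(px, image_size, image_size, byrow = TRUE) # column index (horizontal)
  yg <- matrix(px, image_size, image_size)               # row index (vertical)
  stack <- array(0, dim = c(image_size, image_size, n))
  with_seed(seed, {
    for (k in seq_len(n)) {
      stretch <- 1 + curve$epsilon[k]
      a <- base_diameter * stretch / 2 / pixel_size   # horizontal semi-axis, px
      b <- base_diameter / stretch / 2 / pixel_size   # area-conserving vertical
      mask <- ((xg - cx) / a)^2 + ((yg - cx) / b)^2 <= 1
      frame <- mask * 1
      if (noise_sd > 0) frame <- frame + rnorm(length(frame), 0, noise_sd)
      stack[, , k] <- pmin(pmax(frame, 0), 1)
    }
  })
  attr(stack, "pixel_size") <- pixel_size
  stack
}

#' Write / read a grayscale frame stack as multi-page TIFF
#'
#' @param stack Numeric array `nx x ny x n_frames` with values in \[0, 1\].
#' @param path Output TIFF path.
#' @return `write_frame_stack` returns `path` invisibly; `read_frame_stack`
#'   returns the array.
#' @export
write_frame_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.list(frames)) {
    simplify2array(frames)
  } else {
    array(frames, dim = c(dim(frames), 1L))
  }
}
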
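#' Simulate persistent-random-walk migration tracks
#'
#' Each cell moves at a constant per-cell speed (drawn lognormal around
#' `mean_speed`) along a heading that undergoes rotational diffusion with
#' directional correlation time `persistence_time`: heading increments are
#' Gaussian with variance `2 * dt / persistence_time`, so the direction
#' autocorrelation decays as `exp(-t / persistence_time)`. Track durations
#' are censored at `min(t_max, Exponential(dropout_hazard))`, emulating
#' cells lost to division, death or leaving the field of view.
#'
#' @param n_cells Number of tracks.
#' @param mean_speed Ensemble mean speed in µm/h.
#' @param persistence_time Directional correlation time in hours
#'   (`Inf` gives straight lines, values near 0 a diffusive walk).
#' @param t_max Experiment duration (h).
#' @param dropout_hazard Rate (1/h) of premature track loss; 0 disables
#'   censoring.
#' @param sampling_interval Time between observations (h).
#' @param speed_cv Coefficient of variation of the per-cell speed
#'   distribution.
#' @param seed RNG seed.
#' @return A list with `tracks` (list of [track()]) and `truth` (per-cell
#'   speeds, durations and the generator parameters).
#' @export
simulate_tracks <- function(n_cells, mean_speed = 20, persistence_time = 2,
                            t_max = 48, dropout_hazard = 0,
                            sampling_interval = 0.5, speed_cv = 0.3, seed = 1) {
  stopifnot_scalar_number(n_cells, "n_cells", lower = 1)
  stopifnot_scalar_number(mean_speed, "mean_speed", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(persistence_time, "persistence_time", lower = 0,
                          strict_lower = TRUE)
  stopifnot_scalar_number(dropout_hazard, "dropout_hazard", lower = 0)
  if (sampling_interval > t_max) stop("sampling_interval > t_max", call. = FALSE)
  with_seed(seed, {
    speeds <- rlnorm_mean_cv(n_cells, mean_speed, speed_cv)
    durations <- if (dropout_hazard > 0) {
      pmin(t_max, rexp(n_cells, rate = dropout_hazard))
    } else rep(t_max, n_cells)
    # every track has at least two observations
    durations <- pmax(durations, sampling_interval)
    tracks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      tt <- seq(0, durations[i], by = sampling_interval)
      n_steps <- length(tt) - 1L
      theta0 <- runif(1, 0, 2 * pi)
      dtheta <- if (is.finite(persistence_time)) {
        rnorm(n_steps, 0, sqrt(2 * sampling_interval / persistence_time))
      } else rep(0, n_steps)
      theta <- theta0 + cumsum(c(0, dtheta))[seq_len(n_steps)]
      step <- speeds[i] * sampling_interval
      x <- cumsum(c(0, step * cos(theta)))
      y <- cumsum(c(0, step * sin(theta)))
      tracks[[i]] <- track(sprintf("cell_%04d", i), tt, x, y)
    }
    list(
      tracks = tracks,
      truth = list(speeds = speeds, durations = durations,
                   mean_speed = mean_speed, persistence_time = persistence_time,
                   t_max = t_max, sampling_interval = sampling_interval,
                   seed = seed)
    )
  })
}
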
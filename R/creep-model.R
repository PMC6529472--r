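#' Stretch protocol of an optical-stretcher measurement
#'
#' Describes the timing of a creep-and-recovery measurement: an unloaded
#' baseline phase, a laser-on creep phase, and a laser-off recovery phase.
#' The default protocol is one second of unloaded monitoring, two seconds of
#' stretching and one second of recovery, captured as 120 frames over 4 s.
#'
#' @param n_frames Number of frames in the recorded series.
#' @param frame_rate Acquisition rate in Hz.
#' @param t_load_on Time (s) at which the stretching laser switches on.
#' @param t_load_off Time (s) at which the laser switches off.
#' @return An object of class `stretch_protocol` with the frame time grid in
#'   `$t` (frame k is acquired at `(k-1)/frame_rate` seconds).
#' @export
stretch_protocol <- function(n_frames = 120, frame_rate = 30,
                             t_load_on = 1, t_load_off = 3) {
  stopifnot_scalar_number(n_frames, "n_frames", lower = 2)
  stopifnot_scalar_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  total <- n_frames / frame_rate
  stopifnot_scalar_number(t_load_on, "t_load_on", lower = 0, strict_lower = TRUE)
  if (!(t_load_on < t_load_off && t_load_off < total)) {
    stop("require 0 < t_load_on < t_load_off < n_frames/frame_rate", call. = FALSE)
  }
  structure(
    list(
      n_frames = as.integer(n_frames),
      frame_rate = frame_rate,
      t_load_on = t_load_on,
      t_load_off = t_load_off,
      total_duration = total,
      t = (seq_len(n_frames) - 1) / frame_rate
    ),
    class = "stretch_protocol"
  )
}

#' Parameters of a viscoelastic creep-and-recovery model
#'
#' Parameterizes the expected single-cell strain response to a stress step.
#' Three model families are available:
#' \describe{
#'   \item{kelvin_voigt}{spring-dashpot in parallel; exponential creep
#'     toward `equilibrium_strain` with retardation time `retardation_time`.}
#'   \item{standard_linear_solid}{Kelvin–Voigt element in series with a
#'     spring; an instantaneous elastic jump (30% of the equilibrium strain)
#'     followed by exponential creep.}
#'   \item{power_law}{soft glassy rheology-style creep,
#'     strain proportional to `(t/tau)^0.3` capped at the equilibrium value.}
#' }
#' Recovery after load release decays exponentially toward
#' `(1 - recovery_fraction)` of the strain reached at switch-off, so
#' `recovery_fraction = 1` is a fully recovering (purely viscoelastic) cell
#' and smaller values leave a plastic residual.
#'
#' @param model_name One of `"kelvin_voigt"`, `"standard_linear_solid"`,
#'   `"power_law"`.
#' @param equilibrium_strain Dimensionless plateau strain of the average cell
#'   (must be positive and below 0.5, the small-strain regime).
#' @param retardation_time Creep retardation time in seconds.
#' @param recovery_fraction Fraction of the switch-off strain that is
#'   recovered at long times, in \[0, 1\].
#' @param cv_between_cells Coefficient of variation of the lognormal
#'   cell-to-cell distribution of equilibrium strain.
#' @param measurement_noise_sd SD of additive Gaussian frame-to-frame strain
#'   noise (dimensionless).
#' @return An object of class `creep_params`.
#' @export
creep_params <- function(model_name = c("kelvin_voigt", "standard_linear_solid",
                                        "power_law"),
                         equilibrium_strain = 0.05,
                         retardation_time = 0.5,
                         recovery_fraction = 0.7,
                         cv_between_cells = 0.4,
                         measurement_noise_sd = 0.005) {
  model_name <- match.arg(model_name)
  stopifnot_scalar_number(equilibrium_strain, "equilibrium_strain",
                          lower = 0, strict_lower = TRUE, upper = 0.5)
  stopifnot_scalar_number(retardation_time, "retardation_time",
                          lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(recovery_fraction, "recovery_fraction", 0, 1)
  stopifnot_scalar_number(cv_between_cells, "cv_between_cells", lower = 0)
  stopifnot_scalar_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  structure(
    list(
      model_name = model_name,
      equilibrium_strain = equilibrium_strain,
      retardation_time = retardation_time,
      recovery_fraction = recovery_fraction,
      cv_between_cells = cv_between_cells,
      measurement_noise_sd = measurement_noise_sd
    ),
    class = "creep_params"
  )
}

# Noise-free expected strain curve for one cell with equilibrium strain
# `eps_eq`, evaluated on the protocol time grid. Piecewise: zero before load,
# model-specific creep during load, exponential decay toward the unrecovered
# residual afterwards.
creep_model_curve <- function(params, protocol, eps_eq = params$equilibrium_strain) {
  t <- protocol$t
  tau <- params$retardation_time
  on <- protocol$t_load_on
  off <- protocol$t_load_off
  eps <- numeric(length(t))

  load_phase <- t >= on & t < off
  tl <- t[load_phase] - on
  eps[load_phase] <- switch(
    params$model_name,
    kelvin_voigt = eps_eq * (1 - exp(-tl / tau)),
    standard_linear_solid = eps_eq * (0.3 + 0.7 * (1 - exp(-tl / tau))),
    power_law = pmin(eps_eq, eps_eq * (tl / tau)^0.3)
  )

  # strain at switch-off (limit from the left)
  toff <- off - on
  eps_off <- switch(
    params$model_name,
    kelvin_voigt = eps_eq * (1 - exp(-toff / tau)),
    standard_linear_solid = eps_eq * (0.3 + 0.7 * (1 - exp(-toff / tau))),
    power_law = pmin(eps_eq, eps_eq * (toff / tau)^0.3)
  )
  residual <- (1 - params$recovery_fraction) * eps_off
  rec_phase <- t >= off
  tr <- t[rec_phase] - off
  eps[rec_phase] <- residual + (eps_off - residual) * exp(-tr / tau)
  eps
}

#' Construct a single-cell strain curve
#'
#' @param cell_id Cell identifier.
#' @param t Frame times in seconds.
#' @param epsilon Dimensionless strain per frame.
#' @param baseline_L0 Baseline diameter in micrometres used to normalize.
#' @return An object of class `strain_curve`.
#' @export
strain_curve <- function(cell_id, t, epsilon, baseline_L0 = NA_real_) {
  stopifnot(length(t) == length(epsilon), !is.unsorted(t, strictly = TRUE))
  if (any(epsilon < -1)) stop("strain below -1 is unphysical", call. = FALSE)
  structure(
    list(cell_id = cell_id, t = as.numeric(t), epsilon = as.numeric(epsilon),
         baseline_L0 = baseline_L0),
    class = "strain_curve"
  )
}

#' @export
print.strain_curve <- function(x, ...) {
  cat(sprintf("<strain_curve> cell %s: %d frames, max strain %.4f\n",
              x$cell_id, length(x$t), max(x$epsilon)))
  invisible(x)
}

#' Simulate a population of creep-and-recovery curves
#'
#' Draws per-cell equilibrium strains from a lognormal distribution with the
#' stated mean and coefficient of variation, evaluates the creep model on the
#' protocol time grid and adds Gaussian measurement noise. An optional
#' treatment effect scales every cell's equilibrium strain down by
#' `percent_reduction` percent, the mechanism by which growth-factor-induced
#' stiffening manifests in these data.
#'
#' @param params A [creep_params()] object.
#' @param protocol A [stretch_protocol()] object.
#' @param n_cells Number of cells to simulate.
#' @param effect Either `NULL` (untreated) or a percent reduction in
#'   \[0, 100) applied multiplicatively to the equilibrium strain.
#' @param seed Mandatory RNG seed.
#' @return A list with `curves` (list of [strain_curve()]), and `truth`
#'   (planted per-cell equilibrium strains, the effect and the parameters).
#' @export
simulate_creep_population <- function(params, protocol, n_cells,
                                      effect = NULL, seed) {
  stopifnot(inherits(params, "creep_params"), inherits(protocol, "stretch_protocol"))
  stopifnot_scalar_number(n_cells, "n_cells", lower = 1)
  scale <- 1
  if (!is.null(effect)) {
    stopifnot_scalar_number(effect, "effect", lower = 0, upper = 100 - 1e-9)
    scale <- 1 - effect / 100
  }
  with_seed(seed, {
    eps_eq <- rlnorm_mean_cv(n_cells, params$equilibrium_strain * scale,
                             params$cv_between_cells)
    curves <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      mu <- creep_model_curve(params, protocol, eps_eq[i])
      noise <- if (params$measurement_noise_sd > 0) {
        rnorm(protocol$n_frames, 0, params$measurement_noise_sd)
      } else 0
      curves[[i]] <- strain_curve(sprintf("cell_%04d", i), protocol$t, mu + noise)
    }
    list(
      curves = curves,
      truth = list(eps_eq = eps_eq, effect_percent = if (is.null(effect)) 0 else effect,
                   params = params, protocol = protocol, seed = seed)
    )
  })
}

#' Population-mean strain curve implied by the creep model
#'
#' Closed-form expectation of the simulated population curve (the lognormal
#' cell-to-cell variability enters linearly, so the expected curve is the
#' model curve at the mean equilibrium strain). Used as the known truth in
#' confidence-band coverage checks.
#'
#' @inheritParams simulate_creep_population
#' @return Numeric vector of expected strain per frame.
#' @export
expected_population_curve <- function(params, protocol, effect = NULL) {
  scale <- if (is.null(effect)) 1 else 1 - effect / 100
  creep_model_curve(params, protocol, params$equilibrium_strain * scale)
}
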
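#' Construct a 2D migration track
#'
#' @param cell_id Identifier.
#' @param t Observation times in hours, strictly increasing, length >= 2.
#' @param x,y Positions in micrometres.
#' @return An object of class `track`.
#' @export
track <- function(cell_id, t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2) stop("a track needs at least 2 points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing", call. = FALSE)
  structure(list(cell_id = cell_id, t = as.numeric(t), x = as.numeric(x),
                 y = as.numeric(y)),
            class = "track")
}

track_path_length <- function(tr) {
  sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
}

#' Migration speed of a track
#'
#' Total traveled distance (sum of consecutive Euclidean steps) divided by
#' the total time over which the cell was tracked.
#'
#' @param tr A [track()].
#' @return Speed in µm/h.
#' @export
track_speed <- function(tr) {
  stopifnot(inherits(tr, "track"))
  dt <- tr$t[length(tr$t)] - tr$t[1]
  if (dt <= 0) stop("zero elapsed time", call. = FALSE)
  track_path_length(tr) / dt
}

#' Penalized directional persistence of a track
#'
#' Net displacement (first to last point) divided by total path length,
#' multiplied by `sqrt(t_tracked / t_max)` so that cells tracked only for a
#' short part of the experiment cannot score as highly persistent. A
#' perfectly straight track observed for the whole experiment scores 1.
#'
#' @param tr A [track()].
#' @param t_max Maximal possible tracking time (hours); defaults to 48 h,
#'   the duration of the time-lapse experiment.
#' @return Dimensionless persistence in \[0, 1\]. A degenerate stationary
#'   track (zero path length) returns 0 with a warning.
#' @export
track_persistence <- function(tr, t_max = 48) {
  stopifnot(inherits(tr, "track"))
  t_tracked <- tr$t[length(tr$t)] - tr$t[1]
  if (t_tracked > t_max + 1e-9) stop("t_tracked exceeds t_max", call. = FALSE)
  path <- track_path_length(tr)
  if (path == 0) {
    warning("stationary track: persistence defined as 0")
    return(0)
  }
  n <- length(tr$t)
  net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
  (net / path) * sqrt(t_tracked / t_max)
}

#' Per-track metric table
#'
#' Computes speed and penalized persistence for every track, excluding
#' tracks shorter than `min_points` observations (excluded cell ids are
#' attached as attribute `"excluded"`).
#'
#' @param tracks List of [track()] objects.
#' @param t_max Maximal possible tracking time in hours.
#' @param min_points Minimum observations for a track to be analyzed.
#' @return A data.frame with columns `cell_id`, `speed`, `persistence`,
#'   `t_tracked`, `t_max`, `n_points`.
#' @export
track_metrics <- function(tracks, t_max = 48, min_points = 3) {
  keep <- vapply(tracks, function(tr) length(tr$t) >= min_points, logical(1))
  excluded <- vapply(tracks[!keep], `[[`, character(1), "cell_id")
  tracks <- tracks[keep]
  out <- data.frame(
    cell_id = vapply(tracks, `[[`, character(1), "cell_id"),
    speed = vapply(tracks, track_speed, numeric(1)),
    persistence = vapply(tracks, function(tr) {
      suppressWarnings(track_persistence(tr, t_max))
    }, numeric(1)),
    t_tracked = vapply(tracks, function(tr) tr$t[length(tr$t)] - tr$t[1], numeric(1)),
    t_max = t_max,
    n_points = vapply(tracks, function(tr) length(tr$t), integer(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}

#' Notched-box summary of a metric sample
#'
#' Quartiles use linear interpolation (R quantile type 7); the notch
#' halfwidth is `1.58 * IQR / sqrt(n)`, an approximate 95% comparison
#' interval for the median. Whiskers follow either the Tukey convention
#' (most extreme points within 1.5 IQR of the box, `"iqr15"`) or the
#' 5th/95th percentiles (`"p5p95"`).
#'
#' @param values Numeric sample (n >= 3).
#' @param whisker_mode `"iqr15"` or `"p5p95"`.
#' @return An object of class `box_summary`.
#' @export
summarize_condition <- function(values, whisker_mode = c("iqr15", "p5p95")) {
  whisker_mode <- match.arg(whisker_mode)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  if (whisker_mode == "iqr15") {
    lo_lim <- q[1] - 1.5 * iqr
    hi_lim <- q[3] + 1.5 * iqr
    wl <- min(values[values >= lo_lim])
    wh <- max(values[values <= hi_lim])
  } else {
    w <- unname(quantile(values, c(0.05, 0.95), type = 7))
    wl <- w[1]
    wh <- w[2]
  }
  structure(
    list(median = q[2], q25 = q[1], q75 = q[3],
         notch_halfwidth = 1.58 * iqr / sqrt(n),
         whisker_low = wl, whisker_high = wh, n = n,
         whisker_mode = whisker_mode),
    class = "box_summary"
  )
}

#' Compare migration metrics between two conditions
#'
#' Two-sided Mann–Whitney test per metric (normal approximation with tie
#' correction) plus medians and effect direction.
#'
#' @param control,treated Metric tables from [track_metrics()].
#' @param metrics Which columns to compare.
#' @return A data.frame with one row per metric: medians, direction of the
#'   treated-vs-control shift and the Mann–Whitney p-value.
#' @export
compare_migration <- function(control, treated,
                              metrics = c("speed", "persistence")) {
  if (nrow(control) < 3 || nrow(treated) < 3) {
    stop("need at least 3 tracks per condition", call. = FALSE)
  }
  rows <- lapply(metrics, function(m) {
    xc <- control[[m]]
    xt <- treated[[m]]
    p <- suppressWarnings(
      wilcox.test(xc, xt, alternative = "two.sided", exact = FALSE)$p.value
    )
    data.frame(
      metric = m,
      median_control = median(xc), median_treated = median(xt),
      direction = ifelse(median(xt) > median(xc), "up",
                         ifelse(median(xt) < median(xc), "down", "none")),
      mw_p_value = p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Time-resolved migration metrics over sliding windows
#'
#' Recomputes speed and persistence inside sliding time windows, mirroring
#' time-resolved treatment-effect plots: each track is clipped to
#' `[start, start + window]` and summarized there (persistence normalized by
#' the window length).
#'
#' @param tracks List of [track()] objects.
#' @param window Window length in hours.
#' @param step Window step in hours.
#' @param t_max Experiment duration in hours.
#' @return A data.frame with columns `window_start`, `window_end`,
#'   `cell_id`, `speed`, `persistence`.
#' @export
migration_timecourse <- function(tracks, window = 12, step = 6, t_max = 48) {
  starts <- seq(0, t_max - window, by = step)
  out <- lapply(starts, function(s) {
    clipped <- lapply(tracks, function(tr) {
      sel <- tr$t >= s & tr$t <= s + window
      if (sum(sel) < 3) return(NULL)
      track(tr$cell_id, tr$t[sel], tr$x[sel], tr$y[sel])
    })
    clipped <- Filter(Negate(is.null), clipped)
    if (length(clipped) == 0) return(NULL)
    data.frame(
      window_start = s, window_end = s + window,
      cell_id = vapply(clipped, `[[`, character(1), "cell_id"),
      speed = vapply(clipped, track_speed, numeric(1)),
      persistence = vapply(clipped, function(tr) {
        suppressWarnings(track_persistence(tr, t_max = window))
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, Filter(Negate(is.null), out))
}
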
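# Shared fixtures, built in code.

# Flat strain curves at the given levels on a 2-frame grid: the exact
# resampling distribution of their mean is enumerable by hand.
flat_curves <- function(levels, n_frames = 2) {
  t <- seq_len(n_frames) - 1
  lapply(seq_along(levels), function(i) {
    strain_curve(sprintf("flat_%d", i), t, rep(levels[i], n_frames))
  })
}

# Exhaustive enumeration of the bootstrap distribution of the sample mean
# for n flat curves: all n^n equiprobable resamples.
enumerate_bootstrap_mean <- function(levels) {
  n <- length(levels)
  grids <- do.call(expand.grid, rep(list(seq_len(n)), n))
  means <- apply(grids, 1, function(idx) mean(levels[idx]))
  list(mean = mean(means),
       sd = sqrt(mean((means - mean(means))^2)))  # population SD over resamples
}

# Straight-line track of given duration and speed starting at the origin.
straight_track <- function(duration, speed = 10, n_points = 5, id = "s") {
  t <- seq(0, duration, length.out = n_points)
  track(id, t, speed * t, rep(0, n_points))
}

# Brute-force hypergeometric upper tail: sum the exact outcome
# probabilities C(K,j) C(N-K,n-j) / C(N,n) over j >= k.
brute_hyper_tail <- function(k, N, K, n) {
  j <- max(0, n - (N - K)):min(K, n)
  p <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  sum(p[j >= k])
}
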
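test_that("strain formula is exact and affine-invariant", {
  pro <- stretch_protocol(n_frames = 4, frame_rate = 1, t_load_on = 1,
                          t_load_off = 3)
  d <- diameter_series("c", pro$t, c(10, 11, 12, 10), pro)
  cu <- compute_strain_curve(d, baseline = "first_frame")
  expect_equal(cu$epsilon, c(0, 0.1, 0.2, 0))
  expect_equal(cu$baseline_L0, 10)
  # constant series gives identically zero strain
  dflat <- diameter_series("c", pro$t, rep(12, 4), pro)
  expect_equal(compute_strain_curve(dflat, "first_frame")$epsilon, rep(0, 4))
  # scaling all diameters leaves the strain unchanged
  d2 <- diameter_series("c", pro$t, 3.7 * c(10, 11, 12, 10), pro)
  expect_equal(compute_strain_curve(d2, "first_frame")$epsilon, cu$epsilon)
})

test_that("preload-mean baseline reduces preload strain scatter", {
  pro <- stretch_protocol()
  prm <- creep_params(cv_between_cells = 0, measurement_noise_sd = 0.01)
  withr::with_seed(42, {
    pre_first <- pre_mean <- numeric(100)
    for (i in 1:100) {
      mu <- mechpheno::expected_population_curve(prm, pro)
      L <- 15 * (1 + mu + rnorm(pro$n_frames, 0, 0.01))
      d <- diameter_series("c", pro$t, L, pro)
      pre <- pro$t < pro$t_load_on
      pre_first[i] <- mean(compute_strain_curve(d, "first_frame")$epsilon[pre])
      pre_mean[i] <- mean(compute_strain_curve(d, "preload_mean")$epsilon[pre])
    }
    expect_lt(mean(abs(pre_mean)), mean(abs(pre_first)))
  })
})

test_that("smoothing preserves constants, is the identity at window 1, and denoises", {
  x <- rep(3.2, 50)
  expect_equal(smooth_series(x, "moving_average", 5), x)
  y <- sin(seq(0, 4 * pi, length.out = 100))
  expect_equal(smooth_series(y, window = 1), y)
  withr::with_seed(1, {
    noisy <- y + rnorm(100, 0, 0.2)
    sm <- smooth_series(noisy, "moving_average", 5)
    expect_lt(sd(sm - y), sd(noisy - y))
    lo <- smooth_series(noisy, "loess", 15)
    expect_lt(sd(lo - y), sd(noisy - y))
  })
  expect_error(smooth_series(1:5, window = 9), "window")
})

test_that("bootstrap matches the exhaustive enumeration oracle at n = 2 and n = 3", {
  # n = 2: four equiprobable resamples of flat curves at 0 and 0.1
  oracle2 <- enumerate_bootstrap_mean(c(0, 0.1))
  expect_equal(oracle2$mean, 0.05)
  expect_equal(oracle2$sd, 0.03536, tolerance = 1e-3)
  bs <- bootstrap_mean_curve(flat_curves(c(0, 0.1)), n_bootstrap = 100000,
                             seed = 11)
  mc_err <- 4 * oracle2$sd / sqrt(100000)
  expect_lt(abs(bs$epsilon_bs[1] - oracle2$mean), mc_err)
  expect_equal(bs$ci_halfwidth[1], 2 * oracle2$sd, tolerance = 0.02)
  expect_equal(bs$epsilon_max, bs$epsilon_bs[1])

  # n = 3: 27 equiprobable resamples
  lv <- c(0, 0.1, 0.25)
  oracle3 <- enumerate_bootstrap_mean(lv)
  bs3 <- bootstrap_mean_curve(flat_curves(lv), n_bootstrap = 100000, seed = 12)
  expect_lt(abs(bs3$epsilon_bs[1] - oracle3$mean), 4 * oracle3$sd / sqrt(100000))
  expect_equal(bs3$ci_halfwidth[1], 2 * oracle3$sd, tolerance = 0.02)
})

test_that("degenerate and invalid bootstrap inputs are handled", {
  same <- flat_curves(c(0.07, 0.07, 0.07))
  bs <- bootstrap_mean_curve(same, 200, seed = 1)
  expect_equal(bs$epsilon_bs, rep(0.07, 2))
  expect_equal(bs$ci_halfwidth, rep(0, 2))
  expect_error(bootstrap_mean_curve(same[1], 10, seed = 1), "at least 2")
  mixed <- c(same[1:2], list(strain_curve("x", c(0, 2), c(0, 0))))
  expect_error(bootstrap_mean_curve(mixed, 10, seed = 1), "time grid")
  expect_identical(bootstrap_mean_curve(same, 100, seed = 5),
                   bootstrap_mean_curve(same, 100, seed = 5))
})

test_that("epsilon_max is invariant under cell ordering and sample duplication", {
  prm <- creep_params()
  pro <- stretch_protocol()
  curves <- simulate_creep_population(prm, pro, 40, seed = 31)$curves
  bs <- bootstrap_mean_curve(curves, 500, seed = 1)
  bs_rev <- bootstrap_mean_curve(rev(curves), 500, seed = 2)
  expect_equal(bs_rev$epsilon_max, bs$epsilon_max, tolerance = 0.02)
  bs_dup <- bootstrap_mean_curve(c(curves, curves), 500, seed = 3)
  expect_equal(bs_dup$epsilon_max, bs$epsilon_max, tolerance = 0.02)
})

test_that("confidence bands shrink like 1/sqrt(n) on homogeneous populations", {
  prm <- creep_params(cv_between_cells = 0.3, measurement_noise_sd = 0.003)
  pro <- stretch_protocol()
  widths <- sapply(c(50, 200, 800), function(n) {
    curves <- simulate_creep_population(prm, pro, n, seed = n)$curves
    mean(bootstrap_mean_curve(curves, 400, seed = 1)$ci_halfwidth)
  })
  # each 4x increase in n should halve the band, up to Monte-Carlo slack
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("rigidity comparison recovers identity and the definition arithmetic", {
  prm <- creep_params()
  pro <- stretch_protocol()
  curves <- simulate_creep_population(prm, pro, 60, seed = 41)$curves
  same <- compare_rigidity(curves, curves, n_bootstrap = 400, seed = 1)
  expect_lt(abs(same$percent_reduction), 3)
  expect_gt(same$mw_p_value, 0.9)
  # the percent-reduction definition itself
  expect_equal(100 * (1 - 0.066 / 0.10), 34, tolerance = 1e-9)
})

test_that("diameter extraction from rendered stacks round-trips the strain", {
  pro <- stretch_protocol(n_frames = 12, frame_rate = 3, t_load_on = 1,
                          t_load_off = 3)
  prm <- creep_params(equilibrium_strain = 0.15, cv_between_cells = 0,
                      measurement_noise_sd = 0)
  cu <- simulate_creep_population(prm, pro, 1, seed = 1)$curves[[1]]
  stack <- render_stretcher_frames(cu, base_diameter = 12, pixel_size = 0.15,
                                   image_size = 128, noise_sd = 0.05, seed = 2)
  d <- extract_diameter_series(stack, pro, pixel_size = 0.15)
  # constant-diameter preload frames: L ~ 12 um within one pixel
  expect_equal(d$L[1], 12, tolerance = 2 * 0.15)
  est <- compute_strain_curve(d, baseline = "preload_mean")
  pix_strain <- 2 * 0.15 / 12     # two-pixel-equivalent strain tolerance
  expect_lt(sqrt(mean((est$epsilon - cu$epsilon)^2)), pix_strain)
  # blank stack fails loudly at the first frame
  blank <- array(0, dim = c(32, 32, pro$n_frames))
  expect_error(extract_diameter_series(blank, pro, pixel_size = 0.15),
               "frame 1")
})

test_that("frame stacks survive a TIFF round trip", {
  pro <- stretch_protocol(n_frames = 4, frame_rate = 1, t_load_on = 1,
                          t_load_off = 3)
  cu <- strain_curve("c", pro$t, c(0, 0.1, 0.1, 0))
  stack <- render_stretcher_frames(cu, base_diameter = 8, pixel_size = 0.5,
                                   image_size = 48, noise_sd = 0, seed = 1)
  path <- tempfile(fileext = ".tif")
  write_frame_stack(stack, path)
  back <- read_frame_stack(path)
  expect_equal(dim(back), dim(stack))
  expect_equal(as.vector(back), as.vector(stack), tolerance = 1 / 255)
})
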
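test_that("speed and persistence closed forms hold", {
  # 3-4-5 triangle: 50 um in one hour
  tr <- track("a", c(0, 1), c(0, 30), c(0, 40))
  expect_equal(track_speed(tr), 50)
  # stationary cell: zero speed, persistence 0 with a warning
  still <- track("b", c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  expect_equal(track_speed(still), 0)
  expect_warning(p <- track_persistence(still, t_max = 48), "stationary")
  expect_equal(p, 0)
  # straight full-length track scores 1; quarter-length scores 0.5
  expect_equal(track_persistence(straight_track(48), t_max = 48), 1)
  expect_equal(track_persistence(straight_track(12), t_max = 48), 0.5)
  # closed square loop: zero net displacement
  loop <- track("d", 0:4, c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(track_persistence(loop, t_max = 48), 0)
})

test_that("speed and persistence are invariant under rigid motions", {
  withr::with_seed(7, {
    t <- seq(0, 10, by = 0.5)
    x <- cumsum(rnorm(length(t)))
    y <- cumsum(rnorm(length(t)))
    tr <- track("a", t, x, y)
    th <- 0.83
    rot <- track("a", t, cos(th) * x - sin(th) * y + 12,
                 sin(th) * x + cos(th) * y - 5)
    expect_equal(track_speed(rot), track_speed(tr))
    expect_equal(track_persistence(rot, 48), track_persistence(tr, 48))
    shifted <- track("a", t + 7, x, y)   # time origin shift
    expect_equal(track_speed(shifted), track_speed(tr))
  })
})

test_that("persistence never exceeds its time penalty bound", {
  sim <- simulate_tracks(50, mean_speed = 30, persistence_time = 1,
                         t_max = 24, dropout_hazard = 0.1, seed = 3)
  m <- track_metrics(sim$tracks, t_max = 24)
  expect_true(all(m$persistence <= sqrt(m$t_tracked / m$t_max) + 1e-12))
  expect_true(all(m$speed >= 0))
})

test_that("generator limits: straight lines, diffusive scaling, step lengths", {
  # infinite persistence, no dropout: perfectly straight tracks
  sim <- simulate_tracks(5, mean_speed = 20, persistence_time = Inf,
                         t_max = 12, seed = 1)
  for (tr in sim$tracks) {
    expect_equal(track_persistence(tr, t_max = 12), 1, tolerance = 1e-9)
  }
  # vanishing persistence: mean-squared displacement grows ~ linearly in t
  sim2 <- simulate_tracks(400, mean_speed = 60, persistence_time = 0.01,
                          t_max = 12, sampling_interval = 0.5, seed = 6)
  lags <- 1:20
  msd <- sapply(lags, function(k) {
    mean(sapply(sim2$tracks, function(tr) {
      (tr$x[1 + k] - tr$x[1])^2 + (tr$y[1 + k] - tr$y[1])^2
    }))
  })
  expo <- unname(coef(lm(log(msd) ~ log(lags * 0.5)))[2])
  expect_gt(expo, 0.9)
  expect_lt(expo, 1.1)
  # step lengths average speed * interval
  sim3 <- simulate_tracks(200, mean_speed = 60, persistence_time = 2,
                          t_max = 12, sampling_interval = 0.5, seed = 5)
  steps <- unlist(lapply(sim3$tracks, function(tr) {
    sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  }))
  expect_equal(mean(steps), 30, tolerance = 0.05 * 30)
})

test_that("median persistence increases with the generator's persistence time", {
  meds <- sapply(c(0.25, 1, 4, 16), function(P) {
    sim <- simulate_tracks(150, mean_speed = 30, persistence_time = P,
                           t_max = 24, seed = round(100 * P))
    median(track_metrics(sim$tracks, t_max = 24)$persistence)
  })
  expect_true(all(diff(meds) > 0))
})

test_that("box summaries follow the stated quartile and notch conventions", {
  s <- summarize_condition(1:9, "iqr15")
  expect_equal(s$median, 5)
  expect_equal(s$q25, 3)
  expect_equal(s$q75, 7)
  expect_equal(s$notch_halfwidth, 1.58 * 4 / 3)
  expect_equal(c(s$whisker_low, s$whisker_high), c(1, 9))
  s2 <- summarize_condition(1:100, "p5p95")
  expect_equal(c(s2$whisker_low, s2$whisker_high), c(5.95, 95.05))
  s3 <- summarize_condition(rep(4.2, 10))
  expect_equal(s3$notch_halfwidth, 0)
  expect_equal(s3$whisker_low, 4.2)
  expect_equal(s3$whisker_high, 4.2)
  expect_error(summarize_condition(c(1, 2)), "at least 3")
})

test_that("migration comparison: identity, separation and planted power", {
  sim <- simulate_tracks(50, mean_speed = 20, persistence_time = 2,
                         t_max = 24, seed = 9)
  m <- track_metrics(sim$tracks, t_max = 24)
  same <- compare_migration(m, m)
  expect_true(all(same$mw_p_value > 0.9))
  # disjoint supports at n = 20: far beyond the 0.001 level
  a <- m[1:20, ]
  b <- a
  b$speed <- b$speed + 1000
  b$persistence <- pmin(1, b$persistence + 0.99)
  cmp <- compare_migration(a, b)
  expect_true(all(cmp$mw_p_value < 0.001))
  expect_equal(cmp$direction, c("up", "up"))
  # planted 1.5x speed shift at n = 300 is detected at p < 0.001
  hits <- sapply(1:10, function(s) {
    c0 <- simulate_tracks(300, mean_speed = 20, persistence_time = 2,
                          t_max = 24, seed = 1000 + s)
    c1 <- simulate_tracks(300, mean_speed = 30, persistence_time = 2,
                          t_max = 24, seed = 2000 + s)
    p <- compare_migration(track_metrics(c0$tracks, 24),
                           track_metrics(c1$tracks, 24))
    p$mw_p_value[p$metric == "speed"] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("short tracks are excluded and logged; windows recompute metrics", {
  sim <- simulate_tracks(20, mean_speed = 20, persistence_time = 2,
                         t_max = 24, seed = 2)
  tracks <- c(sim$tracks, list(track("tiny", c(0, 0.5), c(0, 1), c(0, 0))))
  m <- track_metrics(tracks, t_max = 24, min_points = 3)
  expect_equal(nrow(m), 20)
  expect_equal(attr(m, "excluded"), "tiny")
  tc <- migration_timecourse(sim$tracks, window = 12, step = 6, t_max = 24)
  expect_setequal(unique(tc$window_start), c(0, 6, 12))
  expect_true(all(tc$persistence <= 1 + 1e-9))
})

test_that("track TSV round trip and tolerant tracking-export parsing", {
  sim <- simulate_tracks(5, mean_speed = 20, persistence_time = 2,
                         t_max = 6, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_tracks_tsv(sim$tracks, path)
  back <- read_tracks_tsv(path)
  expect_equal(length(back), 5)
  orig <- sim$tracks[[3]]
  got <- back[[orig$cell_id]]
  expect_equal(got$x, orig$x)
  expect_equal(got$t, orig$t)
  # ImageJ MTrack2-style header with frame numbers
  mt <- data.frame(Nr = c(1, 1, 1, 2, 2, 2), Frame = c(1, 2, 3, 1, 2, 3),
                   X = c(0, 3, 6, 1, 1, 1), Y = c(0, 4, 8, 2, 3, 4))
  p2 <- tempfile(fileext = ".txt")
  write.table(mt, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_tracks_tsv(p2, frame_interval_h = 0.5)
  expect_equal(length(parsed), 2)
  expect_equal(parsed[["1"]]$t, c(0, 0.5, 1))
  expect_equal(track_speed(parsed[["1"]]), 10)
})
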
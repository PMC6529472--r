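test_that("fold changes: constants, doubling, replicate means, missing t0", {
  tps <- c(0, 0, 0, 24, 24, 24, 48, 48, 48)
  m <- rbind(
    const = rep(8, 9),
    doubling = c(8, 8, 8, 9, 9, 9, 8, 8, 8),
    trip = c(4, 5, 6, 6, 6, 6, 7, 8, 9)
  )
  fc <- fold_change_matrix(expression_matrix(m, tps))
  expect_equal(unname(fc$log2fc["const", ]), c(0, 0, 0))
  expect_equal(unname(fc$log2fc["doubling", "t24"]), 1)
  expect_equal(unname(fc$log2fc["trip", "t48"]), 3)      # means 5 and 8
  expect_true(all(fc$log2fc[, 1] == 0))
  # a gene with all-NA t = 0 aborts with its name
  m2 <- m
  m2["trip", 1:3] <- NA
  expect_error(fold_change_matrix(expression_matrix(m2, tps)), "trip")
  # a missing later timepoint is linearly interpolated and flagged
  m3 <- m
  m3["doubling", 4:6] <- NA
  fc3 <- fold_change_matrix(expression_matrix(m3, tps))
  expect_true(fc3$interpolated["doubling", "t24"])
  expect_equal(unname(fc3$log2fc["doubling", "t24"]), 0)  # midpoint of 0 and 0
})

test_that("GP smoothing: constants, interpolation of clean trends, shrinkage", {
  tps <- c(0, 0.5, 1, 2, 4, 6, 8, 12, 18, 24, 48)
  flat <- matrix(rep(c(0, rep(0.7, 10)), 2), nrow = 2, byrow = TRUE)
  flat[2, ] <- 0.7    # truly constant series
  rownames(flat) <- c("step", "const")
  fcs <- structure(list(timepoints = tps, log2fc = flat, interpolated = flat * FALSE,
                        smoothed = NULL), class = "fold_change_set")
  sm <- gp_smooth_timecourse(fcs)
  expect_equal(unname(sm$smoothed["const", ]), rep(0.7, 11))

  # noise-free linear trend with a tiny noise floor is interpolated closely
  lin <- matrix(tps / 24, nrow = 1, dimnames = list("lin", NULL))
  fcl <- structure(list(timepoints = tps, log2fc = lin, interpolated = lin * FALSE,
                        smoothed = NULL), class = "fold_change_set")
  sml <- gp_smooth_timecourse(fcl, noise_floor = 1e-4)
  expect_lt(max(abs(sml$smoothed["lin", ] - lin[1, ])), 1e-3)

  # pure white noise is shrunk in most genes
  withr::with_seed(99, {
    noise <- matrix(rnorm(100 * 11), nrow = 100,
                    dimnames = list(sprintf("g%03d", 1:100), NULL))
    fcn <- structure(list(timepoints = tps, log2fc = noise,
                          interpolated = noise * FALSE, smoothed = NULL),
                     class = "fold_change_set")
    smn <- gp_smooth_timecourse(fcn, noise_floor = 0.05)
    shrunk <- rowMeans(abs(smn$smoothed)) < rowMeans(abs(noise))
    expect_gte(mean(shrunk), 0.95)
  })
})

test_that("DE calling recovers planted genes and honors its definition", {
  sim <- simulate_expression_timecourse(1000, de_fraction = 0.05,
                                        effect_log2fc = 2,
                                        noise_sd_log2 = 0.1, seed = 11)
  fc <- gp_smooth_timecourse(fold_change_matrix(sim$expr))
  de <- call_differential_genes(fc, 1)
  called <- union(de$up, de$down)
  truth <- rownames(sim$expr$values)[sim$truth$is_de]
  recall <- length(intersect(called, truth)) / length(truth)
  precision <- length(intersect(called, truth)) / max(1, length(called))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  fpr <- length(setdiff(called, truth)) / (1000 - length(truth))
  expect_lte(fpr, 0.01)
  # an infinite threshold calls nothing
  de_inf <- call_differential_genes(fc, Inf)
  expect_length(de_inf$up, 0)
  expect_length(de_inf$down, 0)
  # an up-then-down excursion beyond both thresholds lands in both lists
  tps <- fc$timepoints
  wave <- matrix(1.5 * sin(seq(0, 2 * pi, length.out = length(tps))),
                 nrow = 1, dimnames = list("wave", NULL))
  fcw <- structure(list(timepoints = tps, log2fc = wave,
                        interpolated = wave * FALSE, smoothed = wave),
                   class = "fold_change_set")
  dew <- call_differential_genes(fcw, 1)
  expect_equal(dew$up, "wave")
  expect_equal(dew$down, "wave")
})

test_that("expression generator: zero effect, determinism, flat non-DE genes", {
  clean <- simulate_expression_timecourse(50, de_fraction = 0,
                                          noise_sd_log2 = 0, seed = 3)
  fc <- fold_change_matrix(clean$expr)
  expect_true(all(fc$log2fc == 0))
  a <- simulate_expression_timecourse(30, seed = 5)
  b <- simulate_expression_timecourse(30, seed = 5)
  expect_identical(a$expr$values, b$expr$values)
})

test_that("hypergeometric tail matches enumeration, phyper and its invariants", {
  # exact value at the fully-overlapping corner case
  e <- hypergeometric_enrichment(paste0("g", 1:10), paste0("g", 1:10),
                                 paste0("g", 1:20))
  expect_equal(e$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(e$fraction_of_set, 100)

  # brute-force enumeration across a grid of small configurations
  withr::with_seed(1, {
    for (rep in 1:200) {
      N <- sample(2:30, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      mine <- mechpheno:::hypergeom_upper_tail(k, N, K, n)
      brute <- brute_hyper_tail(k, N, K, n)
      expect_equal(mine, brute, tolerance = 1e-12)
      # independent library cross-check
      expect_equal(mine, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })

  # monotone decreasing in k; relabeling invariance; k = 0 gives p = 1
  ps <- sapply(0:10, function(k) mechpheno:::hypergeom_upper_tail(k, 40, 15, 10))
  expect_true(all(diff(ps) <= 1e-15))
  uni <- sprintf("gene%02d", 1:40)
  set <- uni[1:12]
  de <- uni[5:20]
  e1 <- hypergeometric_enrichment(set, de, uni)
  perm <- setNames(sample(uni), uni)
  e2 <- hypergeometric_enrichment(unname(perm[set]), unname(perm[de]),
                                  unname(perm[uni]))
  expect_equal(e1$p_value, e2$p_value)
  disjoint <- hypergeometric_enrichment(uni[1:10], uni[31:40], uni)
  expect_equal(disjoint$p_value, 1, tolerance = 1e-12)
  expect_equal(disjoint$overlap, 0)
  # out-of-universe members are dropped with a warning; empty DE warns, p = 1
  expect_warning(hypergeometric_enrichment(c(uni[1:5], "alien"), de, uni),
                 "outside")
  expect_warning(e0 <- hypergeometric_enrichment(set, character(0), uni),
                 "no differentially expressed")
  expect_equal(e0$p_value, 1)
})

test_that("the printed set fractions follow from the overlap arithmetic", {
  # 812-member curated set with 210 up and 170 down overlaps
  uni <- sprintf("g%05d", 1:20000)
  set <- uni[1:812]
  up <- hypergeometric_enrichment(set, uni[1:210], uni, "up")
  expect_equal(up$fraction_of_set, 100 * 210 / 812)
  expect_equal(round(up$fraction_of_set), 26)
  down <- hypergeometric_enrichment(set, uni[603:772], uni, "down")
  expect_equal(round(down$fraction_of_set), 21)
})

test_that("expression and gene-set files round trip", {
  sim <- simulate_expression_timecourse(20, seed = 13)
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(sim$expr, path)
  back <- read_expression_tsv(path)
  expect_equal(back$timepoints, sim$expr$timepoints)
  expect_equal(back$values, sim$expr$values, tolerance = 1e-8)
  gs <- file.path(tempdir(), "set.txt")
  writeLines(c("my_set", "g1", "g2", "g2", "g3"), gs)
  parsed <- read_gene_set(gs)
  expect_equal(parsed$name, "my_set")
  expect_equal(parsed$members, c("g1", "g2", "g3"))
  # the shipped synthetic curated set is readable
  shipped <- read_gene_set(system.file("extdata",
                                       "synthetic_mechanics_geneset.txt",
                                       package = "mechpheno"))
  expect_gt(length(shipped$members), 10)
})
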
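test_that("mean log-intensity matches constants and the brute-force loop", {
  rg <- default_ranges()$side
  expect_equal(mean_log_intensity(as_pattern(matrix(1, 181, 361)), rg, Io = 1), 0)
  expect_equal(mean_log_intensity(as_pattern(matrix(100, 181, 361)), rg, Io = 1), 2)
  expect_error(mean_log_intensity(as_pattern(matrix(1, 181, 361)), rg, Io = 0),
               "Io")

  set.seed(21)
  I <- matrix(10^stats::runif(181 * 361, -3, 2), 181, 361)
  got <- mean_log_intensity(as_pattern(I), rg, Io = 0.5)
  want <- mean_log_oracle(I, 41:141, 1:360, 0.5)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("contrast stretch spans 0..255, handles degeneracy, is affine-invariant", {
  I <- matrix(2, 181, 361); I[1, 1] <- 7
  s <- contrast_stretch(as_pattern(I))
  expect_setequal(unique(as.vector(unclass(s))), c(0L, 255L))

  s0 <- contrast_stretch(as_pattern(matrix(3, 181, 361)))
  expect_true(all(unclass(s0) == 0L))
  expect_true(attr(s0, "degenerate"))

  set.seed(22)
  I <- matrix(10^stats::runif(181 * 361, -4, 0), 181, 361)
  s1 <- contrast_stretch(as_pattern(I))
  s2 <- contrast_stretch(as_pattern(I^2.5))        # L -> 2.5 L
  s3 <- contrast_stretch(as_pattern(I^1.3 * 100))  # L -> 1.3 L + 2
  expect_identical(as.integer(s1), as.integer(s2))
  expect_identical(as.integer(s1), as.integer(s3))

  # linear ramp in L covers the gray range uniformly within rounding
  # (the two edge bins catch only half-width rounding intervals)
  L <- matrix(seq(-3, 1, length.out = 181 * 361), 181, 361)
  sr <- contrast_stretch(as_pattern(10^L))
  counts <- tabulate(as.vector(unclass(sr)) + 1L, 256)
  expect_true(all(counts > 0))
  expect_lt(max(counts[2:255]) / min(counts[2:255]), 1.2)
})

test_that("co-occurrence counting matches pair arithmetic and the brute-force oracle", {
  side <- default_ranges()$side
  # non-degenerate stretch but constant side range
  I <- matrix(5, 181, 361); I[1, 1] <- 50
  s <- contrast_stretch(as_pattern(I))
  gt <- glcm(s, "theta", side)
  gp <- glcm(s, "phi", side)
  expect_identical(sum(gt), 100L * 360L)  # 101 theta rows, 360 phi cols
  expect_identical(sum(gp), 101L * 359L)
  expect_identical(gt[1, 1], sum(gt))     # all pairs at (0, 0)

  # alternating quantized columns 0/7
  I <- matrix(1, 181, 361)
  I[, seq(1, 361, by = 2)] <- 1e9
  sa <- contrast_stretch(as_pattern(I))
  ga_p <- glcm(sa, "phi", side)
  ga_t <- glcm(sa, "theta", side)
  expect_identical(sum(ga_p[cbind(c(1, 8), c(8, 1))]), sum(ga_p))
  expect_identical(sum(ga_t[cbind(c(1, 8), c(8, 1))]), 0L)
  expect_identical(sum(ga_t[cbind(c(1, 8), c(1, 8))]), sum(ga_t))

  set.seed(23)
  for (rep in 1:20) {
    q <- matrix(sample(0:7, 35, replace = TRUE), 5, 7)
    expect_identical(nucscatter:::glcm_counts(q, "theta"), glcm_oracle(q, "theta"))
    expect_identical(nucscatter:::glcm_counts(q, "phi"), glcm_oracle(q, "phi"))
  }
})

test_that("glcm normalization and Haralick contrast behave per definition", {
  set.seed(24)
  g <- matrix(sample(0:20, 64, replace = TRUE), 8, 8)
  p <- normalize_glcm(g)
  expect_equal(sum(p), 1)
  expect_identical(p == 0, g == 0)
  expect_equal(normalize_glcm(matrix(3L, 8, 8)), matrix(1 / 64, 8, 8))

  pd <- diag(8) / 8
  expect_equal(haralick_contrast(pd), 0)
  px <- matrix(0, 8, 8); px[1, 8] <- 0.5; px[8, 1] <- 0.5
  expect_equal(haralick_contrast(px), 49)

  pr <- matrix(stats::runif(64), 8, 8); pr <- pr / sum(pr)
  expect_equal(haralick_contrast(pr), contrast_oracle(pr), tolerance = 1e-12)
  # translation invariance of contrast under a level shift
  g2 <- matrix(0L, 8, 8); g2[1:6, 1:6] <- g[1:6, 1:6]
  g3 <- matrix(0L, 8, 8); g3[3:8, 3:8] <- g[1:6, 1:6]
  expect_equal(haralick_contrast(normalize_glcm(g2)),
               haralick_contrast(normalize_glcm(g3)))
})

test_that("patterns constant along one direction have zero contrast in it", {
  side <- default_ranges()$side
  I <- matrix(10^seq(0, 3, length.out = 181), 181, 361)  # varies in theta only
  s <- contrast_stretch(as_pattern(I))
  expect_equal(haralick_contrast(normalize_glcm(glcm(s, "phi", side))), 0)
  It <- t(matrix(10^seq(0, 3, length.out = 361), 361, 181))
  st <- contrast_stretch(as_pattern(It))
  expect_equal(haralick_contrast(normalize_glcm(glcm(st, "theta", side))), 0)
})

test_that("feature sets assemble per range and refuse degenerate ratios", {
  pat <- born_far_field(small_model(seed = 6), plane_wave(800, 1.36))
  fs <- feature_set(pat, replicate_id = 0L)
  expect_identical(nrow(fs), 3L)
  expect_setequal(fs$range, c("small_angle", "side", "high_angle"))
  expect_true(all(fs$contrast_theta >= 0 & fs$contrast_phi >= 0))
  expect_equal(fs$contrast_ratio, fs$contrast_phi / fs$contrast_theta)

  expect_error(feature_set(as_pattern(matrix(2, 181, 361))),
               class = "nucscatter_degenerate_pattern")
  # constant along theta: polar contrast zero, ratio undefined
  I <- t(matrix(10^seq(0, 3, length.out = 361), 361, 181))
  expect_error(feature_set(as_pattern(I)),
               class = "nucscatter_degenerate_pattern")
})

test_that("replicate aggregation computes mean and standard error", {
  mk <- function(v) {
    data.frame(range = "side", mean_intensity = v[1], contrast_theta = v[2],
               contrast_phi = v[3], contrast_ratio = v[4], replicate_id = 0L)
  }
  agg <- aggregate_replicates(list(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4))))
  expect_equal(agg$contrast_phi_se, 0)
  agg2 <- aggregate_replicates(list(mk(c(1, 1, 1, 1)), mk(c(3, 2, 5, 9))))
  expect_equal(agg2$mean_intensity_mean, 2)
  x <- c(1.2, 1.7, 2.5)
  agg3 <- aggregate_replicates(lapply(x, function(v) mk(rep(v, 4))))
  expect_equal(agg3$contrast_ratio_mean, mean(x))
  expect_equal(agg3$contrast_ratio_se, stats::sd(x) / sqrt(3))
  agg1 <- aggregate_replicates(list(mk(c(1, 2, 3, 4))))
  expect_true(is.na(agg1$contrast_phi_se))
})
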
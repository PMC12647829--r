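test_that("population sparseness hits its closed-form values", {
  expect_equal(population_sparseness(rbind(rep(3, 5))), 0)
  expect_equal(population_sparseness(rbind(c(7, 0, 0, 0))), 1)
  expect_equal(population_sparseness(rbind(c(1, 0, 0, 1))), 2 / 3)
  # all-zero pattern contributes zero
  expect_equal(population_sparseness(rbind(c(1, 0, 0, 1), c(0, 0, 0, 0))),
               1 / 3)
  set.seed(1)
  m <- matrix(rpois(400, 2), 20, 20)
  s <- population_sparseness(m)
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("total variance is additive and equals the covariance trace", {
  expect_equal(total_variance(matrix(5, 10, 4)), 0)
  x <- cbind(c(1, 3, 5, 3), c(2, 2, 6, 2)) # variances 8/3 and 4
  expect_equal(total_variance(x), var(x[, 1]) + var(x[, 2]))
  set.seed(2)
  m <- matrix(rpois(600, 3), 30, 20)
  lam <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(total_variance(m), sum(lam), tolerance = 1e-10)
})

test_that("population correlation spans its 0-1 extremes and hand case", {
  set.seed(3)
  # rank-one covariance: all neurons scale one latent signal
  z <- rnorm(50)
  rank1 <- outer(z, c(1, 2, 3, 4))
  expect_equal(population_correlation(rank1), 1, tolerance = 1e-8)
  # independent equal-variance limit
  iid <- matrix(rnorm(10000), 1000, 10)
  expect_lt(population_correlation(iid), 0.12)
  # sample covariance exactly diag(4, 1, 0) -> 3/2 * (2/3 - 1/3) = 1/2
  e1 <- c(1, -1, 1, -1) / sqrt(4 / 3)
  e2 <- c(1, 1, -1, -1) / sqrt(4 / 3)
  counts <- cbind(2 * e1, 1 * e2, 0) + 10
  expect_equal(unname(cov(counts)), diag(c(4, 1, 0)), tolerance = 1e-12)
  expect_equal(population_correlation(counts), 0.5, tolerance = 1e-10)
  # degenerate constant matrix
  expect_equal(population_correlation(matrix(2, 5, 4)), 0)
})

test_that("wide matrices use the Gram shortcut consistently", {
  set.seed(4)
  m <- matrix(rpois(25 * 60, 1.5), 25, 60) # more neurons than patterns
  lam <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 1e-10 * max(lam)] <- 0
  r <- sqrt(lam)
  N <- ncol(m)
  direct <- N / (N - 1) * (max(r) / sum(r) - 1 / N)
  expect_equal(population_correlation(m), direct, tolerance = 1e-8)
})

test_that("pattern overlap is the mean pairwise Jaccard index", {
  A <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0))
  expect_equal(pattern_overlap(A), 1)
  B <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(pattern_overlap(B), 0)
  C <- rbind(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)) # {1,2,3} vs {2,3,4}
  expect_equal(pattern_overlap(C), 0.5)
  expect_equal(pattern_overlap(C, method = "min"), 2 / 3)
  # empty-vs-empty pairs count as identical
  expect_equal(pattern_overlap(rbind(c(0, 0), c(0, 0))), 1)
})

test_that("metric-accuracy correlations behave on constructed series", {
  df <- data.frame(m = 1:8, acc = 1:8)
  expect_equal(metric_accuracy_correlation(df)["m", "acc"], 1)
  df2 <- data.frame(m = 1:8, acc = 8:1)
  expect_equal(metric_accuracy_correlation(df2, "spearman")["m", "acc"], -1)
  set.seed(5)
  df3 <- data.frame(a = rnorm(500), b = rnorm(500))
  expect_lt(abs(metric_accuracy_correlation(df3)["a", "b"]), 0.15)
  cm <- metric_accuracy_correlation(data.frame(a = rnorm(10), b = rnorm(10),
                                               c = rnorm(10)))
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm, t(cm))
})

test_that("summary statistics and paired tests are calibrated", {
  x <- c(1, 2, 3, 4, 5, 6)
  st <- summary_stats(x)
  expect_equal(st$mean, 3.5)
  expect_equal(st$ci_hi - st$ci_lo,
               2 * qt(0.975, 5) * sd(x) / sqrt(6))
  # identical pairs -> p = 1 by convention
  pt0 <- paired_test(x, x)
  expect_equal(pt0$p, 1)
  expect_equal(pt0$mean_diff, 0)
  # a clean shift is detected
  expect_lt(paired_test(x + 2, x)$p, 1e-6)
  # null calibration: rejection rate ~ alpha
  set.seed(6)
  rej <- mean(vapply(1:4000, function(k) {
    a <- rnorm(8); b <- rnorm(8)
    paired_test(a, b)$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.015)
  # CI coverage of the true mean
  cover <- mean(vapply(1:2000, function(k) {
    s <- summary_stats(rnorm(6, mean = 1))
    s$ci_lo <= 1 && 1 <= s$ci_hi
  }, logical(1)))
  expect_lt(abs(cover - 0.95), 0.02)
})
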
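test_that("item-mean imputation fills with column means and nothing else", {
  m <- cbind(a = c(10, NA, 20), b = c(1, 2, 3))
  mi <- impute_item_means(m)
  expect_equal(mi[2, "a"], c(a = 15))
  expect_equal(mi[, "b"], c(1, 2, 3))
  expect_equal(attr(mi, "n_imputed"), 1)
  # two missing cells in one column both get the observed mean
  m2 <- impute_item_means(cbind(x = c(4, NA, NA, 8)))
  expect_equal(unname(m2[2:3, 1]), c(6, 6))
  # complete matrices pass through unchanged, column means invariant
  full <- matrix(rnorm(20), 5, 4)
  expect_equal(unclass(impute_item_means(full))[, ], full)
  expect_equal(colMeans(impute_item_means(m)), colMeans(m, na.rm = TRUE))
  expect_error(impute_item_means(cbind(c(NA, NA))), "fully missing")
})

test_that("omega on a parallel-item correlation matrix matches the closed form", {
  # six parallel items, loading 0.7: omega = 4.2^2 / (4.2^2 + 6 * 0.51)
  R <- matrix(0.49, 6, 6)
  diag(R) <- 1
  om <- mcdonald_omega(R, is_correlation = TRUE)
  expect_equal(om$omega, 17.64 / 20.70, tolerance = 1e-4)
  expect_equal(om$loadings, rep(0.7, 6), tolerance = 1e-4)
})

test_that("omega approaches 1 for near-perfectly correlated items", {
  R <- matrix(0.999, 5, 5)
  diag(R) <- 1
  expect_gt(mcdonald_omega(R, is_correlation = TRUE)$omega, 0.99)
})

test_that("omega is near 0 for mutually uncorrelated items at large n", {
  set.seed(61)
  x <- matrix(rnorm(5000 * 6), 5000, 6)
  expect_lt(mcdonald_omega(x)$omega, 0.1)
})

test_that("omega from sampled common-factor data recovers the closed form", {
  set.seed(62)
  lambda <- 0.7
  n <- 2000
  f <- rnorm(n)
  x <- sapply(1:6, function(j) lambda * f + sqrt(1 - lambda^2) * rnorm(n))
  expect_equal(mcdonald_omega(x)$omega, 17.64 / 20.70, tolerance = 0.02)
})

test_that("omega is monotone in common-factor strength", {
  oms <- sapply(c(0.3, 0.5, 0.7, 0.9), function(l) {
    R <- matrix(l^2, 6, 6)
    diag(R) <- 1
    mcdonald_omega(R, is_correlation = TRUE)$omega
  })
  expect_true(all(diff(oms) > 0))
})

test_that("omega works on dichotomous correct/incorrect matrices", {
  set.seed(63)
  ability <- rnorm(400)
  x <- sapply(1:8, function(j) as.numeric(ability + rnorm(400) > 0))
  om <- mcdonald_omega(x)
  expect_gt(om$omega, 0.3)
  expect_lt(om$omega, 1)
})

test_that("omega input contracts are enforced", {
  expect_error(mcdonald_omega(matrix(rnorm(10), 5, 2)), "at least 3 items")
  expect_error(mcdonald_omega(matrix(rnorm(12), 3, 4)), "more participants")
  expect_error(mcdonald_omega(cbind(rnorm(9), NA, rnorm(9))), "missing|impute")
})

test_that("identical sessions give icc = 1 and rho = 1; reversal gives rho = -1", {
  s <- c(10, 12, 15, 19, 23, 30)
  tr <- test_retest(s, s)
  expect_equal(tr$icc, 1)
  expect_equal(tr$spearman_rho, 1)
  expect_equal(test_retest(s, rev(s))$spearman_rho, -1)
  expect_error(test_retest(s, rep(1, 6)), "constant")
  expect_error(test_retest(1:4, 4:1), "at least 5")
})

test_that("icc recovers a generated reliability of 0.8 at n = 2000", {
  set.seed(64)
  n <- 2000
  true_score <- rnorm(n, 0, sqrt(0.8))
  t1 <- true_score + rnorm(n, 0, sqrt(0.2))
  t2 <- true_score + rnorm(n, 0, sqrt(0.2))
  tr <- test_retest(t1, t2)
  expect_equal(tr$icc, 0.8, tolerance = 0.03)
  # consistency variant agrees when there is no session shift
  expect_equal(test_retest(t1, t2, icc_type = "ICC3")$icc, 0.8,
               tolerance = 0.03)
})

test_that("absolute-agreement icc penalises a systematic session shift", {
  set.seed(65)
  t1 <- rnorm(200)
  t2 <- t1 + 2  # perfect rank agreement, large mean shift
  icc2 <- test_retest(t1, t2)$icc
  icc3 <- test_retest(t1, t2, icc_type = "ICC3")$icc
  expect_lt(icc2, 0.5)
  expect_gt(icc3, 0.99)
})

test_that("reliability_report wires the matrix, imputation and retest together", {
  set.seed(66)
  sim <- simulate_cohort(sim_config(seed = 660, n_participants = 24,
                                    jitter_sd_ms = 20, ability_sd = 0.6))
  scores <- suppressWarnings(score_tapping(sim$taps, sim$items))
  rep1 <- reliability_report(scores$items, "correct")
  expect_s3_class(rep1$omega, "tap_omega")
  expect_true(rep1$omega$omega >= -0.05 && rep1$omega$omega <= 1)
  sim2 <- simulate_cohort(sim_config(seed = 661, n_participants = 24,
                                     jitter_sd_ms = 20, ability_sd = 0.6))
  scores2 <- suppressWarnings(score_tapping(sim2$taps, sim2$items))
  rep2 <- reliability_report(scores$items, "tempo_dev_pct",
                             retest_scores = scores2$items)
  expect_s3_class(rep2$retest, "tap_retest")
  expect_true(abs(rep2$retest$icc) <= 1)
  expect_gte(rep2$n_imputed, 0)
})
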
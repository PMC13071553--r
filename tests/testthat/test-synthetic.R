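test_that("AR(1) covariance entries and validity", {
  expect_equal(ar1_covariance(2, 0.8), matrix(c(1, .8, .8, 1), 2))
  expect_equal(ar1_covariance(4, 0), diag(4))
  expect_equal(ar1_covariance(3, 0.5)[1, 3], 0.25)
  expect_gt(min(eigen(ar1_covariance(30, 0.95), only.values = TRUE)$values), 0)
  expect_error(ar1_covariance(3, 1), "rho")
})

test_that("Gaussian panel sampler: determinism, covariance, edge sizes", {
  sig <- ar1_covariance(3, 0.4)
  a <- sample_gaussian_panel(10, sig, seed = 32)
  b <- sample_gaussian_panel(10, sig, seed = 32)
  expect_identical(a, b)
  expect_equal(dim(sample_gaussian_panel(1, sig, seed = 1)), c(1L, 3L))
  x <- sample_gaussian_panel(1e5, sig, seed = 33)
  expect_lt(max(abs(crossprod(x) / 1e5 - sig)), 3 * 3 / sqrt(1e5))
  expect_error(sample_gaussian_panel(5, matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("MAF sampler respects the truncated Beta(1,2)/2 law", {
  q <- sample_mafs(1e5, seed = 34)
  expect_true(all(q >= 0.05 & q <= 0.5))
  # E[max(B/2, 0.05)] by numerical integration of the Beta(1,2) density
  target <- integrate(function(b) pmax(b / 2, 0.05) * dbeta(b, 1, 2), 0, 1)$value
  expect_lt(abs(mean(q) - target), 3 * sd(q) / sqrt(1e5))
})

test_that("genotype transform: cutpoints, monotonicity, expected allele count", {
  # q = 0.3: cutpoints z_{0.8} = 0.8416, z_{0.9} = 1.2816
  expect_equal(genotype_transform(c(0, 1, 2), 0.3), c(0L, 1L, 2L))
  expect_equal(genotype_transform(qnorm(0.8) + c(-1e-9, 1e-9), 0.3), c(0L, 1L))
  w <- sort(rnorm(100))
  expect_true(all(diff(genotype_transform(w, 0.2)) >= 0))
  set.seed(35)
  for (q in c(0.05, 0.2, 0.45)) {
    g <- genotype_transform(rnorm(1e6), q)
    expect_lt(abs(mean(g) - q), 3 * sd(g) / sqrt(1e6))
  }
  expect_error(genotype_transform(0, 0.7), "0.5")
})

test_that("genotype panels are polymorphic with near-target allele frequencies", {
  sig <- ar1_covariance(10, 0.95)
  mafs <- sample_mafs(10, seed = 36)
  g <- sample_genotype_panel(2000, sig, mafs, seed = 37)
  expect_true(all(g %in% 0:2))
  expect_true(all(apply(g, 2, var) > 0))
  emp <- colMeans(g) / 2  # per-allele frequency = E[g]/2 = q/2
  expect_lt(max(abs(emp - mafs / 2)), 4 * sqrt(max(mafs) / 2000))
})

test_that("heritability calibration inverts exactly", {
  R <- ar1_covariance(4, 0.5)
  b <- c(1, 0, 0, 1)
  expect_equal(sigma2_from_h(c(1, 0, 0, 0), diag(4), 0.5), 1)
  expect_equal(sigma2_from_h(c(1, 0, 0, 0), diag(4), 0.05), 19)
  for (h0 in c(0.005, 0.05, 0.5, 0.9)) {
    s2 <- sigma2_from_h(b, R, h0)
    brb <- drop(crossprod(b, R %*% b))
    expect_equal(brb / (s2 + brb), h0, tolerance = 1e-12)
  }
  expect_error(sigma2_from_h(b, R, 1), "in \\(0, 1\\)")
})

test_that("phenotype simulation: standardization, determinism, realized heritability", {
  pan <- make_panel(500, 3, seed = 38)
  y1 <- simulate_phenotype(pan, c(1, 0, 0), 2, seed = 39)
  y2 <- simulate_phenotype(pan, c(1, 0, 0), 2, seed = 39)
  expect_identical(y1, y2)
  expect_equal(mean(y1), 0, tolerance = 1e-12)
  expect_equal(mean(y1^2), 1, tolerance = 1e-12)
  # vanishing noise: y is column 1 itself (already standardized)
  y0 <- simulate_phenotype(pan, c(1, 0, 0), 1e-12, seed = 40)
  expect_equal(y0, pan$x[, 1], tolerance = 1e-4)
  # realized heritability across replicates matches the target
  set.seed(41)
  b <- c(1, 0, 1)
  s2 <- sigma2_from_h(b, pan$corr, 0.2)
  r2 <- replicate(200, {
    y <- simulate_phenotype(pan, b, s2)
    summary(lm(y ~ pan$x - 1))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.2), 3 * sd(r2) / sqrt(200) + 0.01)
})

test_that("selection-conditioned phenotypes satisfy the screening predicate", {
  pan <- make_panel(800, 4, rho = 0.6, seed = 42)
  b <- c(0.2, 0, 0, 0)
  out <- simulate_until_selected(pan, b, 1, screened_index = 1,
                                 threshold_t = 0, seed = 43)
  expect_equal(out$resamples, 1L)
  thr <- 0.004
  out2 <- simulate_until_selected(pan, b, 1, screened_index = 2,
                                  threshold_t = thr, seed = 44)
  bom <- drop(crossprod(pan$x[, 2], out2$y)) / pan$n
  expect_gt(bom^2, thr)
  expect_error(simulate_until_selected(pan, numeric(4), 1, 2, 1, max_resamples = 5),
               "selection too rare")
})

test_that("geometric waiting time matches the analytic selection rate under the null", {
  pan <- make_panel(400, 3, rho = 0.3, seed = 45)
  thr <- (qnorm(0.9) / sqrt(pan$n))^2  # 20% two-sided selection rate under the null
  set.seed(46)
  counts <- replicate(300, simulate_until_selected(pan, numeric(3), 1, 1, thr)$resamples)
  rate <- 1 / mean(counts)
  expect_lt(abs(rate - 0.2), 3 * 0.2 / sqrt(300))
})

test_that("FDP and TDP follow the guarded set formulas", {
  expect_equal(fdp_tdp(c(1, 20), c(1, 20)), c(fdp = 0, tdp = 1))
  expect_equal(fdp_tdp(integer(0), c(1, 20)), c(fdp = 0, tdp = 0))
  expect_equal(fdp_tdp(c(1, 2, 3), 1), c(fdp = 2 / 3, tdp = 1))
  expect_equal(fdp_tdp(c(2, 3), c(1, 20)), c(fdp = 1, tdp = 0))
})

test_that("experiment harness is deterministic and controls the global null", {
  # a single nearly-null effect (h = 0.001): every other variant is null
  cfg2 <- sim_config(p = 5, rho = 0.5, n_o = 800, n_r = 300,
                     causal_set = 1, beta_value = 1, h = 0.001,
                     reps = 40, data_seed = 47)
  r1 <- run_experiment(cfg2, methods = c("naive", "corrected_empirical"))
  r2 <- run_experiment(cfg2, methods = c("naive", "corrected_empirical"))
  expect_equal(r1$methods, r2$methods)
  expect_equal(length(r1$records), 40)
  fdr <- r1$methods$corrected_empirical$fdr
  se <- r1$methods$corrected_empirical$fdr_se
  expect_lte(fdr, 0.05 + 3 * max(se, 0.02))
  df <- as.data.frame(r1)
  expect_equal(nrow(df), 2)
})
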
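test_that("selection statistic equals the squared marginal coefficient", {
  pan <- make_panel(300, 5, rho = 0.7, seed = 21)
  marg <- marginal_stats(rnorm(5) / 20, n_o = 300)
  b <- joint_from_marginal(marg, pan)
  for (j in c(1, 3, 5))
    expect_equal(selection_statistic(b, pan$corr, j), marg$beta_om[j]^2,
                 tolerance = 1e-12)
  expect_equal(selection_statistic(numeric(5), pan$corr, 2), 0)
  expect_error(selection_statistic(b, pan$corr, 9), "out of range")
})

test_that("marginal screening threshold: frozen quantile value and monotonicity", {
  # z_{1 - 0.05/20000} = 4.564799, t = (z / sqrt(n_o))^2
  expect_equal(marginal_screen_threshold(1e4, 20000, 0.05),
               (qnorm(1 - 2.5e-6) / 100)^2, tolerance = 1e-12)
  expect_equal(marginal_screen_threshold(1e4), 2.0837e-3, tolerance = 1e-4)
  expect_equal(marginal_screen_threshold(1e4, m = 1, alpha = 0.5), 0)
  expect_gt(marginal_screen_threshold(1e4, m = 4e4), marginal_screen_threshold(1e4))
  expect_lt(marginal_screen_threshold(4e4), marginal_screen_threshold(1e4))
})

test_that("conditioning decomposition reconstructs beta exactly", {
  # identity covariance, coordinate contrast: c = e1, w zeroes coordinate 1
  b <- c(0.7, -0.2, 0.4)
  d <- conditioning_decomposition(b, diag(3), c(1, 0, 0))
  expect_equal(d$c_vec, c(1, 0, 0))
  expect_equal(d$w, c(0, -0.2, 0.4))
  expect_equal(d$u_obs, 0.7)
  # general covariance: reconstruction identity
  V <- random_psd(4, 22)
  b4 <- rnorm(4)
  for (k in 1:4) {
    eta <- numeric(4); eta[k] <- 1
    d <- conditioning_decomposition(b4, V, eta)
    expect_equal(d$w + d$c_vec * d$u_obs, b4, tolerance = 1e-10)
  }
  expect_error(conditioning_decomposition(b, diag(c(1, 1, 0)), c(0, 0, 1)),
               "non-positive")
})

test_that("truncation regions of the rank-1 quadratic are two rays / full line", {
  # craft a decomposition with a = 1, b = 0: v = c_vec = e1, w = 0
  mk <- function(u, c_vec, w, var_u = 1) {
    structure(list(eta = NULL, c_vec = c_vec, w = w, u_obs = u, var_u = var_u),
              class = "conditioning_decomposition")
  }
  sel <- selection_spec(1, 1, diag(3))   # v = e1, t = 1
  reg <- truncation_region(mk(2, c(1, 0, 0), numeric(3)), sel)
  expect_equal(unclass(reg)[, 1], c(-Inf, 1), ignore_attr = TRUE)
  expect_equal(unclass(reg)[, 2], c(-1, Inf), ignore_attr = TRUE)
  # a = 0, b^2 > t: whole line
  reg2 <- truncation_region(mk(0.3, c(0, 1, 0), c(2, 0, 0)), sel)
  expect_equal(unclass(reg2), matrix(c(-Inf, Inf), 1, 2), ignore_attr = TRUE)
  # a = 0, b^2 < t: impossible selection
  expect_error(truncation_region(mk(0.3, c(0, 1, 0), c(0.5, 0, 0)), sel),
               "inconsistent")
  # observed u outside the region
  expect_error(truncation_region(mk(0.2, c(1, 0, 0), numeric(3)), sel),
               "inconsistent")
  # t -> 0: full line minus a point, any u accepted
  sel0 <- selection_spec(1, 1e-20, diag(3))
  reg3 <- truncation_region(mk(0.2, c(1, 0, 0), numeric(3)), sel0)
  expect_equal(nrow(reg3), 2)
  expect_lt(abs(unclass(reg3)[1, 2]), 1e-9)
})

test_that("truncated-normal CDF agrees with direct numerical integration", {
  full <- structure(matrix(c(-Inf, Inf), 1, 2), class = "truncation_region")
  expect_equal(truncnorm_cdf(1.3, 0, 1, full), pnorm(1.3), tolerance = 1e-12)
  rays <- structure(rbind(c(-Inf, -1), c(1, Inf)), class = "truncation_region")
  expect_equal(truncnorm_cdf(1, 0, 1, rays), 0.5, tolerance = 1e-12)
  expect_equal(truncnorm_cdf(-1, 0, 1, rays), 0.5, tolerance = 1e-12)
  expect_equal(truncnorm_cdf(-50, 0, 1, rays), 0)
  expect_equal(truncnorm_cdf(50, 0, 1, rays), 1)
  cases <- list(c(mu = 0.4, var = 2, u = 1.5),
                c(mu = -1, var = 0.5, u = 1.1),
                c(mu = 3, var = 1, u = 4))
  for (cs in cases) {
    got <- truncnorm_cdf(cs["u"], cs["mu"], cs["var"], rays)
    want <- tn_cdf_numeric(cs["u"], cs["mu"], cs["var"], unclass(rays))
    expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # deep-tail stability: mean far from the region still yields a finite CDF
  far <- truncnorm_cdf(8.2, 0, 1, structure(rbind(c(8, Inf)),
                                            class = "truncation_region"))
  expect_true(far > 0 && far < 1)
  # extreme mean far below a far-right region: log-scale masses keep the
  # ratio finite instead of collapsing to 0/0
  expect_equal(truncnorm_cdf(41, -60, 1, structure(rbind(c(40, Inf)),
                                                   class = "truncation_region")),
               1 - exp(pnorm(101, lower.tail = FALSE, log.p = TRUE) -
                         pnorm(100, lower.tail = FALSE, log.p = TRUE)),
               tolerance = 1e-9)
})

test_that("selection-adjusted p-values: no-truncation reduction and boundary case", {
  full <- structure(matrix(c(-Inf, Inf), 1, 2), class = "truncation_region")
  d <- structure(list(u_obs = 1.7, var_u = 0.49), class = "conditioning_decomposition")
  expect_equal(psat_pvalue(d, full), 2 * pnorm(1.7 / 0.7, lower.tail = FALSE),
               tolerance = 1e-12)
  rays <- structure(rbind(c(-Inf, -1), c(1, Inf)), class = "truncation_region")
  d2 <- structure(list(u_obs = 1, var_u = 1), class = "conditioning_decomposition")
  expect_equal(psat_pvalue(d2, rays), 1)  # inner boundary of a symmetric region
})

test_that("selection probability: closed form vs Monte Carlo", {
  V <- random_psd(3, 23)
  sel <- selection_spec(2, 0.5, ar1_covariance(3, 0.6))
  expect_equal(selection_probability(rnorm(3), V, selection_spec(2, 0, diag(3))), 1)
  # m = 0 symmetry
  s2 <- drop(crossprod(sel$v, V %*% sel$v))
  expect_equal(selection_probability(numeric(3), V, sel),
               2 * pnorm(sqrt(0.5 / s2), lower.tail = FALSE), tolerance = 1e-12)
  set.seed(24)
  beta <- c(0.3, -0.1, 0.2)
  reps <- 2e4
  draws <- matrix(rnorm(3 * reps), reps, 3) %*% chol(V)
  draws <- sweep(draws, 2, beta, "+")
  s_mc <- (draws %*% sel$v)^2 > 0.5
  p_mc <- mean(s_mc)
  p_an <- selection_probability(beta, V, sel)
  expect_lt(abs(p_an - p_mc), 3 * sqrt(p_an * (1 - p_an) / reps))
})

test_that("conditional MLE: degenerate threshold, near-certain selection, bias reduction", {
  V <- 0.01 * random_psd(4, 25)
  R <- ar1_covariance(4, 0.5)
  b <- c(0.5, 0.1, -0.2, 0.3)
  expect_equal(conditional_mle(b, V, selection_spec(1, 0, R)), b)
  # |v'b| >> sqrt(t): penalty gradient vanishes
  sel_easy <- selection_spec(1, 1e-6, R)
  expect_equal(conditional_mle(b, V, sel_easy), b, tolerance = 1e-4)
  expect_error(conditional_mle(numeric(4), V, selection_spec(1, 0.5, R)),
               "not satisfied")
  # active selection: the conditional MLE is less biased than the raw estimate
  set.seed(26)
  beta_true <- c(0.05, 0, 0, 0)
  sel <- selection_spec(1, 0.01, R)   # threshold 0.01 on (v'b)^2
  s_v <- sqrt(drop(crossprod(sel$v, V %*% sel$v)))
  raw <- NULL; mle <- NULL
  ch <- chol(V)
  for (r in 1:500) {
    repeat {
      bh <- beta_true + drop(rnorm(4) %*% ch)
      if (drop(crossprod(sel$v, bh))^2 > 0.01) break
    }
    raw <- rbind(raw, bh)
    mle <- rbind(mle, conditional_mle(bh, V, sel))
  }
  bias_raw <- abs(colMeans(raw) - beta_true)
  bias_mle <- abs(colMeans(mle) - beta_true)
  expect_lt(bias_mle[1], bias_raw[1])
})

test_that("pivot uniformity: selection-adjusted null p-values are uniform", {
  set.seed(27)
  p <- 4
  R <- ar1_covariance(p, 0.6)
  V <- 0.0025 * R  # covariance of beta_hat
  beta_true <- c(0, 0, 0.12, 0)       # signal at 3 drives selection; test eta = e1
  sel <- selection_spec(2, 0.004, R)
  ch <- chol(V)
  eta <- c(1, 0, 0, 0)
  pvals <- replicate(2000, {
    repeat {
      bh <- beta_true + drop(rnorm(p) %*% ch)
      if (drop(crossprod(sel$v, bh))^2 > sel$threshold_t) break
    }
    d <- conditioning_decomposition(bh, V, eta)
    psat_pvalue(d, truncation_region(d, sel))
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("selection-adjusted confidence intervals invert the pivot", {
  full <- structure(matrix(c(-Inf, Inf), 1, 2), class = "truncation_region")
  d <- structure(list(u_obs = 0.8, var_u = 0.04), class = "conditioning_decomposition")
  ci <- psat_ci(d, full, level = 0.95)
  expect_equal(unname(ci), 0.8 + c(-1, 1) * qnorm(0.975) * 0.2, tolerance = 1e-6)
  # endpoints monotone in u_obs under truncation
  rays <- structure(rbind(c(-Inf, -0.1), c(0.1, Inf)), class = "truncation_region")
  mk <- function(u) structure(list(u_obs = u, var_u = 0.04),
                              class = "conditioning_decomposition")
  ci1 <- psat_ci(mk(0.15), rays); ci2 <- psat_ci(mk(0.4), rays)
  expect_true(all(ci2 >= ci1))
  # coverage under active selection
  set.seed(28)
  mu <- 0.05; sd_u <- 0.1; thr <- 0.02  # (u)^2 > 0.02 selection on u itself
  hits <- replicate(400, {
    repeat { u <- rnorm(1, mu, sd_u); if (u^2 > thr) break }
    reg <- structure(rbind(c(-Inf, -sqrt(thr)), c(sqrt(thr), Inf)),
                     class = "truncation_region")
    ci <- psat_ci(structure(list(u_obs = u, var_u = sd_u^2),
                            class = "conditioning_decomposition"), reg)
    ci["lower"] <= mu && mu <= ci["upper"]
  })
  expect_gt(mean(hits), 0.95 - 2 * sqrt(0.05 * 0.95 / 400) - 0.01)
})

test_that("psat_finemap with a zero threshold matches the unadjusted analysis", {
  set.seed(29)
  pan_o <- make_panel(2000, 5, rho = 0.6, seed = 29)
  pan_r <- make_panel(400, 5, rho = 0.6, seed = 30)
  y <- simulate_phenotype(pan_o, c(1, 0, 0, 0, 0), sigma2 = 6, seed = 291)
  marg <- marginal_coefficients(pan_o, y)
  sel0 <- selection_spec(3, 0, pan_r$corr)
  adj <- psat_finemap(marg, pan_r, sel0)
  unadj <- finemap_region(marg, pan_r, method = "corrected_empirical")
  expect_equal(adj$p_values, unadj$p_values, tolerance = 1e-9)
  expect_equal(adj$estimate$beta_tilde, unadj$estimate$beta_mc)
  # refusal when the data were not actually selected
  sel_hi <- selection_spec(3, 1e3, pan_r$corr)
  expect_error(psat_finemap(marg, pan_r, sel_hi), "selection event not satisfied")
})

test_that("variants uncorrelated with the screened variant are barely adjusted", {
  set.seed(31)
  p <- 6
  R <- diag(p)  # no LD: a = v'c_vec ~ 0 for eta != e_screen
  V <- 0.0025 * diag(p)
  bh <- c(0.2, 0.01, -0.03, 0.05, 0, 0.08)
  sel <- selection_spec(1, 0.01, R)
  stopifnot(bh[1]^2 > 0.01)
  for (k in 2:p) {
    eta <- numeric(p); eta[k] <- 1
    d <- conditioning_decomposition(bh, V, eta)
    reg <- truncation_region(d, sel)
    padj <- psat_pvalue(d, reg)
    pun <- 2 * pnorm(abs(bh[k]) / 0.05, lower.tail = FALSE)
    expect_equal(padj, pun, tolerance = 1e-6)
  }
})
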
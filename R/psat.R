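# Selection-adjusted inference after marginal screening.
#
# The screening event is the rank-1 quadratic
#   S(beta_mc, R) = (e*' R beta_mc)^2 > t,
# i.e. the squared marginal coefficient at the screened variant exceeds t.
# Conditioning on selection and on W = (I - c eta') beta_mc leaves the
# tested linear combination u = eta' beta_mc with a truncated normal law
# whose truncation region is a union of at most two rays.

#' Selection specification for a marginally screened region
#'
#' Records the screened variant, the squared-coefficient-scale threshold
#' `t` and the induced direction `v = R e*` such that the selection
#' statistic is `(v' beta_mc)^2`.
#'
#' @param screened_index 1-based index of the screened variant.
#' @param threshold_t Positive threshold on the squared marginal
#'   coefficient (see [marginal_screen_threshold()]).
#' @param corr `p x p` LD correlation matrix (e.g. `ref$corr`).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(screened_index, threshold_t, corr) {
  .check_symmetric(corr, name = "corr")
  p <- nrow(corr)
  if (screened_index < 1 || screened_index > p || screened_index != round(screened_index))
    stop("`screened_index` out of range", call. = FALSE)
  if (threshold_t < 0) stop("`threshold_t` must be nonnegative", call. = FALSE)
  structure(list(screened_index = as.integer(screened_index),
                 threshold_t = threshold_t,
                 v = corr[, screened_index]),
            class = "selection_spec")
}

#' Selection statistic of a region
#'
#' \eqn{S(\hat\beta_{mc}, \hat R_r) = (\e^{*\prime} \hat R_r
#' \hat\beta_{mc})^2}, which equals the squared marginal coefficient at the
#' screened index because \eqn{\hat R_r \hat\beta_{mc} = \hat\beta_{om}}.
#'
#' @param beta_mc Length-`p` joint coefficient vector.
#' @param corr `p x p` LD correlation matrix.
#' @param screened_index 1-based screened variant index.
#' @return Nonnegative scalar.
#' @export
selection_statistic <- function(beta_mc, corr, screened_index) {
  .check_symmetric(corr, name = "corr")
  p <- nrow(corr)
  if (screened_index < 1 || screened_index > p)
    stop("`screened_index` out of range", call. = FALSE)
  drop(corr[screened_index, ] %*% beta_mc)^2
}

#' Marginal screening threshold
#'
#' Squared-coefficient-scale threshold for selecting a region by the
#' marginal coefficient of one variant, calibrated as a Bonferroni-corrected
#' genome-wide test assuming no signal and no LD:
#' \eqn{t = (z_{1-\alpha/m} / \sqrt{n_o})^2}, so that selection corresponds
#' to \eqn{|\hat\beta_{om}| \sqrt{n_o} > z_{1-\alpha/m}}.
#'
#' @param n_o Original-study sample size.
#' @param m Number of genome-wide marginal tests (default 20000).
#' @param alpha Genome-wide level (default 0.05).
#' @return Positive scalar threshold `t`.
#' @examples
#' marginal_screen_threshold(1e4)  # ~2.08e-3
#' @export
marginal_screen_threshold <- function(n_o, m = 20000, alpha = 0.05) {
  if (m < 1 || alpha <= 0 || alpha >= 1) stop("invalid `m` or `alpha`", call. = FALSE)
  (stats::qnorm(1 - alpha / m) / sqrt(n_o))^2
}

#' Conditioning decomposition for a linear contrast
#'
#' Splits \eqn{\hat\beta_{mc}} into the tested scalar
#' \eqn{u = \eta'\hat\beta_{mc}} and the conditioning statistic
#' \eqn{W = (I - c\eta')\hat\beta_{mc}} with
#' \eqn{c = \Sigma_{mc}\eta / (\eta'\Sigma_{mc}\eta)}. The reconstruction
#' identity \eqn{W + c\,u = \hat\beta_{mc}} holds exactly.
#'
#' @param beta_mc Length-`p` joint coefficient vector.
#' @param sigma_mc Its `p x p` covariance.
#' @param eta Length-`p` contrast vector (e.g. a coordinate vector).
#' @return An object of class `conditioning_decomposition` with fields
#'   `eta`, `c_vec`, `w`, `u_obs`, `var_u`.
#' @export
conditioning_decomposition <- function(beta_mc, sigma_mc, eta) {
  p <- length(beta_mc)
  if (length(eta) != p || any(dim(sigma_mc) != p))
    stop("dimension mismatch", call. = FALSE)
  var_u <- drop(crossprod(eta, sigma_mc %*% eta))
  if (!is.finite(var_u) || var_u <= 0)
    stop("contrast has non-positive variance under sigma_mc", call. = FALSE)
  c_vec <- drop(sigma_mc %*% eta) / var_u
  u_obs <- drop(crossprod(eta, beta_mc))
  w <- beta_mc - c_vec * u_obs
  structure(list(eta = eta, c_vec = c_vec, w = w, u_obs = u_obs, var_u = var_u),
            class = "conditioning_decomposition")
}

#' Truncation region of the tested scalar given selection
#'
#' Given the decomposition and the rank-1 selection event
#' \eqn{(v'\hat\beta_{mc})^2 > t}, substitute
#' \eqn{\hat\beta_{mc} = W + c\,u} to get \eqn{(b + a u)^2 > t} with
#' \eqn{a = v'c}, \eqn{b = v'W}. The solution set in `u` is two rays
#' (`a != 0`), the whole line (`a = 0`, `b^2 > t`), or empty.
#'
#' @param decomp A `conditioning_decomposition`.
#' @param sel A `selection_spec`.
#' @return An object of class `truncation_region`: a matrix of disjoint
#'   open intervals (columns `lower`, `upper`, rows sorted).
#' @export
truncation_region <- function(decomp, sel) {
  stopifnot(inherits(decomp, "conditioning_decomposition"),
            inherits(sel, "selection_spec"))
  a <- drop(crossprod(sel$v, decomp$c_vec))
  b <- drop(crossprod(sel$v, decomp$w))
  t <- sel$threshold_t
  rt <- sqrt(t)
  tol <- 1e-10
  if (abs(a) < 1e-14 * max(1, abs(b))) {
    if (b^2 > t) {
      iv <- matrix(c(-Inf, Inf), 1, 2)
    } else {
      stop("inconsistent selection: the event cannot occur for any value of the tested contrast",
           call. = FALSE)
    }
  } else {
    u1 <- (-rt - b) / a
    u2 <- ( rt - b) / a
    lo <- min(u1, u2); hi <- max(u1, u2)
    iv <- rbind(c(-Inf, lo), c(hi, Inf))
  }
  # the observed u must itself satisfy selection
  if ((b + a * decomp$u_obs)^2 < t * (1 - 1e-8) - tol)
    stop("inconsistent selection: observed data do not satisfy the selection event",
         call. = FALSE)
  structure(iv, class = "truncation_region", a = a, b = b, threshold_t = t)
}

# log P(lo < Z <= hi) for standard normal, stable in both tails
.log_interval_mass <- function(lo, hi) {
  if (hi <= lo) return(-Inf)
  logdiff <- function(la, lb) {
    if (lb == -Inf) return(la)
    if (la <= lb) return(-Inf)
    la + log1p(-exp(lb - la))
  }
  if (lo >= 0) {
    logdiff(stats::pnorm(lo, lower.tail = FALSE, log.p = TRUE),
            stats::pnorm(hi, lower.tail = FALSE, log.p = TRUE))
  } else if (hi <= 0) {
    logdiff(stats::pnorm(hi, log.p = TRUE), stats::pnorm(lo, log.p = TRUE))
  } else {
    log(stats::pnorm(hi) - stats::pnorm(lo))
  }
}

.logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' CDF of a truncated normal over a union of intervals
#'
#' \eqn{F(u) = P(Z \le u, Z \in A) / P(Z \in A)} for
#' \eqn{Z \sim N(\mu, \mathrm{var})} and truncation region \eqn{A}.
#' Interval masses are computed with log-scale tail probabilities so the
#' ratio stays accurate deep in the tails. `F` is nondecreasing in `u` and
#' decreasing in `mu`, which makes the pivot invertible for confidence
#' intervals.
#'
#' @param u Evaluation point.
#' @param mu Mean of the untruncated normal.
#' @param var Its variance (positive).
#' @param region A `truncation_region`.
#' @return Probability in `[0, 1]`.
#' @export
truncnorm_cdf <- function(u, mu, var, region) {
  stopifnot(inherits(region, "truncation_region"), var > 0)
  sd <- sqrt(var)
  lo <- (region[, 1] - mu) / sd
  hi <- (region[, 2] - mu) / sd
  z  <- (u - mu) / sd
  lmass <- mapply(.log_interval_mass, lo, hi)
  ltot <- .logsumexp(lmass)
  if (ltot == -Inf)
    stop("truncation region has numerically zero mass under N(mu, var); ",
         "the selection event is essentially impossible at this mean -- ",
         "check the threshold and covariance scale", call. = FALSE)
  lpart <- mapply(.log_interval_mass, lo, pmin(hi, z))
  lnum <- .logsumexp(lpart)
  min(1, max(0, exp(lnum - ltot)))
}

#' Selection-adjusted two-sided p-value
#'
#' Evaluates the truncated-normal CDF of the tested contrast at the null
#' mean 0 and returns \eqn{2\min(F_0(u), 1 - F_0(u))}. With no truncation
#' this reduces to the ordinary two-sided normal p-value.
#'
#' @param decomp A `conditioning_decomposition`.
#' @param region The matching `truncation_region`.
#' @return p-value in `[0, 1]`.
#' @export
psat_pvalue <- function(decomp, region) {
  F0 <- truncnorm_cdf(decomp$u_obs, 0, decomp$var_u, region)
  min(1, 2 * min(F0, 1 - F0))
}

# log selection probability and its derivative in m = v'beta,
# with s = sd of v'beta_hat
.log_sel_prob <- function(m, s, t) {
  rt <- sqrt(t)
  a1 <- (rt - m) / s      # upper ray mass: Phi_bar(a1)
  a2 <- (-rt - m) / s     # lower ray mass: Phi(a2)
  l1 <- stats::pnorm(a1, lower.tail = FALSE, log.p = TRUE)
  l2 <- stats::pnorm(a2, log.p = TRUE)
  lp <- .logsumexp(c(l1, l2))
  # dP/dm = (phi(a1) - phi(a2)) / s
  ld1 <- stats::dnorm(a1, log = TRUE)
  ld2 <- stats::dnorm(a2, log = TRUE)
  mx <- max(ld1, ld2)
  dP <- exp(mx) * (exp(ld1 - mx) - exp(ld2 - mx)) / s
  list(logp = lp, dlogp = dP / exp(lp))
}

#' Probability of the selection event
#'
#' For \eqn{\hat\beta_{mc} \sim N(\beta, \Sigma_{mc})} the selection
#' statistic is driven by the scalar \eqn{v'\hat\beta_{mc} \sim N(m, s^2)}
#' with \eqn{m = v'\beta}, \eqn{s^2 = v'\Sigma_{mc}v}, so
#' \deqn{P(S > t) = \bar\Phi\!\left(\frac{\sqrt t - m}{s}\right) +
#'   \Phi\!\left(\frac{-\sqrt t - m}{s}\right).}
#'
#' @param beta Length-`p` mean vector.
#' @param sigma_mc `p x p` covariance.
#' @param sel A `selection_spec`.
#' @return Probability in `(0, 1]`.
#' @export
selection_probability <- function(beta, sigma_mc, sel) {
  stopifnot(inherits(sel, "selection_spec"))
  m <- drop(crossprod(sel$v, beta))
  s2 <- drop(crossprod(sel$v, sigma_mc %*% sel$v))
  if (s2 <= 0) stop("v' sigma_mc v must be positive", call. = FALSE)
  if (sel$threshold_t == 0) return(1)
  exp(.log_sel_prob(m, sqrt(s2), sel$threshold_t)$logp)
}

#' Conditional maximum-likelihood estimate after selection
#'
#' Maximizes the selection-adjusted Gaussian log-likelihood
#' \eqn{\ell(\beta) - \log P_\beta(S > t)} for
#' \eqn{\hat\beta_{mc} \sim N(\beta, \Sigma_{mc})}. Because the penalty
#' depends on \eqn{\beta} only through the scalar \eqn{m = v'\beta}, the
#' stationarity condition collapses to the one-dimensional equation
#' \eqn{m = \hat m - s^2\,\partial_m \log P(m)} with
#' \eqn{\hat m = v'\hat\beta_{mc}}, \eqn{s^2 = v'\Sigma_{mc} v}; the full
#' vector follows as
#' \eqn{\tilde\beta = \hat\beta_{mc} - \partial_m\log P(m^*)\,\Sigma_{mc} v}.
#' The scalar equation is solved by bracketed root finding, which is exact
#' and reliable; at `t = 0` the penalty vanishes and
#' \eqn{\tilde\beta = \hat\beta_{mc}}.
#'
#' @param beta_mc Observed length-`p` joint coefficient vector (must
#'   satisfy the selection event).
#' @param sigma_mc Positive-definite `p x p` covariance.
#' @param sel A `selection_spec`.
#' @return Length-`p` conditional MLE \eqn{\tilde\beta_{mc}}.
#' @export
conditional_mle <- function(beta_mc, sigma_mc, sel) {
  stopifnot(inherits(sel, "selection_spec"))
  t <- sel$threshold_t
  if (t == 0) return(beta_mc)
  v <- sel$v
  m_hat <- drop(crossprod(v, beta_mc))
  s2 <- drop(crossprod(v, sigma_mc %*% v))
  s <- sqrt(s2)
  if (m_hat^2 < t * (1 - 1e-8))
    stop("selection event not satisfied by `beta_mc`", call. = FALSE)
  g <- function(m) .log_sel_prob(m, s, t)$dlogp
  f <- function(m) m - m_hat + s2 * g(m)
  f0 <- f(m_hat)
  if (abs(f0) < 1e-14) {
    m_star <- m_hat
  } else {
    step <- max(s, abs(m_hat) * 0.1, 1e-8)
    lo <- m_hat; hi <- m_hat
    for (k in seq_len(200)) {
      if (f0 > 0) lo <- lo - step else hi <- hi + step
      step <- step * 1.6
      if (f(lo) <= 0 && f(hi) >= 0) break
      if (k == 200)
        stop("conditional MLE did not converge: no bracket found for the score equation ",
             "(m_hat = ", format(m_hat), ", s = ", format(s), ", t = ", format(t), ")",
             call. = FALSE)
    }
    m_star <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  drop(beta_mc - g(m_star) * (sigma_mc %*% v))
}

#' Selection-adjusted confidence interval for a contrast
#'
#' Inverts the truncated-normal pivot: the interval is
#' \eqn{\{\mu : \alpha/2 \le F_\mu(u_{obs}) \le 1 - \alpha/2\}}, found by
#' bracketed root finding in \eqn{\mu} using the monotone decrease of
#' \eqn{F_\mu(u)} in \eqn{\mu}. With no truncation this is the Wald
#' interval \eqn{u_{obs} \pm z_{1-\alpha/2}\sqrt{\mathrm{var}_u}}.
#'
#' @param decomp A `conditioning_decomposition`.
#' @param region The matching `truncation_region`.
#' @param level Coverage in `(0, 1)` (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
psat_ci <- function(decomp, region, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  u <- decomp$u_obs
  sd <- sqrt(decomp$var_u)
  Fmu <- function(mu) truncnorm_cdf(u, mu, decomp$var_u, region)
  solve_mu <- function(target) {
    h <- function(mu) Fmu(mu) - target
    lo <- u - 2 * sd; hi <- u + 2 * sd
    step <- 2 * sd
    for (k in seq_len(200)) {
      if (h(lo) > 0 && h(hi) < 0) break   # F decreasing in mu
      if (h(lo) <= 0) lo <- lo - step
      if (h(hi) >= 0) hi <- hi + step
      step <- step * 1.6
      if (k == 200) stop("confidence bound bracket expansion failed", call. = FALSE)
    }
    stats::uniroot(h, c(lo, hi), tol = 1e-10 * max(1, sd))$root
  }
  c(lower = solve_mu(1 - alpha / 2), upper = solve_mu(alpha / 2))
}

#' Fine-map a region selected by marginal screening
#'
#' Selection-adjusted analogue of [finemap_region()]. The pipeline:
#' reconstruct \eqn{\hat\beta_{mc}} and verify the selection event; build an
#' initial corrected covariance from the unconditional thresholded plug-in;
#' replace the coefficient plug-in by the conditional MLE
#' \eqn{\tilde\beta_{mc}} (which removes the upward selection bias) and
#' refresh \eqn{\hat\sigma^2} and \eqn{\hat\Sigma_{mc}} once with it; then
#' test each variant with the truncated-normal law conditional on the
#' selection event and on \eqn{W}, and apply BH.
#'
#' @param marg A `marginal_stats` object.
#' @param ref A reference `standardized_panel`.
#' @param sel A `selection_spec` (use [marginal_screen_threshold()] for the
#'   screening threshold; `threshold_t = 0` reproduces the unadjusted
#'   analysis).
#' @param method Moment-estimation method, as in [finemap_region()]
#'   (default `"corrected_empirical"`).
#' @param q Nominal BH FDR level.
#' @param threshold_level Plug-in threshold significance level.
#' @return A `region_result`; `estimate$beta_tilde` holds the conditional
#'   MLE and `estimate$selection` the selection spec.
#' @export
psat_finemap <- function(marg, ref, sel,
                         method = c("corrected_empirical", "corrected_gaussian"),
                         q = 0.05, threshold_level = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(marg, "marginal_stats"), inherits(ref, "standardized_panel"),
            inherits(sel, "selection_spec"))
  beta_mc <- joint_from_marginal(marg, ref)
  S <- selection_statistic(beta_mc, ref$corr, sel$screened_index)
  if (S < sel$threshold_t * (1 - 1e-8))
    stop("selection event not satisfied: squared marginal coefficient at the ",
         "screened variant (", format(S), ") is below threshold_t (",
         format(sel$threshold_t), ")", call. = FALSE)
  n_o <- marg$n_o; n_r <- ref$n
  moments <- region_moments(ref, method)
  # initial covariance from the unconditional thresholded plug-in
  s2_init <- residual_variance(beta_mc, ref$corr)
  beta_thr <- threshold_beta(beta_mc, ref, s2_init, n_o, level = threshold_level)
  Smc0 <- sigma_mc(beta_thr, s2_init, ref$corr, moments$v_corr, n_o, n_r)
  # conditional MLE, then one refresh of sigma2 and Sigma_mc
  beta_tilde <- conditional_mle(beta_mc, Smc0, sel)
  s2 <- residual_variance(beta_tilde, ref$corr)
  beta_tilde_thr <- threshold_beta(beta_tilde, ref, s2, n_o, level = threshold_level)
  Smc <- sigma_mc(beta_tilde_thr, s2, ref$corr, moments$v_corr, n_o, n_r)
  p <- ref$p
  pvals <- numeric(p)
  zs <- numeric(p)
  for (i in seq_len(p)) {
    eta <- numeric(p); eta[i] <- 1
    dec <- conditioning_decomposition(beta_mc, Smc, eta)
    reg <- truncation_region(dec, sel)
    pvals[i] <- psat_pvalue(dec, reg)
    zs[i] <- dec$u_obs / sqrt(dec$var_u)
  }
  est <- structure(list(beta_mc = beta_mc, beta_tilde = beta_tilde,
                        beta_threshold = beta_tilde_thr,
                        sigma2_hat = s2, sigma_mc = Smc,
                        method = paste0(method, "_mle"),
                        ratio_c = n_r / n_o, n_o = n_o, n_r = n_r,
                        moments = moments, corr = ref$corr,
                        selection = sel,
                        variant_ids = marg$variant_ids %||% ref$variant_ids),
                   class = "joint_estimate")
  structure(list(estimate = est, z_scores = zs, p_values = pvals,
                 rejected = bh_adjust(pvals, q), fdr_level = q),
            class = "region_result")
}
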
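# Point estimation from summary statistics and a reference panel.

#' Standardize a covariate/genotype panel
#'
#' Centers and scales each column to mean 0 and standard deviation 1 with
#' divisor `n` (not `n - 1`), so that the stored correlation estimate
#' `corr = X'X / n` has an exact unit diagonal.
#'
#' @param x_raw An `n x p` numeric matrix (rows = individuals, columns =
#'   variants or covariates).
#' @param variant_ids Optional character vector of column identifiers;
#'   defaults to existing column names.
#' @return An object of class `standardized_panel` with components `x`,
#'   `n`, `p`, `corr` and `variant_ids`.
#' @examples
#' pan <- standardize_panel(matrix(rnorm(40), 10, 4))
#' colMeans(pan$x)        # ~0
#' diag(pan$corr)         # exactly 1
#' @export
standardize_panel <- function(x_raw, variant_ids = colnames(x_raw)) {
  if (!is.matrix(x_raw) || !is.numeric(x_raw))
    stop("`x_raw` must be a numeric matrix", call. = FALSE)
  n <- nrow(x_raw); p <- ncol(x_raw)
  if (n < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  if (anyNA(x_raw)) stop("`x_raw` contains missing values", call. = FALSE)
  mu <- colMeans(x_raw)
  xc <- sweep(x_raw, 2L, mu)
  sd_n <- sqrt(colMeans(xc^2))
  bad <- which(sd_n <= 0 | !is.finite(sd_n))
  if (length(bad)) {
    lab <- if (!is.null(variant_ids)) variant_ids[bad] else bad
    stop("degenerate (constant) column(s): ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  x <- sweep(xc, 2L, sd_n, "/")
  corr <- crossprod(x) / n
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2
  structure(list(x = x, n = n, p = p, corr = corr,
                 variant_ids = variant_ids),
            class = "standardized_panel")
}

#' @export
print.standardized_panel <- function(x, ...) {
  cat("Standardized panel: n =", x$n, "individuals, p =", x$p, "variants\n")
  invisible(x)
}

#' Marginal association coefficients
#'
#' Per-variant simple-regression coefficients of a standardized phenotype on
#' each standardized column: \eqn{\hat\beta_{om} = X'y / n}.
#'
#' @param panel A `standardized_panel`.
#' @param y Length-`n` phenotype vector, standardized (mean 0, sd 1 with
#'   divisor `n`).
#' @param n_o Original-study sample size attached to the result; defaults
#'   to `panel$n` (the usual case when computing marginals from the study
#'   panel itself).
#' @return An object of class `marginal_stats` with `beta_om`, `n_o` and
#'   `variant_ids`.
#' @export
marginal_coefficients <- function(panel, y, n_o = panel$n) {
  stopifnot(inherits(panel, "standardized_panel"))
  if (length(y) != panel$n)
    stop("length(y) does not match the panel row count", call. = FALSE)
  if (abs(mean(y)) > 1e-6 || abs(sqrt(mean((y - mean(y))^2)) - 1) > 1e-6)
    stop("`y` must be standardized (mean 0, sd 1 with divisor n)", call. = FALSE)
  beta_om <- drop(crossprod(panel$x, y)) / panel$n
  marginal_stats(beta_om, n_o = n_o, variant_ids = panel$variant_ids)
}

#' Construct marginal summary statistics
#'
#' Container for reported per-variant marginal coefficients of a
#' standardized phenotype and the original-study sample size.
#'
#' @param beta_om Numeric vector of marginal coefficients.
#' @param n_o Original-study sample size.
#' @param variant_ids Optional identifiers.
#' @return An object of class `marginal_stats`.
#' @export
marginal_stats <- function(beta_om, n_o, variant_ids = NULL) {
  beta_om <- as.numeric(beta_om)
  if (!all(is.finite(beta_om))) stop("non-finite marginal coefficients", call. = FALSE)
  if (length(n_o) != 1L || n_o < 1) stop("invalid `n_o`", call. = FALSE)
  structure(list(beta_om = beta_om, n_o = as.integer(n_o),
                 variant_ids = variant_ids),
            class = "marginal_stats")
}

#' @export
print.marginal_stats <- function(x, ...) {
  cat("Marginal stats: p =", length(x$beta_om), ", n_o =", x$n_o, "\n")
  invisible(x)
}

# Solve R b = y through a Cholesky factorization with a condition guard;
# returns list(beta, chol, diag_inv) where diag_inv = diag(R^-1).
.solve_corr <- function(corr, rhs, cond_limit = getOption("finemapvc.cond_limit", 1e8)) {
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit)
    stop("singular or ill-conditioned LD matrix (condition number > ",
         format(cond_limit), "); prune highly correlated variants or shrink the region",
         call. = FALSE)
  ch <- chol(corr)
  beta <- backsolve(ch, forwardsolve(t(ch), rhs))
  inv <- chol2inv(ch)
  list(beta = drop(beta), diag_inv = diag(inv), inv = inv)
}

#' Joint coefficients from marginal coefficients
#'
#' Plug-in reconstruction of the multiple-regression coefficients from
#' marginal coefficients and a reference-panel LD matrix:
#' \eqn{\hat\beta_{mc} = \hat R_r^{-1}\hat\beta_{om}}. The linear system is
#' solved by symmetric factorization, never by forming an explicit inverse.
#'
#' @param marg A `marginal_stats` object.
#' @param ref A `standardized_panel` (the reference sample), with
#'   `ref$n > length(beta_om)`.
#' @return Numeric length-`p` vector \eqn{\hat\beta_{mc}}.
#' @export
joint_from_marginal <- function(marg, ref) {
  stopifnot(inherits(marg, "marginal_stats"), inherits(ref, "standardized_panel"))
  if (length(marg$beta_om) != ref$p)
    stop("marginal statistics and reference panel disagree on p", call. = FALSE)
  .solve_corr(ref$corr, marg$beta_om)$beta
}

#' Residual variance of the standardized phenotype
#'
#' \eqn{\hat\sigma^2 = 1 - \hat\beta' \hat R \hat\beta}, clipped to
#' \eqn{[10^{-8}, 1]}. With `conservative = TRUE` returns 1, a valid upper
#' bound for a standardized phenotype (at a cost in power).
#'
#' @param beta Length-`p` coefficient vector (usually \eqn{\hat\beta_{mc}}).
#' @param corr `p x p` LD correlation matrix.
#' @param conservative Logical; return 1 instead of the plug-in estimate.
#' @return A scalar in `(0, 1]`.
#' @export
residual_variance <- function(beta, corr, conservative = FALSE) {
  if (conservative) return(1)
  .check_symmetric(corr, name = "corr")
  s2 <- 1 - drop(crossprod(beta, corr %*% beta))
  min(max(s2, 1e-8), 1)
}

#' Threshold estimator of the coefficient vector
#'
#' Sets to zero every coefficient whose naive-variance test statistic
#' \eqn{T_i^* = \sqrt{n_o}\,\hat\beta_{mc,i} / (\hat\sigma
#' \sqrt{(\hat R_r^{-1})_{ii}})} falls below the two-sided normal critical
#' value at `level`; other entries are kept unchanged. The thresholded
#' vector is the plug-in for \eqn{\beta} inside the corrected covariance;
#' zeros there cut the cost of the correction term.
#'
#' Because \eqn{T_i^*} uses the (liberal) naive variance, any coefficient a
#' variability-corrected test would retain is also retained here. With many
#' truly nonzero coefficients in a region the heuristic can zero some of
#' them; use a more lenient `level` (or skip thresholding) in dense-signal
#' regions.
#'
#' @param beta_mc Length-`p` joint coefficient vector.
#' @param ref The reference `standardized_panel`.
#' @param sigma2 Residual variance estimate.
#' @param n_o Original-study sample size.
#' @param level Two-sided significance level in `(0, 1)` used for the
#'   threshold (default 0.05).
#' @return Numeric vector with sub-threshold entries set to 0.
#' @export
threshold_beta <- function(beta_mc, ref, sigma2, n_o, level = 0.05) {
  stopifnot(inherits(ref, "standardized_panel"))
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  diag_inv <- .solve_corr(ref$corr, beta_mc)$diag_inv
  t_star <- sqrt(n_o) * beta_mc / (sqrt(sigma2) * sqrt(diag_inv))
  crit <- stats::qnorm(1 - level / 2)
  out <- beta_mc
  out[abs(t_star) < crit] <- 0
  out
}
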
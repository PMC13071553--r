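# Independent oracles used across the test files. These re-derive the
# quantities under test by brute force (finite differences, direct
# numerical integration, hand-rolled step-up) and never call the code path
# they check.

# Jacobian of vec(cov -> corr) by central finite differences
fd_corr_jacobian <- function(sigma, eps = 1e-6) {
  p <- nrow(sigma)
  to_corr <- function(s) {
    d <- 1 / sqrt(diag(s))
    s * tcrossprod(d)
  }
  J <- matrix(0, p * p, p * p)
  for (k in seq_len(p * p)) {
    e <- matrix(0, p, p); e[k] <- eps
    J[, k] <- (as.vector(to_corr(sigma + e)) - as.vector(to_corr(sigma - e))) / (2 * eps)
  }
  J
}

# BH step-up rejection by direct implementation of the rule
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# truncated-normal CDF by direct numerical integration of the density
tn_cdf_numeric <- function(u, mu, var, intervals) {
  sd <- sqrt(var)
  mass <- function(lo, hi) {
    lo <- max(lo, mu - 12 * sd); hi <- min(hi, mu + 12 * sd)
    if (hi <= lo) return(0)
    stats::integrate(function(x) stats::dnorm(x, mu, sd), lo, hi,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  tot <- sum(apply(intervals, 1, function(r) mass(r[1], r[2])))
  num <- sum(apply(intervals, 1, function(r) mass(r[1], min(r[2], u))))
  num / tot
}

# random PSD covariance with strictly positive diagonal
random_psd <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  crossprod(a) / (p + 2) + diag(p) * 0.1
}

# small standardized Gaussian panel
make_panel <- function(n, p, rho = 0.5, seed = 1) {
  standardize_panel(sample_gaussian_panel(n, ar1_covariance(p, rho), seed = seed))
}
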
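# Sampling covariance of vectorized covariance / correlation matrices.
# All operators act on vec() in column-major order, so the (i,j) entry of a
# p x p matrix sits at position i + (j-1)*p of its vectorization.

.p_max <- function() getOption("finemapvc.p_max", 150L)

.check_p <- function(p) {
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p < 1 || p != round(p))
    stop("`p` must be a single positive integer", call. = FALSE)
  p <- as.integer(p)
  if (p > .p_max())
    stop("p = ", p, " exceeds the supported region size (", .p_max(),
         "); dense p^2 x p^2 moment matrices scale as O(p^4). ",
         "Split the region or raise options(finemapvc.p_max = ...) at your own risk.",
         call. = FALSE)
  p
}

.check_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !is.numeric(m))
    stop("`", name, "` must be a square numeric matrix", call. = FALSE)
  invisible(m)
}

.check_symmetric <- function(m, tol = 1e-8, name = deparse(substitute(m))) {
  .check_square(m, name)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop("`", name, "` is not symmetric within tolerance", call. = FALSE)
  invisible(m)
}

#' Commutation matrix
#'
#' The \eqn{p^2 \times p^2} permutation matrix \eqn{K_p} satisfying
#' \eqn{K_p\,\mathrm{vec}(A) = \mathrm{vec}(A')} for every \eqn{p \times p}
#' matrix \eqn{A}. It is an involution: \eqn{K_p K_p = I}.
#'
#' @param p Matrix dimension (positive integer).
#' @return A `p^2 x p^2` 0/1 matrix of class `operator_matrix`.
#' @seealso [symmetrizer_matrix()]
#' @export
commutation_matrix <- function(p) {
  p <- .check_p(p)
  p2 <- p * p
  K <- matrix(0, p2, p2)
  # vec(A)[i + (j-1)p] = A[i,j] must land at vec(A')[j + (i-1)p]
  i <- rep(seq_len(p), times = p)
  j <- rep(seq_len(p), each  = p)
  K[cbind(j + (i - 1L) * p, i + (j - 1L) * p)] <- 1
  structure(K, class = c("operator_matrix", "matrix"), kind = "commutation")
}

#' Symmetrizer matrix
#'
#' \eqn{M_s = (I_{p^2} + K_p)/2}, the orthogonal projector onto vectorized
#' symmetric matrices: \eqn{M_s\,\mathrm{vec}(A) = \mathrm{vec}((A + A')/2)}.
#' It is symmetric and idempotent.
#'
#' @inheritParams commutation_matrix
#' @return A `p^2 x p^2` matrix of class `operator_matrix`.
#' @export
symmetrizer_matrix <- function(p) {
  p <- .check_p(p)
  Ms <- (diag(p * p) + unclass(commutation_matrix(p))) / 2
  structure(Ms, class = c("operator_matrix", "matrix"), kind = "symmetrizer")
}

#' Gaussian-moment covariance of the vectorized sample covariance matrix
#'
#' Under Gaussian rows with covariance \eqn{\Sigma}, the asymptotic covariance
#' of \eqn{\sqrt{n}\,\mathrm{vec}(\hat\Sigma)} has the closed form
#' \eqn{2 M_s (\Sigma \otimes \Sigma)}. Evaluated at the plug-in
#' `sigma_hat`. For standardized panels `sigma_hat` is the correlation
#' matrix and the result estimates \eqn{V_{\hat\Sigma}} of the reference
#' sample at \eqn{O(p^4)} cost (no pass over the data).
#'
#' @param sigma_hat A symmetric positive semidefinite `p x p` covariance
#'   (or correlation) matrix.
#' @return An object of class `moment_estimates` with component `v_sigma`
#'   (`p^2 x p^2`), `method = "gaussian"`.
#' @examples
#' vcov_vec_cov_gaussian(diag(2))$v_sigma  # 2 * Ms
#' @export
vcov_vec_cov_gaussian <- function(sigma_hat) {
  .check_symmetric(sigma_hat, name = "sigma_hat")
  p <- .check_p(nrow(sigma_hat))
  Ms <- unclass(symmetrizer_matrix(p))
  V <- 2 * Ms %*% (sigma_hat %x% sigma_hat)
  V <- (V + t(V)) / 2   # exact symmetry (Ms commutes with S (x) S)
  new_moment_estimates(v_sigma = V, method = "gaussian", n_used = NA_integer_)
}

#' Empirical covariance of the vectorized sample covariance matrix
#'
#' Distribution-free estimator of the covariance of
#' \eqn{\sqrt{n}\,\mathrm{vec}(\hat\Sigma)}: with per-row rank-one estimates
#' \eqn{\hat\Sigma_i = x_i x_i'},
#' \deqn{\hat V = n^{-1} \sum_i (\mathrm{vec}(\hat\Sigma_i) -
#'   \mathrm{vec}(\hat\Sigma))(\mathrm{vec}(\hat\Sigma_i) -
#'   \mathrm{vec}(\hat\Sigma))'.}
#' Cost is \eqn{O(n p^4)}; the inner sum is a single `crossprod` over the
#' row-wise Khatri-Rao product, not an R-level loop.
#'
#' @param x An `n x p` numeric matrix with centered columns (e.g. a
#'   standardized panel). With `center = "auto"` un-centered columns are
#'   centered with a warning; with `center = "error"` (default) they are
#'   rejected.
#' @param center `"error"` or `"auto"`.
#' @return An object of class `moment_estimates` with `v_sigma`,
#'   `method = "empirical"`, `n_used = nrow(x)`.
#' @export
vcov_vec_cov_empirical <- function(x, center = c("error", "auto")) {
  center <- match.arg(center)
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  n <- nrow(x)
  p <- .check_p(ncol(x))
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  mu <- colMeans(x)
  if (max(abs(mu)) > 1e-6 * max(1, max(abs(x)))) {
    if (center == "error")
      stop("columns of `x` are not centered; standardize the panel first or use center = \"auto\"",
           call. = FALSE)
    warning("auto-centering columns of `x`")
    x <- sweep(x, 2L, mu)
  }
  # Z[i, ] = vec(x_i x_i'): column k = i + (j-1)p is x[, i] * x[, j]
  ii <- rep(seq_len(p), times = p)
  jj <- rep(seq_len(p), each  = p)
  Z <- x[, ii, drop = FALSE] * x[, jj, drop = FALSE]
  Zc <- sweep(Z, 2L, colMeans(Z))
  V <- crossprod(Zc) / n
  V <- (V + t(V)) / 2
  new_moment_estimates(v_sigma = V, method = "empirical", n_used = n)
}

#' Jacobian of the covariance-to-correlation transform
#'
#' Closed-form \eqn{J = \partial\,\mathrm{vec}(R)/\partial\,\mathrm{vec}(\Sigma)}
#' evaluated at `sigma`, where \eqn{R = D^{-1/2}\Sigma D^{-1/2}} and
#' \eqn{D = \mathrm{diag}(\Sigma)}. Rows corresponding to diagonal positions
#' of \eqn{R} are identically zero (the diagonal of a correlation matrix is
#' constant). Used to push the covariance of \eqn{\mathrm{vec}(\hat\Sigma)}
#' through the delta method; see [vcov_vec_corr()].
#'
#' @param sigma A `p x p` covariance matrix with strictly positive diagonal.
#' @return A `p^2 x p^2` matrix of class `operator_matrix`.
#' @export
corr_jacobian <- function(sigma) {
  .check_symmetric(sigma, name = "sigma")
  p <- .check_p(nrow(sigma))
  d <- diag(sigma)
  if (any(d <= 0))
    stop("degenerate input: `sigma` has a non-positive diagonal entry", call. = FALSE)
  p2 <- p * p
  s <- 1 / sqrt(d)
  R <- sigma * tcrossprod(s)
  i <- rep(seq_len(p), times = p)
  j <- rep(seq_len(p), each  = p)
  r <- seq_len(p2)                       # row index of entry (i, j)
  J <- matrix(0, p2, p2)
  J[cbind(r, r)] <- s[i] * s[j]          # dR_ij / dSigma_ij
  dcol <- function(k) k + (k - 1L) * p   # vec position of a diagonal entry
  # dR_ij / dSigma_ii and / dSigma_jj; for i == j they cancel to 0
  J[cbind(r, dcol(i))] <- J[cbind(r, dcol(i))] - R[cbind(i, j)] / (2 * d[i])
  J[cbind(r, dcol(j))] <- J[cbind(r, dcol(j))] - R[cbind(i, j)] / (2 * d[j])
  structure(J, class = c("operator_matrix", "matrix"), kind = "jacobian")
}

#' Covariance of the vectorized sample correlation matrix
#'
#' Delta-method transform \eqn{V_{\hat R} = J V_{\hat\Sigma} J'} of the
#' covariance of the vectorized covariance matrix into the covariance of
#' \eqn{\sqrt{n}\,\mathrm{vec}(\hat R)}. Rows and columns indexed by
#' diagonal positions of \eqn{R} are exactly zero.
#'
#' @param moments A `moment_estimates` object holding `v_sigma` (from
#'   [vcov_vec_cov_gaussian()] or [vcov_vec_cov_empirical()]).
#' @param sigma The `p x p` covariance at which to evaluate the Jacobian
#'   (for a standardized panel, its correlation matrix).
#' @return The input `moment_estimates` with `v_corr` filled in.
#' @export
vcov_vec_corr <- function(moments, sigma) {
  stopifnot(inherits(moments, "moment_estimates"))
  .check_symmetric(sigma, name = "sigma")
  p <- nrow(sigma)
  if (nrow(moments$v_sigma) != p * p)
    stop("dimension mismatch between `moments` and `sigma`", call. = FALSE)
  J <- unclass(corr_jacobian(sigma))
  V <- J %*% moments$v_sigma %*% t(J)
  V <- (V + t(V)) / 2
  dpos <- seq_len(p) + (seq_len(p) - 1L) * p
  V[dpos, ] <- 0
  V[, dpos] <- 0
  moments$v_corr <- V
  moments
}

new_moment_estimates <- function(v_sigma = NULL, v_corr = NULL, method, n_used) {
  structure(list(v_sigma = v_sigma, v_corr = v_corr,
                 method = method, n_used = n_used),
            class = "moment_estimates")
}

#' @export
print.moment_estimates <- function(x, ...) {
  p2 <- if (!is.null(x$v_sigma)) nrow(x$v_sigma) else nrow(x$v_corr)
  cat("Moment estimates (", x$method, "): p^2 = ", p2,
      if (!is.null(x$v_corr)) "; v_corr filled" else "; v_sigma only",
      "\n", sep = "")
  invisible(x)
}
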
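# Simulation generators: Gaussian AR(1) covariates, quantile-thresholded
# pseudo-genotypes, phenotypes at a target heritability, screened
# (selection-conditioned) phenotypes, and the FDR/power harness.

#' AR(1) correlation matrix
#'
#' \eqn{\Sigma_{ij} = \rho^{|i-j|}}, the standard first-order
#' autoregressive LD surrogate.
#'
#' @param p Dimension.
#' @param rho AR(1) parameter, `|rho| < 1`.
#' @return A `p x p` positive-definite matrix.
#' @export
ar1_covariance <- function(p, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a Gaussian covariate panel
#'
#' Rows iid \eqn{N(0, \Sigma)} via a Cholesky factor.
#'
#' @param n Number of rows.
#' @param sigma `p x p` positive semidefinite covariance.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return An `n x p` raw (unstandardized) matrix.
#' @export
sample_gaussian_panel <- function(n, sigma, seed = NULL) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("`sigma` is not positive definite: ",
                                          conditionMessage(e), call. = FALSE))
  p <- ncol(sigma)
  .with_seed(seed, matrix(stats::rnorm(n * p), n, p) %*% ch)
}

#' Sample minor allele frequencies
#'
#' \eqn{q_j = \max(B_j / 2, 0.05)} with \eqn{B_j \sim \mathrm{Beta}(1, 2)}:
#' a left-skewed MAF spectrum truncated below at 0.05 so every variant is
#' comfortably polymorphic.
#'
#' @param p Number of variants.
#' @param seed Optional integer seed.
#' @return Length-`p` vector in `[0.05, 0.5]`.
#' @export
sample_mafs <- function(p, seed = NULL) {
  .with_seed(seed, pmax(stats::rbeta(p, 1, 2) / 2, 0.05))
}

#' Quantile-threshold transform of Gaussians to genotypes
#'
#' Maps a standard-normal latent value to a minor-allele count in
#' \eqn{\{0, 1, 2\}} using the cutpoints \eqn{z_{1 - 2q/3}} and
#' \eqn{z_{1 - q/3}}, so that \eqn{P(g = 1) = P(g = 2) = q/3} and the
#' expected allele count is \eqn{E[g] = q}.
#'
#' @param w Numeric vector of latent Gaussian values.
#' @param q Minor allele frequency in `(0, 0.5]`.
#' @return Integer vector of genotypes 0/1/2.
#' @export
genotype_transform <- function(w, q) {
  if (length(q) != 1L || q <= 0 || q > 0.5)
    stop("`q` must be in (0, 0.5]", call. = FALSE)
  c1 <- stats::qnorm(1 - 2 * q / 3)
  c2 <- stats::qnorm(1 - q / 3)
  ifelse(w >= c2, 2L, ifelse(w > c1, 1L, 0L))
}

#' Sample a pseudo-genotype panel
#'
#' Latent rows \eqn{N(0, \Sigma)} are column-wise quantile-thresholded into
#' genotypes with per-variant MAFs ([genotype_transform()]). Columns that
#' come out monomorphic (possible at small `n` and MAF near the floor) are
#' redrawn; the redraw count is reported as an attribute `redraws`.
#'
#' @param n Number of individuals.
#' @param sigma `p x p` latent covariance.
#' @param mafs Length-`p` MAF vector (see [sample_mafs()]).
#' @param seed Optional integer seed.
#' @param max_redraws Cap on per-column redraw attempts (default 100).
#' @return An `n x p` integer matrix of 0/1/2 counts.
#' @export
sample_genotype_panel <- function(n, sigma, mafs, seed = NULL, max_redraws = 100) {
  p <- ncol(sigma)
  if (length(mafs) != p) stop("length(mafs) != p", call. = FALSE)
  .with_seed(seed, {
    w <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
    g <- vapply(seq_len(p), function(j) genotype_transform(w[, j], mafs[j]),
                integer(n))
    redraws <- 0L
    for (j in seq_len(p)) {
      k <- 0L
      while (stats::var(g[, j]) == 0) {
        k <- k + 1L
        if (k > max_redraws)
          stop("column ", j, " stayed monomorphic after ", max_redraws, " redraws",
               call. = FALSE)
        g[, j] <- genotype_transform(stats::rnorm(n), mafs[j])
      }
      redraws <- redraws + k
    }
    attr(g, "redraws") <- redraws
    g
  })
}

#' Residual variance from a target heritability
#'
#' Inverts \eqn{h = \beta'R\beta / (\sigma^2 + \beta'R\beta)}:
#' \eqn{\sigma^2 = \beta'R\beta (1 - h)/h}.
#'
#' @param beta Length-`p` coefficient vector with \eqn{\beta'R\beta > 0}.
#' @param corr `p x p` correlation matrix.
#' @param h Heritability in `(0, 1)`.
#' @return Positive scalar \eqn{\sigma^2}.
#' @export
sigma2_from_h <- function(beta, corr, h) {
  if (h <= 0 || h >= 1) stop("`h` must be in (0, 1)", call. = FALSE)
  brb <- drop(crossprod(beta, corr %*% beta))
  if (brb <= 0) stop("beta' R beta must be positive", call. = FALSE)
  brb * (1 - h) / h
}

#' Simulate a standardized phenotype
#'
#' \eqn{y_{raw} = X\beta + \varepsilon}, \eqn{\varepsilon \sim N(0,
#' \sigma^2 I)}, on the standardized panel; the returned phenotype is then
#' itself standardized (mean 0, sd 1, divisor `n`), matching how summary
#' statistics for standardized traits are reported.
#'
#' @param panel A `standardized_panel`.
#' @param beta Length-`p` coefficient vector.
#' @param sigma2 Noise variance.
#' @param seed Optional integer seed.
#' @return Length-`n` standardized phenotype vector.
#' @export
simulate_phenotype <- function(panel, beta, sigma2, seed = NULL) {
  stopifnot(inherits(panel, "standardized_panel"))
  if (length(beta) != panel$p) stop("length(beta) != p", call. = FALSE)
  .with_seed(seed, {
    y <- drop(panel$x %*% beta) + stats::rnorm(panel$n, sd = sqrt(sigma2))
    y <- y - mean(y)
    y / sqrt(mean(y^2))
  })
}

#' Resample noise until the region is selected
#'
#' Repeats [simulate_phenotype()] until the squared marginal coefficient of
#' the screened variant exceeds `threshold_t`, mirroring how a
#' selection-conditioned replicate is produced: covariates are held fixed
#' and only the noise is redrawn.
#'
#' @param panel The original-study `standardized_panel`.
#' @param beta Length-`p` coefficient vector.
#' @param sigma2 Noise variance.
#' @param screened_index Screened variant (1-based).
#' @param threshold_t Squared-coefficient selection threshold.
#' @param max_resamples Attempt cap (default 1e5).
#' @param seed Optional integer seed.
#' @return List with `y` (a selected standardized phenotype) and
#'   `resamples` (number of attempts; 1 means the first draw was selected).
#' @export
simulate_until_selected <- function(panel, beta, sigma2, screened_index,
                                    threshold_t, max_resamples = 1e5,
                                    seed = NULL) {
  stopifnot(inherits(panel, "standardized_panel"))
  .with_seed(seed, {
    for (k in seq_len(max_resamples)) {
      y <- simulate_phenotype(panel, beta, sigma2)
      bom <- drop(crossprod(panel$x[, screened_index], y)) / panel$n
      if (bom^2 > threshold_t) return(list(y = y, resamples = k))
    }
    stop("selection too rare: not observed in ", max_resamples,
         " noise resamples (empirical selection rate < ",
         format(1 / max_resamples), ")", call. = FALSE)
  })
}

#' False and true discovery proportions
#'
#' \eqn{FDP = |s \setminus s^*| / \max(|s|, 1)},
#' \eqn{TDP = |s \cap s^*| / \max(1, |s^*|)}.
#'
#' @param rejected_set Integer indices of rejected variants (`s`).
#' @param causal_set Integer indices of truly causal variants (`s^*`).
#' @return Named numeric vector `c(fdp = , tdp = )`.
#' @export
fdp_tdp <- function(rejected_set, causal_set) {
  s <- unique(as.integer(rejected_set))
  ss <- unique(as.integer(causal_set))
  c(fdp = length(setdiff(s, ss)) / max(length(s), 1),
    tdp = length(intersect(s, ss)) / max(1, length(ss)))
}

#' Simulation configuration
#'
#' Bundles the design of one simulation setting: region size, AR(1) LD
#' parameter, sample sizes, causal set, heritability, covariate kind and
#' (optionally) a marginal-screening selection stage.
#'
#' @param p Variants per region (default 20).
#' @param rho AR(1) parameter of the (latent) covariate correlation
#'   (0.8 for the Gaussian design, 0.95 for the genotype designs).
#' @param n_o,n_r Original and reference sample sizes.
#' @param causal_set Indices with nonzero effect (default `c(1, p)`).
#' @param beta_value Effect size on the causal set (default 1).
#' @param h Heritability in `(0, 1)`.
#' @param covariate_kind `"gaussian"` or `"genotype"`.
#' @param reps Number of replicates.
#' @param q Nominal BH FDR level (default 0.05).
#' @param threshold_level Plug-in threshold level (default 0.05).
#' @param selection Optional list with `screened_index` and either
#'   `threshold_t` or (`alpha`, `m`) for [marginal_screen_threshold()];
#'   `max_resamples` optional.
#' @param maf_seed Seed for drawing the MAF vector (genotype designs); the
#'   MAFs are drawn once and held fixed across replicates.
#' @param data_seed Master seed for the replicate streams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = 20, rho = 0.8, n_o = 1e4, n_r = 1e3,
                       causal_set = c(1, p), beta_value = 1, h = 0.05,
                       covariate_kind = c("gaussian", "genotype"),
                       reps = 1000, q = 0.05, threshold_level = 0.05,
                       selection = NULL, maf_seed = 20L, data_seed = 1L) {
  covariate_kind <- match.arg(covariate_kind)
  stopifnot(all(causal_set >= 1), all(causal_set <= p), h > 0, h < 1, reps >= 1)
  if (!is.null(selection)) {
    if (is.null(selection$screened_index))
      stop("selection needs `screened_index`", call. = FALSE)
    if (is.null(selection$threshold_t))
      selection$threshold_t <- marginal_screen_threshold(
        n_o, m = selection$m %||% 20000, alpha = selection$alpha %||% 0.05)
    selection$max_resamples <- selection$max_resamples %||% 1e5
  }
  structure(list(p = p, rho = rho, n_o = n_o, n_r = n_r,
                 causal_set = as.integer(causal_set), beta_value = beta_value,
                 h = h, covariate_kind = covariate_kind, reps = as.integer(reps),
                 q = q, threshold_level = threshold_level,
                 selection = selection, maf_seed = maf_seed,
                 data_seed = data_seed),
            class = "sim_config")
}

# one replicate's data: original panel, reference panel, beta, sigma2
.sim_draw_panels <- function(config, mafs = NULL) {
  sigma <- ar1_covariance(config$p, config$rho)
  if (config$covariate_kind == "gaussian") {
    xo_raw <- sample_gaussian_panel(config$n_o, sigma)
    xr_raw <- sample_gaussian_panel(config$n_r, sigma)
  } else {
    xo_raw <- sample_genotype_panel(config$n_o, sigma, mafs)
    xr_raw <- sample_genotype_panel(config$n_r, sigma, mafs)
  }
  list(xo = standardize_panel(xo_raw), xr = standardize_panel(xr_raw))
}

#' Run a simulation experiment
#'
#' For each replicate: draw fresh original and reference panels, set
#' \eqn{\beta} on the causal set, calibrate \eqn{\sigma^2} to the target
#' heritability via the original panel's correlation, simulate the
#' phenotype (resampling noise until selection when a selection stage is
#' configured), run every requested method's fine-mapping pipeline, apply
#' BH at the configured level, and record FDP/TDP. Replicate seeds are
#' derived from `data_seed` so runs are reproducible and replicate streams
#' independent. A replicate in which a method fails is recorded as skipped
#' for that method with a warning.
#'
#' @param config A `sim_config`.
#' @param methods Character vector from `"naive"`, `"corrected_gaussian"`,
#'   `"corrected_empirical"`, `"full"` (oracle OLS on the original data)
#'   and, when selection is configured, `"psat_mle"`.
#' @return An object of class `sim_result`: per-method `fdr`, `fdr_se`,
#'   `power`, `power_se`, unconditional power when selection is active, and
#'   the per-replicate records.
#' @export
run_experiment <- function(config,
                           methods = c("naive", "corrected_empirical")) {
  stopifnot(inherits(config, "sim_config"))
  known <- c("naive", "corrected_gaussian", "corrected_empirical", "full", "psat_mle")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "),
         call. = FALSE)
  if ("psat_mle" %in% methods && is.null(config$selection))
    stop("method \"psat_mle\" requires a selection stage in the config", call. = FALSE)
  beta <- numeric(config$p)
  beta[config$causal_set] <- config$beta_value
  mafs <- if (config$covariate_kind == "genotype")
    sample_mafs(config$p, seed = config$maf_seed) else NULL
  rep_seeds <- .with_seed(config$data_seed,
                          sample.int(.Machine$integer.max - 1L, config$reps))
  sel <- config$selection
  records <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    rec <- .with_seed(rep_seeds[r], tryCatch({
      panels <- .sim_draw_panels(config, mafs)
      sigma2 <- sigma2_from_h(beta, panels$xo$corr, config$h)
      if (is.null(sel)) {
        y <- simulate_phenotype(panels$xo, beta, sigma2)
        resamples <- 1L
      } else {
        drawn <- simulate_until_selected(panels$xo, beta, sigma2,
                                         sel$screened_index, sel$threshold_t,
                                         max_resamples = sel$max_resamples)
        y <- drawn$y
        resamples <- drawn$resamples
      }
      marg <- marginal_coefficients(panels$xo, y)
      out <- list(resamples = resamples)
      for (m in methods) {
        rej <- tryCatch(
          .run_method(m, marg, panels, y, config),
          error = function(e) {
            warning("replicate ", r, ", method ", m, " failed: ",
                    conditionMessage(e), call. = FALSE)
            NULL
          })
        out[[m]] <- if (is.null(rej)) c(fdp = NA_real_, tdp = NA_real_)
                    else fdp_tdp(which(rej), config$causal_set)
      }
      out
    }, error = function(e) {
      warning("replicate ", r, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }))
    records[[r]] <- rec
  }
  records <- Filter(Negate(is.null), records)
  summarize <- function(m, comp) {
    vals <- vapply(records, function(r) r[[m]][[comp]], numeric(1))
    vals <- vals[!is.na(vals)]
    c(mean = mean(vals), se = stats::sd(vals) / sqrt(length(vals)), n = length(vals))
  }
  res <- lapply(methods, function(m) {
    f <- summarize(m, "fdp"); t <- summarize(m, "tdp")
    out <- list(fdr = unname(f["mean"]), fdr_se = unname(f["se"]),
                power = unname(t["mean"]), power_se = unname(t["se"]),
                n_used = unname(f["n"]))
    if (!is.null(sel)) {
      # unconditional power: discoveries per selection attempt
      tdp <- vapply(records, function(r) r[[m]][["tdp"]], numeric(1))
      att <- vapply(records, function(r) r[["resamples"]], numeric(1))
      keep <- !is.na(tdp)
      out$power_unconditional <- sum(tdp[keep]) / sum(att[keep])
      out$mean_resamples <- mean(att)
    }
    out
  })
  names(res) <- methods
  structure(list(methods = res, config = config, records = records,
                 conditional = !is.null(sel)),
            class = "sim_result")
}

# dispatch one method on one replicate; returns the logical rejection vector
.run_method <- function(method, marg, panels, y, config) {
  if (method == "full") {
    fit <- stats::lm(y ~ panels$xo$x - 1)
    p <- summary(fit)$coefficients[, 4]
    return(bh_adjust(unname(p), config$q))
  }
  if (method == "psat_mle") {
    sel <- config$selection
    spec <- selection_spec(sel$screened_index, sel$threshold_t, panels$xr$corr)
    return(psat_finemap(marg, panels$xr, spec, method = "corrected_empirical",
                        q = config$q,
                        threshold_level = config$threshold_level)$rejected)
  }
  finemap_region(marg, panels$xr, method = method, q = config$q,
                 threshold_level = config$threshold_level)$rejected
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result (", length(x$records), " replicates",
      if (x$conditional) ", selection-conditioned", "):\n", sep = "")
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("  %-22s FDR %.4f (SE %.4f)  power %.4f (SE %.4f)",
                m, r$fdr, r$fdr_se, r$power, r$power_se))
    if (!is.null(r$power_unconditional))
      cat(sprintf("  uncond. power %.4f", r$power_unconditional))
    cat("\n")
  }
  invisible(x)
}

#' Coerce a simulation result to a data frame
#'
#' One row per method with FDR, power and their Monte-Carlo standard
#' errors.
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.sim_result <- function(x, ...) {
  rows <- lapply(names(x$methods), function(m) {
    r <- x$methods[[m]]
    data.frame(method = m, fdr = r$fdr, fdr_se = r$fdr_se,
               power = r$power, power_se = r$power_se,
               power_unconditional = r$power_unconditional %||% NA_real_,
               conditional = x$conditional, n_reps = r$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
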
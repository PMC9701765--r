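# Effect-size trends over the number of added genotypes:
# generalized least squares with an exponential variance function,
# Var(eps_i) = sigma^2 exp(2 delta mu_i), variance covariate = fitted values.

#' Log2-transform of the number of added genotypes
#'
#' @param n_genotypes_added integer vector, >= 1.
#' @return `log2(n)`.
#' @export
log_genotypes <- function(n_genotypes_added) {
  if (any(n_genotypes_added < 1)) {
    stop("n_genotypes_added must be >= 1", call. = FALSE)
  }
  log2(n_genotypes_added)
}

# profile log-likelihood machinery: for fixed delta and variance covariate
# mu, the weighted LS solution and the ML profile likelihood are closed form
.gls_profile <- function(delta, X, y, mu) {
  n <- length(y)
  w <- exp(-2 * delta * mu)
  XtW <- t(X * w)
  cXtWX <- tryCatch(chol(XtW %*% X), error = function(e) NULL)
  if (is.null(cXtWX)) return(NULL)
  beta <- backsolve(cXtWX, forwardsolve(t(cXtWX), XtW %*% y))
  r <- drop(y - X %*% beta)
  sigma2 <- sum(w * r^2) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n) - delta * sum(mu)
  list(beta = drop(beta), sigma2 = sigma2, ll = ll, w = w, cXtWX = cXtWX)
}

#' Generalized least squares with exponential variance function
#'
#' Fits `y = b0 + b1 x + eps` with `Var(eps_i) = sigma^2 exp(2 delta
#' mu_i)`, the variance covariate `mu_i` being the fitted values. The
#' variance parameter `delta` is profiled by maximum likelihood; fitting
#' iterates the variance covariate to convergence of the log-likelihood.
#'
#' @param x predictor (typically `log_genotypes(n)`); must not be
#'   constant.
#' @param y response (effect sizes).
#' @param delta fix the variance parameter at a value instead of
#'   estimating it (`delta = 0` reduces exactly to OLS).
#' @param max_iter,tol iteration control for the variance-covariate loop.
#' @return Object of class `gls_fit`: `beta` (intercept, slope), `delta`,
#'   `sigma2`, `vcov_beta`, `loglik`, `df_resid = n - 2`, `t_slope`,
#'   `p_slope`, plus the data and weights.
#' @export
fit_gls_varexp <- function(x, y, delta = NULL, max_iter = 100L, tol = 1e-8) {
  stopifnot(length(x) == length(y), length(y) >= 4)
  if (stats::sd(x) == 0) stop("constant predictor: trend not estimable",
                              call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x = x)
  n <- length(y)

  # OLS start for the variance covariate
  beta <- qr.coef(qr(X), y)
  mu <- drop(X %*% beta)
  ll_old <- -Inf
  ll_prev2 <- -Inf
  fixed_delta <- !is.null(delta)
  cur <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (fixed_delta) {
      d_hat <- delta
    } else {
      o <- optimize(function(d) {
        pr <- .gls_profile(d, X, y, mu)
        if (is.null(pr)) -Inf else pr$ll
      }, interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
      d_hat <- o$maximum
    }
    cur <- .gls_profile(d_hat, X, y, mu)
    if (is.null(cur)) stop("GLS fit failed (singular weighted design)",
                           call. = FALSE)
    mu_new <- drop(X %*% cur$beta)
    # accept on stationarity or on a two-cycle of the covariate update
    if (abs(cur$ll - ll_old) < tol || abs(cur$ll - ll_prev2) < tol) {
      mu <- mu_new
      converged <- TRUE
      break
    }
    ll_prev2 <- ll_old
    ll_old <- cur$ll
    # damp the covariate update after the first iterations to suppress
    # oscillation between fixed points
    mu <- if (it > 10L) (mu + mu_new) / 2 else mu_new
  }
  if (!converged) {
    stop("GLS variance-covariate iteration did not converge after ",
         max_iter, " iterations", call. = FALSE)
  }

  df_resid <- n - 2L
  # vcov with residual-df scaled sigma2 for t-type inference
  XtWXinv <- chol2inv(cur$cXtWX)
  r <- drop(y - X %*% cur$beta)
  s2_df <- sum(cur$w * r^2) / df_resid
  vcov_beta <- s2_df * XtWXinv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  t_slope <- cur$beta[2] / sqrt(vcov_beta[2, 2])
  fit <- list(
    beta = setNames(cur$beta, colnames(X)),
    delta = d_hat, sigma2 = s2_df,
    vcov_beta = vcov_beta,
    loglik = cur$ll,
    df_resid = df_resid,
    t_slope = unname(t_slope),
    p_slope = unname(2 * pt(-abs(t_slope), df_resid)),
    x = x, y = y, fitted = drop(X %*% cur$beta), weights = cur$w,
    delta_fixed = fixed_delta
  )
  class(fit) <- "gls_fit"
  fit
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("GLS with exponential variance function\n")
  cat(sprintf("  slope = %.4f (t = %.3f, df = %d, p = %.4g), delta = %.4f\n",
              x$beta[2], x$t_slope, x$df_resid, x$p_slope, x$delta))
  invisible(x)
}

#' Marginal predictions with 95% confidence band
#'
#' Pointwise confidence band from the coefficient covariance; grid points
#' outside the observed predictor range are flagged as extrapolation.
#'
#' @param fit a `gls_fit`.
#' @param x_grid predictor values at which to predict.
#' @param level confidence level.
#' @return Data frame `x`, `fit`, `ci_low`, `ci_high`, `extrapolated`.
#' @export
predict_with_band <- function(fit, x_grid, level = 0.95) {
  stopifnot(inherits(fit, "gls_fit"))
  Xg <- cbind(1, x_grid)
  mu <- drop(Xg %*% fit$beta)
  se <- sqrt(rowSums((Xg %*% fit$vcov_beta) * Xg))
  tcrit <- qt(1 - (1 - level) / 2, fit$df_resid)
  extra <- x_grid < min(fit$x) | x_grid > max(fit$x)
  if (any(extra)) {
    warning("prediction grid extends beyond the observed predictor range")
  }
  data.frame(x = x_grid, fit = mu,
             ci_low = mu - tcrit * se, ci_high = mu + tcrit * se,
             extrapolated = extra)
}

#' Per-group genotype-number trends
#'
#' Fits [fit_gls_varexp()] of effect size on `log2(n_genotypes_added)`
#' pooled and separately per trophic group (groups with fewer than
#' `min_obs` observations or a constant predictor are skipped).
#'
#' @param d effect-size table with columns `g`, `n_genotypes_added`,
#'   `trophic_group`.
#' @param min_obs minimum observations per group.
#' @return Data frame with one row per fitted stratum: `group`, `slope`,
#'   `t`, `df`, `p`, `delta`.
#' @export
trend_by_group <- function(d, min_obs = 10L) {
  strata <- c(list(pooled = d),
              split(d, d$trophic_group),
              list(antagonist = d[d$trophic_group %in% antagonist_groups(), ]))
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    x <- log_genotypes(s$n_genotypes_added)
    if (nrow(s) < min_obs || stats::sd(x) == 0) return(NULL)
    f <- fit_gls_varexp(x, s$g)
    data.frame(group = nm, slope = unname(f$beta[2]), t = f$t_slope,
               df = f$df_resid, p = f$p_slope, delta = f$delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
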
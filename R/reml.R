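# Multilevel mixed-effects meta-regression fitted by (RE)ML.
#
# Marginal model: y ~ N(X beta, V) with
#   V = diag(v) + tau2_species_phylo Z_sp R Z_sp' + tau2_species Z_sp Z_sp'
#             + tau2_study Z_st Z_st' + tau2_obs I
# Variance components are profiled out of beta (GLS at each V) and
# maximized on the log scale.

.known_components <- c("species_phylo", "species", "study", "obs")

.make_Z <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# n x n kernel matrices for each requested variance component
.build_kernels <- function(data, random, R, species_col, study_col) {
  n <- nrow(data)
  kernels <- list()
  for (comp in random) {
    K <- switch(comp,
      obs = diag(n),
      study = {
        Z <- .make_Z(data[[study_col]])
        tcrossprod(Z)
      },
      species = {
        Z <- .make_Z(data[[species_col]])
        tcrossprod(Z)
      },
      species_phylo = {
        if (is.null(R)) stop("component 'species_phylo' requires R", call. = FALSE)
        sp <- as.character(data[[species_col]])
        in_tree <- sp %in% rownames(R)
        Rfull <- matrix(0, n, n)
        if (any(in_tree)) {
          idx <- match(sp[in_tree], rownames(R))
          Rfull[in_tree, in_tree] <- R[idx, idx]
        }
        Rfull
      },
      stop("unknown random component: ", comp, call. = FALSE)
    )
    kernels[[comp]] <- K
  }
  kernels
}

# log-likelihood of the marginal model at variance components tau2
# returns list(ll, beta, vcov_beta, ...) or ll only
.meta_eval <- function(tau2, y, X, v, kernels, method, full = FALSE) {
  n <- length(y); p <- ncol(X)
  V <- diag(v, n)
  for (k in seq_along(kernels)) V <- V + tau2[k] * kernels[[k]]
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    return(if (full) NULL else -Inf)
  }
  logdetV <- 2 * sum(log(diag(L)))
  ViX <- backsolve(L, forwardsolve(t(L), X))
  Viy <- backsolve(L, forwardsolve(t(L), y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(if (full) NULL else -Inf)
  beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), XtViy))
  r <- y - X %*% beta
  Vir <- backsolve(L, forwardsolve(t(L), r))
  quad <- sum(r * Vir)
  if (method == "REML") {
    logdetXtViX <- 2 * sum(log(diag(cXtViX)))
    logdetXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXtViX + quad) +
      0.5 * as.numeric(logdetXtX)
  } else {
    ll <- -0.5 * (n * log(2 * pi) + logdetV + quad)
  }
  if (!full) return(ll)
  vcov_beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), diag(p)))
  vcov_beta <- (vcov_beta + t(vcov_beta)) / 2
  list(ll = ll, beta = drop(beta), vcov_beta = vcov_beta, V = V)
}

#' Control parameters for [fit_meta()]
#'
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum optimizer iterations.
#' @param restarts number of additional deterministic dispersed starts
#'   (beyond the moment-based start); the best restricted likelihood wins,
#'   ties broken by smallest total heterogeneity.
#' @param eps floor added to variance components on the log scale.
#' @return A list of control values.
#' @export
meta_control <- function(reltol = 1e-10, maxit = 1000L, restarts = 2L,
                         eps = 1e-10) {
  list(reltol = reltol, maxit = maxit, restarts = restarts, eps = eps)
}

#' Fit a multilevel mixed-effects meta-regression model
#'
#' Fits `y ~ N(X beta, V)` with `V = diag(v) + sum_k tau2_k K_k`, where
#' the kernels are (optionally) a phylogenetically correlated species
#' intercept, an iid species intercept, a study intercept and an
#' observation-level component; variance components are estimated by
#' restricted maximum likelihood (or ML) on the log scale and `beta` by
#' generalized least squares at the optimum.
#'
#' @param data data frame holding the effect sizes, sampling variances and
#'   moderators (typically from [add_effect_sizes()]).
#' @param fixed right-hand-side formula for the moderators, e.g.
#'   `~ 0 + trophic_group`.
#' @param random character vector naming variance components among
#'   `"species_phylo"`, `"species"`, `"study"`, `"obs"`.
#' @param R phylogenetic correlation matrix (from [phylo_correlation()]);
#'   required iff `"species_phylo"` is requested.
#' @param yi,vi column names of the effect size and its sampling variance.
#' @param species_col,study_col grouping column names.
#' @param method `"REML"` (default) or `"ML"`.
#' @param tau2 optional named numeric of components to FIX (e.g.
#'   `c(study = 0)` to drop the study component from optimization while
#'   keeping it in the model at that value).
#' @param control see [meta_control()].
#' @return An object of class `meta_fit`: coefficients `beta`, `se`,
#'   `vcov_beta`, variance components `tau2`, `loglik` (restricted or ML),
#'   counts, `df_resid = n_obs - p`, and the information needed to refit.
#' @export
fit_meta <- function(data, fixed = ~ 1, random = c("species", "study", "obs"),
                     R = NULL, yi = "g", vi = "v",
                     species_col = "plant_species", study_col = "study_id",
                     method = c("REML", "ML"), tau2 = NULL,
                     control = meta_control()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), yi %in% names(data), vi %in% names(data))
  if (length(unique(data[[study_col]])) < 2L) {
    stop("need at least 2 studies", call. = FALSE)
  }
  y <- as.numeric(data[[yi]])
  v <- as.numeric(data[[vi]])
  stopifnot(all(is.finite(y)), all(is.finite(v)), all(v > 0))

  mf <- model.frame(fixed, data, na.action = stats::na.fail)
  mf <- droplevels(mf)
  X <- model.matrix(fixed, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- length(y); p <- ncol(X)
  if (n - p < 1L) stop("no residual degrees of freedom", call. = FALSE)

  if (length(random) > 0L) {
    random <- match.arg(random, .known_components, several.ok = TRUE)
  }
  kernels <- .build_kernels(data, random, R, species_col, study_col)

  fixed_tau2 <- numeric(0)
  if (!is.null(tau2)) {
    stopifnot(!is.null(names(tau2)), all(names(tau2) %in% random))
    fixed_tau2 <- tau2
  }
  free <- setdiff(random, names(fixed_tau2))
  K <- length(free)

  tau2_of <- function(par) {
    out <- setNames(numeric(length(random)), random)
    out[names(fixed_tau2)] <- fixed_tau2
    if (K > 0L) out[free] <- exp(par)
    out
  }
  negll <- function(par) {
    -.meta_eval(tau2_of(par), y, X, v, kernels, method)
  }

  if (K == 0L) {
    opt_par <- numeric(0)
    opt_ll <- -negll(opt_par)
    conv <- TRUE
  } else {
    # moment-based start: excess variance split across free components
    s2 <- max(var(y) - mean(v), 0.05 * var(y), 1e-4)
    base_start <- log(rep(s2 / K, K))
    starts <- list(base_start)
    disp <- list(base_start + log(10), base_start - log(10),
                 base_start + rep_len(c(log(25), -log(25)), K))
    if (control$restarts > 0L) {
      starts <- c(starts, disp[seq_len(min(control$restarts, length(disp)))])
    }
    best <- NULL
    for (st in starts) {
      res <- if (K == 1L) {
        o <- optimize(negll, interval = c(st - 20, st + 12), tol = 1e-12)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        optim(st, negll, method = "Nelder-Mead",
              control = list(reltol = control$reltol, maxit = control$maxit))
      }
      if (is.null(best) ||
          res$value < best$value - 1e-9 ||
          (abs(res$value - best$value) <= 1e-9 &&
           sum(exp(res$par)) < sum(exp(best$par)))) {
        best <- res
      }
    }
    opt_par <- best$par
    opt_ll <- -best$value
    conv <- is.finite(opt_ll) && (K == 1L || best$convergence == 0L)
    if (!conv) {
      stop("meta-regression did not converge (final objective ",
           format(-opt_ll), ")", call. = FALSE)
    }
  }

  tau2_hat <- tau2_of(opt_par)
  # snap numerically-zero components to zero
  tau2_hat[tau2_hat < control$eps] <- 0
  final <- .meta_eval(pmax(tau2_hat, 0), y, X, v, kernels, method, full = TRUE)
  if (is.null(final)) stop("variance matrix singular at optimum", call. = FALSE)

  beta <- setNames(final$beta, colnames(X))
  se <- sqrt(diag(final$vcov_beta))
  fit <- list(
    beta = beta, se = setNames(se, names(beta)),
    vcov_beta = final$vcov_beta,
    tau2 = tau2_hat,
    loglik = final$ll,
    method = method,
    n_obs = n,
    n_studies = length(unique(data[[study_col]])),
    n_species = length(unique(data[[species_col]])),
    df_resid = n - p,
    fixed = fixed, random = random, R = R,
    yi = yi, vi = vi, species_col = species_col, study_col = study_col,
    fixed_tau2 = if (length(fixed_tau2)) fixed_tau2 else NULL,
    control = control,
    data = data, X = X, y = y, v = v,
    kernels = kernels
  )
  class(fit) <- "meta_fit"
  fit
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Multilevel meta-regression (", x$method, ")\n", sep = "")
  cat(sprintf("  %d observations, %d studies, %d species; logLik = %.6f\n",
              x$n_obs, x$n_studies, x$n_species, x$loglik))
  cat("  Variance components:\n")
  for (k in names(x$tau2)) {
    cat(sprintf("    tau2_%-14s %.6f\n", k, x$tau2[k]))
  }
  cat("  Coefficients:\n")
  tab <- data.frame(estimate = x$beta, se = x$se,
                    t = x$beta / x$se,
                    p = 2 * pt(-abs(x$beta / x$se), x$df_resid))
  print(round(tab, 4))
  invisible(x)
}

# refit with modified arguments (used for ML refits and bias tests)
.update_meta <- function(fit, fixed = fit$fixed, method = fit$method,
                         data = fit$data) {
  fit_meta(data, fixed = fixed, random = fit$random, R = fit$R,
           yi = fit$yi, vi = fit$vi, species_col = fit$species_col,
           study_col = fit$study_col, method = method,
           tau2 = fit$fixed_tau2, control = fit$control)
}

#' Likelihood-ratio test between nested meta-regression fits
#'
#' When the fixed-effects structures differ, both models are refitted by
#' maximum likelihood before comparison (REML likelihoods are not
#' comparable across fixed-effect structures); variance-component
#' comparisons with identical fixed effects use the REML likelihoods as
#' fitted.
#'
#' @param fit_full,fit_reduced `meta_fit` objects fitted on the same
#'   observations, the reduced model nested in the full one.
#' @return List with `statistic`, `df`, `p`, and the (possibly refitted)
#'   log-likelihoods.
#' @export
lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "meta_fit"), inherits(fit_reduced, "meta_fit"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("models were fitted on different numbers of observations",
         call. = FALSE)
  }
  terms_f <- attr(terms(fit_full$fixed), "term.labels")
  terms_r <- attr(terms(fit_reduced$fixed), "term.labels")
  same_fixed <- identical(sort(terms_f), sort(terms_r)) &&
    attr(terms(fit_full$fixed), "intercept") ==
      attr(terms(fit_reduced$fixed), "intercept")
  if (!same_fixed) {
    if (!all(terms_r %in% terms_f)) {
      stop("models are not nested in their fixed effects", call. = FALSE)
    }
    if (fit_full$method != "ML") fit_full <- .update_meta(fit_full, method = "ML")
    if (fit_reduced$method != "ML") fit_reduced <- .update_meta(fit_reduced, method = "ML")
  } else if (fit_full$method != fit_reduced$method) {
    stop("same fixed effects but different likelihood types", call. = FALSE)
  }
  npar <- function(f) length(f$beta) + sum(!names(f$tau2) %in% names(f$fixed_tau2))
  df <- npar(fit_full) - npar(fit_reduced)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  if (df < 0) stop("full model has fewer parameters than reduced model",
                   call. = FALSE)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p,
       loglik_full = fit_full$loglik, loglik_reduced = fit_reduced$loglik,
       method = fit_full$method)
}

#' Per-category mean effects with t statistics and confidence intervals
#'
#' Linear combinations `c' beta` of the fitted coefficients with
#' t-based inference on `df_resid = n_obs - p` degrees of freedom.
#'
#' @param fit a `meta_fit`.
#' @param term name of a single factor term fitted as `~ 0 + term` (the
#'   usual per-group mean parameterization); one estimate per level, with
#'   per-level observation and study counts. Ignored when `contrasts` is
#'   given.
#' @param contrasts optional numeric matrix (rows = contrasts, columns
#'   matching `coef` order) with rownames as labels.
#' @param level confidence level (default 0.95).
#' @return Data frame with `label`, `effect`, `se`, `t`, `ci_low`,
#'   `ci_high`, `p`, `k_obs`, `k_studies`.
#' @export
category_estimates <- function(fit, term = NULL, contrasts = NULL,
                               level = 0.95) {
  stopifnot(inherits(fit, "meta_fit"))
  p <- length(fit$beta)
  if (is.null(contrasts)) {
    L <- diag(p)
    rownames(L) <- names(fit$beta)
    if (!is.null(term)) {
      stopifnot(term %in% names(fit$data))
      lev <- levels(droplevels(factor(fit$data[[term]])))
      want <- paste0(term, lev)
      if (!all(want %in% names(fit$beta))) {
        stop("inestimable contrast: term '", term,
             "' does not index the coefficients (fit with ~ 0 + ", term, ")",
             call. = FALSE)
      }
      L <- L[match(want, names(fit$beta)), , drop = FALSE]
      rownames(L) <- lev
    }
  } else {
    L <- as.matrix(contrasts)
    if (ncol(L) != p) stop("contrast matrix must have ", p, " columns",
                           call. = FALSE)
    if (is.null(rownames(L))) rownames(L) <- paste0("contrast_", seq_len(nrow(L)))
  }
  est <- drop(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov_beta %*% t(L)))
  if (any(se < 1e-12)) stop("inestimable contrast (zero variance)",
                            call. = FALSE)
  tval <- est / se
  tcrit <- qt(1 - (1 - level) / 2, fit$df_resid)
  pval <- 2 * pt(-abs(tval), fit$df_resid)

  k_obs <- k_st <- rep(NA_integer_, nrow(L))
  if (is.null(contrasts) && !is.null(term)) {
    f <- as.character(fit$data[[term]])
    st <- fit$data[[fit$study_col]]
    k_obs <- vapply(rownames(L), function(l) sum(f == l), integer(1))
    k_st <- vapply(rownames(L), function(l) length(unique(st[f == l])),
                   integer(1))
  }
  data.frame(
    label = rownames(L),
    effect = est, se = se, t = tval,
    ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    p = pval, k_obs = k_obs, k_studies = k_st,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Audit local optimality of a fitted model's variance components
#'
#' Evaluates the objective likelihood at deterministic multiplicative
#' perturbations of the estimated variance components and checks none
#' exceeds the returned optimum.
#'
#' @param fit a `meta_fit`.
#' @param n_perturb number of perturbations.
#' @param radius log-scale perturbation magnitude.
#' @param tol slack allowed on the comparison.
#' @return TRUE if the optimum dominates all perturbations; otherwise the
#'   largest improvement found (numeric), for inspection.
#' @export
check_local_optimum <- function(fit, n_perturb = 64L, radius = 0.5,
                                tol = 1e-6) {
  stopifnot(inherits(fit, "meta_fit"))
  free <- setdiff(fit$random, names(fit$fixed_tau2))
  if (length(free) == 0L) return(TRUE)
  base <- pmax(fit$tau2, 1e-8)
  ll0 <- fit$loglik
  best_gain <- -Inf
  # deterministic quasi-random audit directions (no RNG state touched)
  dirs <- outer(seq_len(n_perturb), seq_along(free),
                function(i, k) sin(i * exp(k)) * radius)
  for (i in seq_len(n_perturb)) {
    tau2 <- base
    tau2[free] <- base[free] * exp(dirs[i, ])
    ll <- .meta_eval(tau2, fit$y, fit$X, fit$v, fit$kernels, fit$method)
    best_gain <- max(best_gain, ll - ll0)
  }
  if (best_gain <= tol) TRUE else best_gain
}
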
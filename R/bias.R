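# Publication-bias diagnostics: residual regression test within the
# multilevel model and the Rosenthal fail-safe number.

#' Regression-based publication-bias test
#'
#' Refits a multilevel meta-regression with the sampling variance (or
#' standard error) appended as an additional moderator; a significant
#' coefficient indicates small-study effects / publication bias. This is
#' the multilevel analogue of the Egger regression test, applied within
#' the established model rather than to raw effects.
#'
#' @param fit a `meta_fit` (the established model specification).
#' @param moderator `"vi"` to append the sampling variance (default) or
#'   `"sei"` for its square root.
#' @return List with `slope_v`, `t_v`, `p_v`, `df`, and the augmented
#'   `fit`. Errors if the added column is collinear with the existing
#'   design.
#' @export
regression_bias_test <- function(fit, moderator = c("vi", "sei")) {
  stopifnot(inherits(fit, "meta_fit"))
  moderator <- match.arg(moderator)
  data <- fit$data
  col <- if (moderator == "vi") ".bias_v" else ".bias_se"
  data[[col]] <- if (moderator == "vi") data[[fit$vi]] else sqrt(data[[fit$vi]])
  # collinearity check before refitting
  Xa <- cbind(fit$X, data[[col]])
  if (qr(Xa)$rank < ncol(Xa)) {
    stop("design error: ", moderator,
         " is collinear with the existing moderators", call. = FALSE)
  }
  terms0 <- attr(terms(fit$fixed), "term.labels")
  has_int <- attr(terms(fit$fixed), "intercept") == 1
  fixed_aug <- stats::reformulate(c(terms0, col), intercept = has_int)
  fit_aug <- .update_meta(fit, fixed = fixed_aug, data = data)
  b <- fit_aug$beta[col]
  se <- fit_aug$se[col]
  tval <- unname(b / se)
  list(slope_v = unname(b), t_v = tval,
       p_v = 2 * pt(-abs(tval), fit_aug$df_resid),
       df = fit_aug$df_resid, moderator = moderator, fit = fit_aug)
}

#' Rosenthal fail-safe number
#'
#' Number of unpublished null results required to bring the combined
#' one-tailed significance test down to `alpha`:
#' `N = max(0, ceiling((sum z)^2 / z_alpha^2 - k))`.
#'
#' @param z one-tailed z-scores of the k observed effects. Alternatively
#'   supply `p` (one-tailed p-values) and z is `qnorm(1 - p)`.
#' @param p optional one-tailed p-values (used if `z` missing).
#' @param alpha one-tailed significance level (default 0.05).
#' @return Nonnegative integer fail-safe N.
#' @export
failsafe_rosenthal <- function(z = NULL, p = NULL, alpha = 0.05) {
  if (is.null(z)) {
    if (is.null(p)) stop("supply z or p", call. = FALSE)
    stopifnot(all(p > 0), all(p < 1))
    z <- qnorm(1 - p)
  }
  k <- length(z)
  if (k < 1L) stop("need at least one effect", call. = FALSE)
  z_alpha <- qnorm(1 - alpha)
  n <- ceiling(sum(z)^2 / z_alpha^2 - k)
  max(0L, as.integer(n))
}

#' Fail-safe number for an effect-size table
#'
#' Converts each effect size to a one-tailed z in the direction of the
#' observed sign of the pooled evidence (`z_i = g_i / sqrt(v_i)`, signs
#' kept as-is, direction set by `direction`), then applies
#' [failsafe_rosenthal()].
#'
#' @param d effect-size table with columns `g` and `v`.
#' @param direction `"positive"`, `"negative"`, or `"auto"` (the sign of
#'   the inverse-variance weighted mean).
#' @param alpha one-tailed level.
#' @return List with `failsafe_n`, `k`, `direction`.
#' @export
failsafe_from_effects <- function(d, direction = c("auto", "positive",
                                                   "negative"),
                                  alpha = 0.05) {
  direction <- match.arg(direction)
  z <- d$g / sqrt(d$v)
  if (direction == "auto") {
    direction <- if (sum(d$g / d$v) >= 0) "positive" else "negative"
  }
  if (direction == "negative") z <- -z
  list(failsafe_n = failsafe_rosenthal(z = z, alpha = alpha),
       k = length(z), direction = direction)
}
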
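# Hedges' g standardized mean difference with unbiased sampling variance.

#' Pooled standard deviation of two arms
#'
#' `sqrt(((n_t-1) sd_t^2 + (n_c-1) sd_c^2) / (n_t + n_c - 2))`.
#'
#' @param sd_treat,sd_ctrl nonnegative standard deviations.
#' @param n_treat,n_ctrl arm sample sizes (each >= 2 for a defined SMD).
#' @return Pooled SD (vectorized). Errors if both SDs are zero anywhere
#'   (the effect size is undefined on a degenerate contrast).
#' @export
pooled_sd <- function(sd_treat, sd_ctrl, n_treat, n_ctrl) {
  stopifnot(all(sd_treat >= 0), all(sd_ctrl >= 0))
  m <- n_treat + n_ctrl - 2
  stopifnot(all(m >= 1))
  if (any(sd_treat == 0 & sd_ctrl == 0)) {
    stop("degenerate input: both arm SDs are zero; effect size undefined",
         call. = FALSE)
  }
  sqrt(((n_treat - 1) * sd_treat^2 + (n_ctrl - 1) * sd_ctrl^2) / m)
}

#' Small-sample bias correction factor
#'
#' Exact Hedges correction
#' `J(m) = Gamma(m/2) / (sqrt(m/2) Gamma((m-1)/2))` with
#' `m = n_treat + n_ctrl - 2` pooled degrees of freedom (computed on the
#' log-gamma scale for numerical stability). The familiar
#' `1 - 3/(4m - 1)` is its first-order approximation and agrees to about
#' three decimals.
#'
#' @param m pooled degrees of freedom, >= 2.
#' @return Correction factor in (0, 1).
#' @export
smd_correction <- function(m) {
  stopifnot(all(m >= 2))
  exp(lgamma(m / 2) - 0.5 * log(m / 2) - lgamma((m - 1) / 2))
}

#' Standardized mean difference (Hedges' g) with unbiased variance
#'
#' Computes `d = (mean_treat - mean_ctrl) / sd_pooled`, the bias-corrected
#' `g = J(m) d`, and Hedges' (1983) unbiased sampling-variance estimator
#' `v = (n_t + n_c) / (n_t n_c) + (1 - (m - 2) / (m J(m)^2)) g^2`.
#'
#' @param mean_treat,mean_ctrl arm means.
#' @param sd_treat,sd_ctrl arm standard deviations (>= 0, not both zero).
#' @param n_treat,n_ctrl arm sample sizes (integers >= 2).
#' @return Data frame with columns `g`, `v`, `m`, `j` (vectorized).
#' @export
smd <- function(mean_treat, mean_ctrl, sd_treat, sd_ctrl, n_treat, n_ctrl) {
  stopifnot(all(n_treat >= 2), all(n_ctrl >= 2))
  m <- n_treat + n_ctrl - 2
  sdp <- pooled_sd(sd_treat, sd_ctrl, n_treat, n_ctrl)
  d <- (mean_treat - mean_ctrl) / sdp
  j <- smd_correction(m)
  g <- j * d
  v <- (n_treat + n_ctrl) / (n_treat * n_ctrl) +
    (1 - (m - 2) / (m * j^2)) * g^2
  data.frame(g = g, v = v, m = m, j = j)
}

#' Augment an observation table with effect-size columns
#'
#' @param records validated observation data frame
#'   (see [validate_observations()]).
#' @return `records` with columns `g`, `v`, `m`, `j` appended and an
#'   `obs` factor (one level per row) for the observation-level random
#'   effect.
#' @export
add_effect_sizes <- function(records) {
  es <- smd(records$mean_treat, records$mean_ctrl,
            records$sd_treat, records$sd_ctrl,
            records$n_treat, records$n_ctrl)
  out <- cbind(records, es)
  out$obs <- out$obs_id
  out
}
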
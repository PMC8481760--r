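## Truncated-normal helpers (truncation from below only).
## Inverse-CDF transform so one baseline consumes exactly one uniform draw,
## keeping seeded streams aligned across designs.
.qtnorm <- function(u, mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(qnorm(u, mean, sd))
  plo <- pnorm(lower, mean, sd)
  qnorm(plo + u * (1 - plo), mean, sd)
}

.tnorm_mean <- function(mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(mean)
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

.tnorm_var <- function(mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(sd^2)
  a <- (lower - mean) / sd
  lam <- dnorm(a) / (1 - pnorm(a))
  sd^2 * (1 + a * lam - lam^2)
}

#' Draw baseline HbA1c values
#'
#' Samples baseline HbA1c from `N(baseline_mean, baseline_sd)` truncated below
#' at `baseline_floor` (the pilot eligibility bound), via the inverse-CDF
#' transform on the truncated region, using R's current RNG stream.
#'
#' @param n Number of subjects (>= 1).
#' @param params A [generative_params()] object.
#' @return Numeric vector of `n` baseline HbA1c values (%).
#' @examples
#' set.seed(1)
#' min(draw_baseline(1000, generative_params())) >= 7.5
#' @export
draw_baseline <- function(n, params = generative_params()) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a positive count")
  .qtnorm(runif(n), params$baseline_mean, params$baseline_sd, params$baseline_floor)
}

#' Assign latent receptiveness indicators
#'
#' Draws, for each subject, independent Bernoulli receptiveness indicators for
#' App and Nurse, and the combination indicator under the rule
#' `rc_combo = rc_app | rc_nurse | Bernoulli(q)` with the residual probability
#' `q = params$combo_residual_q`.
#'
#' @inheritParams draw_baseline
#' @return A `data.frame` with integer columns `rc_app`, `rc_nurse`,
#'   `rc_combo` (1 = receptive).
#' @export
assign_receptiveness <- function(n, params = generative_params()) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a positive count")
  rc_app <- runif(n) < params$p_receptive_app
  rc_nurse <- runif(n) < params$p_receptive_nurse
  rc_combo <- rc_app | rc_nurse | (runif(n) < params$combo_residual_q)
  data.frame(rc_app = as.integer(rc_app),
             rc_nurse = as.integer(rc_nurse),
             rc_combo = as.integer(rc_combo))
}

#' Draw stage-wise HbA1c changes
#'
#' The HbA1c reduction for a stage is normal with SD `sigma_stage` and mean
#' `mu_stage` if the subject is receptive to the treatment they received in
#' that stage, mean 0 otherwise. Positive values denote reduction; negative
#' draws (worsening) are allowed and not clipped.
#'
#' @param receptive_to_assigned Vector of 0/1 indicators: receptiveness to the
#'   treatment actually received in `stage`.
#' @param stage Stage number, 1 (weeks 0-6) or 2 (weeks 6-12).
#' @inheritParams draw_baseline
#' @return Numeric vector of HbA1c reductions, one per indicator.
#' @export
draw_stage_change <- function(receptive_to_assigned, stage,
                              params = generative_params()) {
  stopifnot(inherits(params, "generative_params"))
  if (length(stage) != 1 || !stage %in% c(1, 2))
    stop("stage must be 1 or 2")
  r <- as.integer(receptive_to_assigned)
  if (anyNA(r) || any(r != 0 & r != 1))
    stop("receptive_to_assigned must be binary 0/1")
  mu <- if (stage == 1) params$stage1_receptive_mean else params$stage2_receptive_mean
  sigma <- if (stage == 1) params$stage1_sd else params$stage2_sd
  rnorm(length(r), mean = mu * r, sd = sigma)
}
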
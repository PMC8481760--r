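#' Mean HbA1c reduction among receptive participants
#'
#' The pilot study reports marginal mean HbA1c reductions over all
#' participants. The generative model treats each stage's change as a
#' two-component mixture: receptive participants reduce by a normal draw with
#' mean `mu_stage`, non-receptive participants by a normal draw with mean 0.
#' With a receptive fraction `f`, the marginal mean is `f * mu_stage`, so the
#' receptive-group mean is recovered as `pilot_mean / f`.
#'
#' @param pilot_mean Marginal mean HbA1c reduction (percentage points) observed
#'   in the pilot cohort for the stage.
#' @param receptive_fraction Assumed fraction of the pilot cohort receptive to
#'   their intervention, in `(0, 1]`.
#' @return Mean HbA1c reduction (percentage points) for receptive subjects.
#' @examples
#' derive_receptive_means(0.92, 0.60) # ~1.53
#' @export
derive_receptive_means <- function(pilot_mean, receptive_fraction) {
  if (!is.numeric(pilot_mean) || !is.numeric(receptive_fraction))
    stop("pilot_mean and receptive_fraction must be numeric")
  if (any(receptive_fraction <= 0) || any(receptive_fraction > 1))
    stop("receptive_fraction must be in (0, 1]")
  pilot_mean / receptive_fraction
}

#' Residual combination-receptiveness probability
#'
#' Receptiveness to the stage-2 combination (App + Nurse) is modelled as
#' `rc_combo = rc_app | rc_nurse | Bernoulli(q)`: anyone receptive to either
#' single intervention is receptive to the combination, and subjects receptive
#' to neither get an independent residual chance `q`. This solves for the `q`
#' that makes the average combination receptiveness among subjects
#' non-receptive to their (equally likely App or Nurse) initial intervention
#' equal `combo_avg_target`:
#' \deqn{\tfrac12\left[(p_A + (1-p_A)q) + (p_N + (1-p_N)q)\right] = t}
#'
#' @param p_app,p_nurse Receptiveness probabilities for App and Nurse.
#' @param combo_avg_target Target average combination receptiveness among the
#'   initially non-receptive.
#' @return The residual probability `q`, clamped to `[0, 1]` (with a warning
#'   when clamping was required or the system is degenerate).
#' @examples
#' derive_combo_residual(0.51, 0.69, 0.75) # 0.375
#' @export
derive_combo_residual <- function(p_app, p_nurse, combo_avg_target) {
  stopifnot(length(p_app) == 1, length(p_nurse) == 1, length(combo_avg_target) == 1)
  if (p_app < 0 || p_app > 1 || p_nurse < 0 || p_nurse > 1 ||
      combo_avg_target < 0 || combo_avg_target > 1)
    stop("probabilities must lie in [0, 1]")
  denom <- 2 - p_app - p_nurse
  if (denom <= .Machine$double.eps) {
    warning("everyone is receptive to a single intervention; residual probability is unidentified, returning 0")
    return(0)
  }
  q <- (2 * combo_avg_target - p_app - p_nurse) / denom
  if (q < 0 || q > 1) {
    warning(sprintf("residual combination probability %.4f outside [0, 1]; clamping", q))
    q <- min(max(q, 0), 1)
  }
  q
}

#' Generative model parameters for the synthetic patient population
#'
#' Bundles and validates every distributional parameter of the synthetic
#' cohort: baseline HbA1c (normal, optionally truncated below at the pilot
#' eligibility floor), latent receptiveness to App/Nurse/combination, and the
#' stage-wise HbA1c change distributions conditional on receptiveness.
#' Defaults reproduce the pilot-anchored base case: baseline `N(9.73, 1.37)`
#' floored at 7.5, receptiveness rates 0.51 (App) and 0.69 (Nurse) drawn
#' independently, combination receptiveness averaging 0.75 among the initially
#' non-receptive, and receptive-group reductions 1.53 (SD 0.71) at stage 1 and
#' 0.94 (SD 0.77) at stage 2 (non-receptive means are 0 with the same SDs).
#'
#' @param baseline_mean,baseline_sd Mean and SD of baseline HbA1c (%).
#' @param baseline_floor Eligibility lower bound for baseline HbA1c (%); the
#'   baseline distribution is truncated below at this value. Use `-Inf` (or
#'   `NA`) to disable truncation.
#' @param p_receptive_app,p_receptive_nurse Receptiveness probabilities.
#' @param combo_avg_target Average combination receptiveness among subjects
#'   non-receptive to their initial intervention.
#' @param combo_residual_q Residual combination-receptiveness probability for
#'   subjects receptive to neither single intervention. Default: derived from
#'   `combo_avg_target` via [derive_combo_residual()].
#' @param stage1_receptive_mean,stage1_sd Stage-1 (weeks 0-6) HbA1c reduction
#'   distribution for receptive subjects; non-receptive subjects use mean 0
#'   with the same SD.
#' @param stage2_receptive_mean,stage2_sd Stage-2 (weeks 6-12) analogue.
#' @param pilot_stage1_mean,pilot_stage2_mean Marginal pilot-cohort mean
#'   reductions the receptive-group means are derived from (bookkeeping; used
#'   for the consistency check `receptive_mean * fraction == pilot mean`).
#' @param assumed_receptive_fraction Receptive fraction assumed for the pilot
#'   cohort when splitting its marginal means.
#' @return An object of class `generative_params` (a validated named list).
#' @examples
#' gp <- generative_params()
#' gp$combo_residual_q # 0.375
#' @export
generative_params <- function(baseline_mean = 9.73,
                              baseline_sd = 1.37,
                              baseline_floor = 7.5,
                              p_receptive_app = 0.51,
                              p_receptive_nurse = 0.69,
                              combo_avg_target = 0.75,
                              combo_residual_q = NULL,
                              stage1_receptive_mean = 1.53,
                              stage1_sd = 0.71,
                              stage2_receptive_mean = 0.94,
                              stage2_sd = 0.77,
                              pilot_stage1_mean = 0.92,
                              pilot_stage2_mean = 0.56,
                              assumed_receptive_fraction = 0.60) {
  if (is.null(baseline_floor) || is.na(baseline_floor)) baseline_floor <- -Inf
  for (k in c("p_receptive_app", "p_receptive_nurse", "combo_avg_target")) {
    v <- get(k)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("parameter '", k, "' must be a probability in [0, 1]")
  }
  if (is.null(combo_residual_q))
    combo_residual_q <- derive_combo_residual(p_receptive_app, p_receptive_nurse,
                                              combo_avg_target)
  p <- list(baseline_mean = baseline_mean,
            baseline_sd = baseline_sd,
            baseline_floor = baseline_floor,
            p_receptive_app = p_receptive_app,
            p_receptive_nurse = p_receptive_nurse,
            combo_avg_target = combo_avg_target,
            combo_residual_q = combo_residual_q,
            stage1_receptive_mean = stage1_receptive_mean,
            stage1_sd = stage1_sd,
            stage2_receptive_mean = stage2_receptive_mean,
            stage2_sd = stage2_sd,
            pilot_stage1_mean = pilot_stage1_mean,
            pilot_stage2_mean = pilot_stage2_mean,
            assumed_receptive_fraction = assumed_receptive_fraction)
  class(p) <- "generative_params"
  validate_generative_params(p)
}

#' @rdname generative_params
#' @param params A `generative_params` object to re-validate (e.g. after
#'   manual modification).
#' @export
validate_generative_params <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  probs <- c("p_receptive_app", "p_receptive_nurse", "combo_avg_target",
             "combo_residual_q", "assumed_receptive_fraction")
  for (k in probs) {
    v <- params[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("parameter '", k, "' must be a probability in [0, 1]")
  }
  for (k in c("baseline_sd", "stage1_sd", "stage2_sd")) {
    v <- params[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("parameter '", k, "' must be a positive SD")
  }
  if (params$assumed_receptive_fraction == 0)
    stop("assumed_receptive_fraction must be positive")
  if (params$baseline_floor >= params$baseline_mean)
    stop("baseline_floor must lie below baseline_mean")
  ## receptive-group means must be consistent with the pilot marginal means
  for (s in 1:2) {
    rm <- params[[sprintf("stage%d_receptive_mean", s)]]
    pm <- params[[sprintf("pilot_stage%d_mean", s)]]
    if (abs(round(rm * params$assumed_receptive_fraction, 2) - round(pm, 2)) > 0.005 + 1e-9)
      warning(sprintf(
        "stage-%d receptive mean %.3f x fraction %.2f does not reproduce the pilot mean %.2f to 2 decimals",
        s, rm, params$assumed_receptive_fraction, pm))
  }
  params
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Generative model parameters (synthetic insulin-titration cohort)\n")
  cat(sprintf("  baseline HbA1c : N(%.2f, %.2f)%s\n", x$baseline_mean, x$baseline_sd,
              if (is.finite(x$baseline_floor))
                sprintf(", truncated below at %.2f", x$baseline_floor) else ""))
  cat(sprintf("  receptiveness  : App %.2f, Nurse %.2f (independent); combo residual q = %.3f (target avg %.2f)\n",
              x$p_receptive_app, x$p_receptive_nurse, x$combo_residual_q, x$combo_avg_target))
  cat(sprintf("  stage 1 change : receptive N(%.2f, %.2f), non-receptive N(0, %.2f)\n",
              x$stage1_receptive_mean, x$stage1_sd, x$stage1_sd))
  cat(sprintf("  stage 2 change : receptive N(%.2f, %.2f), non-receptive N(0, %.2f)\n",
              x$stage2_receptive_mean, x$stage2_sd, x$stage2_sd))
  invisible(x)
}
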
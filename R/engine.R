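#' Single-trial design configuration
#'
#' @param design `"SMART"` or `"RCT"`.
#' @param n Trial size (>= 2 for SMART, >= 4 for RCT).
#' @param delta Response threshold, percentage points of HbA1c reduction.
#' @param allocation `"BALANCED"` (exact 1:1 via permutation) or
#'   `"BERNOULLI"` (independent coin per subject).
#' @param seed Integer seed for the trial's random stream.
#' @return An object of class `design_config`.
#' @export
design_config <- function(design = c("SMART", "RCT"), n = 100, delta = 0.5,
                          allocation = c("BALANCED", "BERNOULLI"), seed = 1L) {
  design <- match.arg(design)
  allocation <- match.arg(allocation)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n != round(n))
    stop("n must be an integer count")
  if (design == "SMART" && n < 2) stop("SMART requires n >= 2")
  if (design == "RCT" && n < 4) stop("RCT requires n >= 4 (one subject per arm)")
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta))
    stop("delta must be a single number")
  structure(list(design = design, n = as.integer(n), delta = delta,
                 allocation = allocation, seed = as.integer(seed)),
            class = "design_config")
}

## Vectorized simulation of B trials of n subjects in one pass.
##
## Random stream layout per block (fixed draw order so that SMART and RCT runs
## from the same seed share the identical population): baseline uniforms,
## rc_app, rc_nurse, residual-combo uniforms, stage-1 noise, stage-2 noise,
## allocation uniforms; design-specific draws (permutation labels, SMART
## stage-2 coins) come last.
.simulate_block <- function(design, B, n, delta, gen, costs, allocation,
                            seed, keep_records = FALSE) {
  set.seed(seed)
  B <- as.integer(B); n <- as.integer(n)
  N <- B * n
  trial <- rep.int(seq_len(B), rep.int(n, B))

  y0 <- .qtnorm(runif(N), gen$baseline_mean, gen$baseline_sd, gen$baseline_floor)
  rc_a <- runif(N) < gen$p_receptive_app
  rc_n <- runif(N) < gen$p_receptive_nurse
  rc_c <- rc_a | rc_n | (runif(N) < gen$combo_residual_q)
  e1 <- rnorm(N, 0, gen$stage1_sd)
  e2 <- rnorm(N, 0, gen$stage2_sd)
  u_alloc <- runif(N)

  if (design == "SMART") {
    grp <- .alloc_groups(u_alloc, B, n, k = 2L, scheme = allocation)
    s1 <- ifelse(grp == 1L, .TX_NURSE, .TX_APP)
    arm <- rep(NA_integer_, N)
  } else {
    arm <- .alloc_groups(u_alloc, B, n, k = 4L, scheme = allocation)
    s1 <- ifelse(arm <= 2L, .TX_NURSE, .TX_APP)
  }

  rc1 <- ifelse(s1 == .TX_APP, rc_a, rc_n)
  d1 <- gen$stage1_receptive_mean * rc1 + e1
  resp <- d1 >= delta

  if (design == "SMART") {
    coin <- runif(N) < 0.5
    s2 <- ifelse(resp, s1, ifelse(coin, 3L - s1, .TX_COMBO))
  } else {
    ns2 <- c(.TX_APP, .TX_COMBO, .TX_NURSE, .TX_COMBO)[arm]
    s2 <- ifelse(resp, s1, ns2)
  }

  rc2 <- ifelse(s2 == .TX_APP, rc_a, ifelse(s2 == .TX_NURSE, rc_n, rc_c))
  d2 <- gen$stage2_receptive_mean * rc2 + e2
  y <- y0 - d1 - d2

  stage_cost <- c(costs$app, costs$nurse, costs$combo)
  cost <- costs$monitoring + stage_cost[s1] + stage_cost[s2] +
    if (design == "SMART") costs$rerandomization * !resp else 0

  ## per-trial overall means
  dt <- data.table(trial = trial, y = y, cost = cost)
  overall <- dt[, list(ybar = mean(y), costbar = mean(cost)), by = "trial"]

  ## per-trial, per-AI estimates
  if (design == "SMART") {
    idx_r <- which(resp); idx_nr <- which(!resp)
    ai_nr <- .ai_of_nonresponder(s1[idx_nr], s2[idx_nr])
    long <- data.table(
      trial = c(trial[idx_r], trial[idx_r], trial[idx_nr]),
      ai = c(ifelse(s1[idx_r] == .TX_NURSE, 1L, 3L),
             ifelse(s1[idx_r] == .TX_NURSE, 2L, 4L),
             ai_nr),
      w = c(rep.int(2, 2L * length(idx_r)), rep.int(4, length(idx_nr))),
      y = c(y[idx_r], y[idx_r], y[idx_nr]))
    est <- long[, list(est_hajek = sum(w * y) / sum(w),
                       est_ht = sum(w * y) / n,
                       m = .N), by = c("trial", "ai")]
  } else {
    est <- data.table(trial = trial, ai = arm, y = y)[
      , list(est_hajek = mean(y), est_ht = mean(y), m = .N),
      by = c("trial", "ai")]
  }

  estm <- matrix(NA_real_, nrow = B, ncol = 4L)
  estm[cbind(est$trial, est$ai)] <- est$est_hajek
  est_ht <- matrix(NA_real_, nrow = B, ncol = 4L)
  est_ht[cbind(est$trial, est$ai)] <- est$est_ht
  cntm <- matrix(0L, nrow = B, ncol = 4L)
  cntm[cbind(est$trial, est$ai)] <- est$m

  out <- list(B = B, n = n,
              trial = overall$trial, ybar = overall$ybar,
              costbar = overall$costbar,
              estimates = estm, estimates_ht = est_ht, counts = cntm)

  if (keep_records) {
    out$records <- data.table(
      trial = trial,
      baseline = y0,
      rc_app = as.integer(rc_a), rc_nurse = as.integer(rc_n),
      rc_combo = as.integer(rc_c),
      stage1_tx = .TX_LABELS[s1],
      delta1 = d1,
      responder = as.integer(resp),
      stage2_tx = .TX_LABELS[s2],
      delta2 = d2,
      final_y = y,
      assigned_arm = arm,
      cost = cost)
  }
  out
}

## run one trial through the block engine and package the results
.run_trial <- function(config, gen, costs) {
  blk <- .simulate_block(config$design, B = 1L, n = config$n,
                         delta = config$delta, gen = gen, costs = costs,
                         allocation = config$allocation, seed = config$seed,
                         keep_records = TRUE)
  records <- blk$records[, -1]            # drop trial id for a single trial
  estimates <- if (config$design == "SMART") {
    ipw_estimates_smart(records)
  } else {
    arm_means_rct(records)
  }
  structure(list(design = config$design, config = config,
                 records = records, estimates = estimates),
            class = "trial_result")
}

#' Run one simulated SMART trial
#'
#' Generates `config$n` synthetic subjects, randomizes stage 1 between Nurse
#' and App, classifies response at week 6 against `config$delta`,
#' re-randomizes non-responders 1:1 between the switch and combination
#' options, draws the stage-2 change according to receptiveness to the
#' received treatment, and accumulates outcomes and costs.
#'
#' @param config A [design_config()] with `design = "SMART"`.
#' @param gen A [generative_params()] object.
#' @param costs A [cost_table()].
#' @return A `trial_result`: list with `records` (one row per subject),
#'   `estimates` (IPW estimates of the four embedded AIs), `design`, `config`.
#' @export
run_smart_trial <- function(config, gen = generative_params(),
                            costs = default_cost_table(gen)) {
  stopifnot(inherits(config, "design_config"))
  if (config$design != "SMART") stop("config$design must be 'SMART'")
  .run_trial(config, gen, costs)
}

#' Run one simulated four-arm RCT trial
#'
#' As [run_smart_trial()] but subjects are allocated 1:1:1:1 to the four
#' adaptive-intervention arms at baseline; the same week-6 response rule is
#' applied, and non-responders switch to their arm's prespecified stage-2
#' treatment (no re-randomization).
#'
#' @param config A [design_config()] with `design = "RCT"`.
#' @inheritParams run_smart_trial
#' @return A `trial_result` (see [run_smart_trial()]); `estimates` are arm
#'   means.
#' @export
run_rct_trial <- function(config, gen = generative_params(),
                          costs = default_cost_table(gen)) {
  stopifnot(inherits(config, "design_config"))
  if (config$design != "RCT") stop("config$design must be 'RCT'")
  .run_trial(config, gen, costs)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Simulated %s trial: n = %d, delta = %.2f, seed = %d\n",
              x$design, x$config$n, x$config$delta, x$config$seed))
  cat(sprintf("  responders: %d / %d\n", sum(x$records$responder),
              nrow(x$records)))
  cat("  per-AI estimates of E(Y):\n")
  print(round(x$estimates$mean_y, 4))
  cat(sprintf("  best AI: %d\n", x$estimates$best_ai))
  invisible(x)
}
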
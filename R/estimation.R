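## analytic responder probabilities under the generative model
## r1/r0: P(delta1 >= delta | receptive / non-receptive to stage-1 treatment)
.responder_rates <- function(gen, delta) {
  r1 <- 1 - pnorm((delta - gen$stage1_receptive_mean) / gen$stage1_sd)
  r0 <- 1 - pnorm(delta / gen$stage1_sd)
  list(r1 = r1, r0 = r0,
       r_nurse = gen$p_receptive_nurse * r1 + (1 - gen$p_receptive_nurse) * r0,
       r_app = gen$p_receptive_app * r1 + (1 - gen$p_receptive_app) * r0)
}

.ai_estimates <- function(mean_y, n_consistent, weight_sum = NULL) {
  unavailable <- n_consistent == 0L
  mean_y[unavailable] <- NA_real_
  best <- tryCatch(select_best_ai(mean_y), error = function(e) NA_integer_)
  structure(list(mean_y = mean_y, n_consistent = n_consistent,
                 weight_sum = weight_sum, unavailable = unavailable,
                 best_ai = best),
            class = "ai_estimates")
}

#' IPW estimates of the embedded adaptive interventions from SMART records
#'
#' Each subject's observed pathway is consistent with one embedded AI
#' (non-responders, randomized twice with probability 1/2 each) or two
#' (responders, randomized once), so inverse-probability weights are 4 and 2
#' respectively. The default estimator is the self-normalized (Hajek) form
#' `sum(w*y) / sum(w)` over the subjects consistent with each AI, which is
#' bounded by the observed outcomes; `method = "ht"` gives the
#' Horvitz-Thompson form `sum(w*y) / n`.
#'
#' @param records SMART subject records (columns `stage1_tx`, `responder`,
#'   `stage2_tx`, `final_y`).
#' @param method `"hajek"` (default) or `"ht"`.
#' @return An `ai_estimates` object: `mean_y` (length 4, `NA` where an AI has
#'   no consistent subjects), `n_consistent`, `unavailable` flags, `best_ai`
#'   (argmin over available estimates, ties to the lowest index).
#' @examples
#' rec <- data.frame(stage1_tx = c("NURSE", "NURSE"), responder = c(1, 0),
#'                   stage2_tx = c("NURSE", "APP"), final_y = c(8, 9))
#' ipw_estimates_smart(rec)$mean_y[1] # (2*8 + 4*9) / 6
#' @export
ipw_estimates_smart <- function(records, method = c("hajek", "ht")) {
  method <- match.arg(method)
  n <- nrow(records)
  ais <- consistent_ais(records)
  w <- ifelse(records$responder == 1L, 2, 4)
  len <- lengths(ais)
  ai <- unlist(ais, use.names = FALSE)
  wi <- rep.int(w, len)
  yi <- rep.int(records$final_y, len)
  num <- as.vector(tapply(wi * yi, factor(ai, levels = 1:4), sum, default = 0))
  den <- as.vector(tapply(wi, factor(ai, levels = 1:4), sum, default = 0))
  cnt <- as.integer(tabulate(ai, nbins = 4L))
  mean_y <- if (method == "hajek") num / den else num / n
  mean_y[cnt == 0L] <- NA_real_
  .ai_estimates(mean_y, cnt, weight_sum = den)
}

#' Arm means of the four adaptive-intervention arms of the RCT
#'
#' @param records RCT subject records (columns `assigned_arm`, `final_y`).
#' @return An `ai_estimates` object (see [ipw_estimates_smart()]).
#' @export
arm_means_rct <- function(records) {
  arm <- factor(records$assigned_arm, levels = 1:4)
  mean_y <- as.vector(tapply(records$final_y, arm, mean))
  cnt <- as.integer(tabulate(records$assigned_arm, nbins = 4L))
  mean_y[cnt == 0L] <- NA_real_
  .ai_estimates(mean_y, cnt)
}

#' Select the best adaptive intervention
#'
#' Argmin over the available per-AI mean-outcome estimates (HbA1c: lower is
#' better); ties break to the lowest AI index; `NA` estimates (empty strata)
#' are excluded.
#'
#' @param estimates Numeric vector of 4 per-AI estimates (may contain `NA`),
#'   or an `ai_estimates` object.
#' @return The selected AI index (1-4).
#' @export
select_best_ai <- function(estimates) {
  if (inherits(estimates, "ai_estimates")) estimates <- estimates$mean_y
  if (all(is.na(estimates))) stop("no available AI estimates to select from")
  which.min(estimates)                      # NA ignored; ties -> lowest index
}

#' @export
print.ai_estimates <- function(x, ...) {
  cat("Per-AI estimates of E(Y) (final HbA1c, %)\n")
  tab <- data.frame(AI = 1:4, estimate = round(x$mean_y, 4),
                    n_consistent = x$n_consistent)
  print(tab, row.names = FALSE)
  cat(sprintf("  best AI: %s\n", x$best_ai))
  invisible(x)
}

#' Monte Carlo operating characteristics of a trial design
#'
#' Simulates `B` independent replicate trials (each of size `n`) and
#' aggregates the per-trial statistics: the Monte Carlo mean
#' `ytilde = sum(ybar_b) / B` and SD `s = sqrt(sum((ybar_b - ytilde)^2) /
#' (B - 1))` of the per-trial overall mean final HbA1c and of each per-AI
#' estimate, the per-AI selection frequencies, and mean/SD of per-trial mean
#' cost. Replicates are simulated in vectorized blocks whose seeds are spawned
#' deterministically from `master_seed`, so results are reproducible and the
#' two designs share identical populations when given the same seed.
#'
#' @param design `"SMART"` or `"RCT"`.
#' @param n Trial size.
#' @param B Number of replicate trials (>= 2).
#' @param delta Response threshold.
#' @param gen A [generative_params()] object.
#' @param costs A [cost_table()].
#' @param master_seed Integer master seed.
#' @param allocation Allocation scheme, see [design_config()].
#' @param ipw_method `"hajek"` or `"ht"` (SMART only).
#' @param keep_trials If `TRUE`, attach the per-trial statistics table.
#' @param chunk_b Replicates per vectorized block (memory knob; the default
#'   keeps blocks near 2e6 subjects). Results do not depend on it... except
#'   through the RNG stream layout, so it is fixed deterministically from `n`.
#' @return An object of class `mc_summary`.
#' @export
run_monte_carlo <- function(design = c("SMART", "RCT"), n = 100, B = 10000,
                            delta = 0.5, gen = generative_params(),
                            costs = default_cost_table(gen),
                            master_seed = 1L,
                            allocation = c("BALANCED", "BERNOULLI"),
                            ipw_method = c("hajek", "ht"),
                            keep_trials = FALSE, chunk_b = NULL) {
  design <- match.arg(design)
  allocation <- match.arg(allocation)
  ipw_method <- match.arg(ipw_method)
  if (!is.numeric(B) || length(B) != 1 || B < 2)
    stop("B must be at least 2 (the Monte Carlo SD needs two replicates)")
  cfg_check <- design_config(design, n = n, delta = delta,
                             allocation = allocation, seed = 1L) # validates n
  n <- cfg_check$n; B <- as.integer(B)
  if (is.null(chunk_b)) chunk_b <- max(1L, as.integer(2e6 %/% n))
  n_chunks <- ceiling(B / chunk_b)
  set.seed(master_seed)
  chunk_seeds <- sample.int(2147483646L, n_chunks)
  sizes <- rep.int(chunk_b, n_chunks)
  sizes[n_chunks] <- B - chunk_b * (n_chunks - 1L)

  ybar <- numeric(B); costbar <- numeric(B)
  estm <- matrix(NA_real_, B, 4L); cntm <- matrix(0L, B, 4L)
  off <- 0L
  for (i in seq_len(n_chunks)) {
    blk <- .simulate_block(design, B = sizes[i], n = n, delta = delta,
                           gen = gen, costs = costs, allocation = allocation,
                           seed = chunk_seeds[i])
    idx <- off + seq_len(sizes[i])
    ybar[idx] <- blk$ybar
    costbar[idx] <- blk$costbar
    estm[idx, ] <- if (ipw_method == "hajek") blk$estimates else blk$estimates_ht
    cntm[idx, ] <- blk$counts
    off <- off + sizes[i]
  }

  em <- estm; em[is.na(em)] <- Inf
  best <- max.col(-em, ties.method = "first")
  best[!is.finite(em[cbind(seq_len(B), best)])] <- NA_integer_
  n_selectable <- sum(!is.na(best))

  out <- structure(list(
    design = design, n = n, B = B, delta = delta, allocation = allocation,
    ipw_method = if (design == "SMART") ipw_method else "arm_mean",
    master_seed = as.integer(master_seed),
    y_tilde_overall = mean(ybar),
    s_overall = sd(ybar),
    y_tilde_ai = colMeans(estm, na.rm = TRUE),
    s_ai = apply(estm, 2, sd, na.rm = TRUE),
    p_opt = tabulate(best, nbins = 4L) / n_selectable,
    cost_mean = mean(costbar),
    cost_sd = sd(costbar),
    n_unavailable = colSums(cntm == 0L),
    n_no_selection = B - n_selectable), class = "mc_summary")
  if (keep_trials)
    out$trials <- data.table(trial = seq_len(B), ybar = ybar,
                             costbar = costbar,
                             est_ai1 = estm[, 1], est_ai2 = estm[, 2],
                             est_ai3 = estm[, 3], est_ai4 = estm[, 4],
                             best_ai = best)
  out
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary: %s design, n = %d, B = %d, delta = %.2f\n",
              x$design, x$n, x$B, x$delta))
  cat(sprintf("  overall Y : %.2f (%.2f)\n", x$y_tilde_overall, x$s_overall))
  cat(sprintf("  cost (USD): %.2f (%.2f)\n", x$cost_mean, x$cost_sd))
  for (j in 1:4)
    cat(sprintf("  AI%d: Y = %.2f (%.2f), p_opt = %5.2f%%\n", j,
                x$y_tilde_ai[j], x$s_ai[j], 100 * x$p_opt[j]))
  if (x$n_no_selection > 0 || any(x$n_unavailable > 0))
    cat(sprintf("  empty strata: %s trials per AI; %d trials with no selection\n",
                paste(x$n_unavailable, collapse = "/"), x$n_no_selection))
  invisible(x)
}

#' Closed-form expected final HbA1c of each adaptive intervention
#'
#' Exact expectations under the generative model by total-probability
#' decomposition, with no simulation: the truncated-normal baseline mean,
#' minus the expected stage-1 reduction `P(receptive to stage-1) * mu1`,
#' minus the expected stage-2 reduction summed over receptiveness x
#' responder-status branches. For switch rules the stage-2 receptiveness
#' probability is the other intervention's marginal rate (independence); for
#' combination rules it is 1 for subjects receptive to the stage-1 treatment
#' and `p_other + (1 - p_other) * q` otherwise.
#'
#' Serves as the independent oracle for the unbiasedness of both designs'
#' estimators.
#'
#' @param gen A [generative_params()] object.
#' @param delta Response threshold.
#' @return Named numeric vector `c(AI1, AI2, AI3, AI4)` of expected final
#'   HbA1c, with attributes `baseline_mean` (truncated-normal mean),
#'   `overall` (expected overall mean under either design's 1:1 stage-1
#'   split), and `best_ai`.
#' @export
analytic_expectations <- function(gen = generative_params(), delta = 0.5) {
  stopifnot(inherits(gen, "generative_params"))
  ey0 <- .tnorm_mean(gen$baseline_mean, gen$baseline_sd, gen$baseline_floor)
  rr <- .responder_rates(gen, delta)
  mu1 <- gen$stage1_receptive_mean; mu2 <- gen$stage2_receptive_mean
  q <- gen$combo_residual_q
  pA <- gen$p_receptive_app; pN <- gen$p_receptive_nurse

  ## E(delta2) for one AI: stage-1 receptiveness prob pT, stage-2 receptive
  ## probability given rc_T = 1 / 0
  e_d2 <- function(pT, p2_1, p2_0) {
    mu2 * (pT * (rr$r1 * 1 + (1 - rr$r1) * p2_1) +
             (1 - pT) * (rr$r0 * 0 + (1 - rr$r0) * p2_0))
  }
  combo_given_not <- function(p_other) p_other + (1 - p_other) * q
  ey <- c(
    AI1 = ey0 - pN * mu1 - e_d2(pN, pA, pA),
    AI2 = ey0 - pN * mu1 - e_d2(pN, 1, combo_given_not(pA)),
    AI3 = ey0 - pA * mu1 - e_d2(pA, pN, pN),
    AI4 = ey0 - pA * mu1 - e_d2(pA, 1, combo_given_not(pN)))

  ## overall mean under either design: 1:1 stage-1 split, non-responders
  ## split 1:1 between switch and combination
  overall <- ey0 - (pN + pA) / 2 * mu1 -
    0.5 * (e_d2(pN, (pA + 1) / 2, (pA + combo_given_not(pA)) / 2) +
             e_d2(pA, (pN + 1) / 2, (pN + combo_given_not(pN)) / 2))
  attr(ey, "baseline_mean") <- ey0
  attr(ey, "overall") <- overall
  attr(ey, "best_ai") <- which.min(ey)
  ey
}
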
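## Independent oracles used across the test files. These deliberately avoid
## the package's engine and inverse-CDF sampling paths: truncation is done by
## rejection, receptiveness with rbinom, and each adaptive intervention is
## followed directly as a per-subject rule.

## mean outcome of one adaptive intervention followed by every subject
oracle_regime <- function(ai, n, gen = generative_params(), delta = 0.5) {
  defs <- ai_definitions()
  s1 <- defs$stage1[ai]
  ns2 <- defs$nonresponder_stage2[ai]

  y0 <- numeric(0)
  while (length(y0) < n) {
    cand <- rnorm(n, gen$baseline_mean, gen$baseline_sd)
    y0 <- c(y0, cand[cand >= gen$baseline_floor])
  }
  y0 <- y0[seq_len(n)]

  rc <- list(APP = rbinom(n, 1, gen$p_receptive_app),
             NURSE = rbinom(n, 1, gen$p_receptive_nurse))
  rc$COMBO <- as.integer(rc$APP | rc$NURSE | rbinom(n, 1, gen$combo_residual_q))

  d1 <- rnorm(n, gen$stage1_receptive_mean * rc[[s1]], gen$stage1_sd)
  resp <- d1 >= delta
  s2 <- ifelse(resp, s1, ns2)
  rc2 <- ifelse(s2 == "APP", rc$APP, ifelse(s2 == "NURSE", rc$NURSE, rc$COMBO))
  d2 <- rnorm(n, gen$stage2_receptive_mean * rc2, gen$stage2_sd)
  y <- y0 - d1 - d2
  list(mean = mean(y), se = sd(y) / sqrt(n))
}

## average combination receptiveness among subjects non-receptive to their
## (equally likely) initial intervention, by enumeration over the four
## (rc_app, rc_nurse) cells under the rule rc_combo = rc_a | rc_n | Bern(q)
oracle_combo_average <- function(p_app, p_nurse, q) {
  cells <- expand.grid(a = 0:1, n = 0:1)
  cells$p <- ifelse(cells$a == 1, p_app, 1 - p_app) *
    ifelse(cells$n == 1, p_nurse, 1 - p_nurse)
  cells$p_combo <- ifelse(cells$a == 1 | cells$n == 1, 1, q)
  ## initially on App (and non-receptive to it): condition on a == 0
  on_app <- with(cells[cells$a == 0, ], sum(p * p_combo) / sum(p))
  on_nurse <- with(cells[cells$n == 0, ], sum(p * p_combo) / sum(p))
  (on_app + on_nurse) / 2
}
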
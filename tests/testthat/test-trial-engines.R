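test_that("response classification is inclusive at the threshold", {
  expect_identical(classify_response(c(0.92, 0.5, 0.49), 0.5), c(1L, 1L, 0L))
})

test_that("stage-1 allocation honours the scheme", {
  set.seed(11)
  a <- allocate_stage1(100, "BALANCED")
  expect_equal(sort(as.vector(table(a))), c(50, 50))
  odd <- allocate_stage1(3, "BALANCED")
  expect_setequal(unique(odd), c("NURSE", "APP"))
  expect_equal(sort(as.vector(table(odd))), c(1, 2))
  bern <- allocate_stage1(2e5, "BERNOULLI")
  expect_lt(abs(mean(bern == "APP") - 0.5), 3 * 0.5 / sqrt(2e5))
  expect_error(allocate_stage1(1), "at least 2")
})

test_that("four-arm allocation is 1:1:1:1 with near-equal blocks", {
  set.seed(12)
  arms <- rct_allocate(100, "BALANCED")
  expect_equal(as.vector(table(factor(arms, levels = 1:4))), rep(25L, 4))
  a7 <- rct_allocate(7, "BALANCED")
  cnt <- tabulate(a7, 4)
  expect_lte(diff(range(cnt)), 1L)
  # over repeated odd-n allocations the surplus arm is not systematic
  surplus <- replicate(200, which.max(tabulate(rct_allocate(5, "BALANCED"), 4)))
  expect_gt(length(unique(surplus)), 1)
  bern <- rct_allocate(2e5, "BERNOULLI")
  expect_lt(max(abs(tabulate(bern, 4) / 2e5 - 0.25)), 3 * sqrt(0.25 * 0.75 / 2e5))
  expect_error(rct_allocate(3, "BALANCED"), "at least 4")
})

test_that("SMART stage-2 reassignment: continuation and fair re-randomization", {
  expect_identical(smart_reassign("NURSE", 1), "NURSE")
  expect_identical(smart_reassign("APP", 1), "APP")
  set.seed(13)
  s2 <- smart_reassign(rep("NURSE", 2e5), rep(0, 2e5))
  expect_setequal(unique(s2), c("APP", "COMBO"))
  expect_lt(abs(mean(s2 == "APP") - 0.5), 3 * 0.5 / sqrt(2e5))
  s2a <- smart_reassign(rep("APP", 1000), rep(0, 1000))
  expect_setequal(unique(s2a), c("NURSE", "COMBO"))
  expect_error(smart_reassign("COMBO", 0), "stage-1")
})

test_that("SMART records satisfy the structural subject-level invariants", {
  cfg <- design_config("SMART", n = 200, delta = 0.5, seed = 21)
  tr <- run_smart_trial(cfg)
  rec <- tr$records
  expect_equal(nrow(rec), 200)
  expect_equal(rec$final_y, rec$baseline - rec$delta1 - rec$delta2)
  expect_identical(rec$responder, as.integer(rec$delta1 >= 0.5))
  expect_true(all(rec$stage2_tx[rec$responder == 1] ==
                    rec$stage1_tx[rec$responder == 1]))
  expect_true(all(rec$stage2_tx[rec$responder == 0] !=
                    rec$stage1_tx[rec$responder == 0]))
  expect_false(any(rec$stage1_tx == "COMBO"))
  # responders are consistent with exactly two embedded AIs, non-responders one
  ais <- consistent_ais(rec)
  expect_identical(lengths(ais), ifelse(rec$responder == 1, 2L, 1L))
  expect_true(all(unlist(ais) %in% 1:4))
})

test_that("RCT records follow the arm's prespecified stage-2 rule", {
  cfg <- design_config("RCT", n = 100, delta = 0.5, seed = 22)
  tr <- run_rct_trial(cfg)
  rec <- tr$records
  expect_equal(as.vector(table(factor(rec$assigned_arm, levels = 1:4))), rep(25L, 4))
  defs <- ai_definitions()
  expect_identical(rec$stage1_tx, defs$stage1[rec$assigned_arm])
  nr <- rec$responder == 0
  expect_identical(rec$stage2_tx[nr], defs$nonresponder_stage2[rec$assigned_arm[nr]])
  expect_identical(rec$stage2_tx[!nr], rec$stage1_tx[!nr])
})

test_that("consistent_ais maps pathways to Table-1 rules and rejects bad records", {
  rec <- data.frame(stage1_tx = c("NURSE", "APP", "NURSE", "NURSE", "APP", "APP"),
                    responder = c(1, 1, 0, 0, 0, 0),
                    stage2_tx = c("NURSE", "APP", "APP", "COMBO", "NURSE", "COMBO"))
  ais <- consistent_ais(rec)
  expect_identical(ais, list(c(1L, 2L), c(3L, 4L), 1L, 2L, 3L, 4L))
  bad <- data.frame(stage1_tx = "NURSE", responder = 1, stage2_tx = "APP")
  expect_error(consistent_ais(bad), "inconsistent")
})

test_that("same seed gives SMART and RCT identical populations", {
  g <- generative_params(); ct <- default_cost_table(g)
  s <- smartsim:::.simulate_block("SMART", B = 5, n = 40, delta = 0.5, gen = g,
                                  costs = ct, allocation = "BALANCED",
                                  seed = 777, keep_records = TRUE)$records
  r <- smartsim:::.simulate_block("RCT", B = 5, n = 40, delta = 0.5, gen = g,
                                  costs = ct, allocation = "BALANCED",
                                  seed = 777, keep_records = TRUE)$records
  expect_identical(s$baseline, r$baseline)
  expect_identical(s[, c("rc_app", "rc_nurse", "rc_combo")],
                   r[, c("rc_app", "rc_nurse", "rc_combo")])
})

test_that("engine per-trial estimates agree with the record-level estimators", {
  g <- generative_params(); ct <- default_cost_table(g)
  blk <- smartsim:::.simulate_block("SMART", B = 4, n = 60, delta = 0.5,
                                    gen = g, costs = ct,
                                    allocation = "BALANCED", seed = 31,
                                    keep_records = TRUE)
  for (b in 1:4) {
    rec <- blk$records[blk$records$trial == b, ]
    est <- ipw_estimates_smart(rec)
    expect_equal(unname(blk$estimates[b, ]), unname(est$mean_y))
    est_ht <- ipw_estimates_smart(rec, method = "ht")
    expect_equal(unname(blk$estimates_ht[b, ]), unname(est_ht$mean_y))
  }
  blk_r <- smartsim:::.simulate_block("RCT", B = 3, n = 60, delta = 0.5,
                                      gen = g, costs = ct,
                                      allocation = "BALANCED", seed = 32,
                                      keep_records = TRUE)
  for (b in 1:3) {
    rec <- blk_r$records[blk_r$records$trial == b, ]
    expect_equal(unname(blk_r$estimates[b, ]), unname(arm_means_rct(rec)$mean_y))
  }
})

test_that("threshold extremes degenerate as expected", {
  g <- generative_params(); ct <- default_cost_table(g)
  lo <- run_smart_trial(design_config("SMART", n = 50, delta = -1e9, seed = 41),
                        g, ct)$records
  expect_true(all(lo$responder == 1) && all(lo$stage2_tx == lo$stage1_tx))
  hi <- run_smart_trial(design_config("SMART", n = 50, delta = 1e9, seed = 41),
                        g, ct)$records
  expect_true(all(hi$responder == 0) && all(hi$stage2_tx != hi$stage1_tx))
  hr <- run_rct_trial(design_config("RCT", n = 40, delta = 1e9, seed = 42),
                      g, ct)$records
  defs <- ai_definitions()
  expect_identical(hr$stage2_tx, defs$nonresponder_stage2[hr$assigned_arm])
})

test_that("no-effect, no-noise settings leave outcomes at baseline", {
  g <- generative_params(p_receptive_app = 0, p_receptive_nurse = 0,
                         combo_avg_target = 0, stage1_sd = 1e-12,
                         stage2_sd = 1e-12)
  tr <- run_smart_trial(design_config("SMART", n = 30, seed = 5), g,
                        default_cost_table())
  expect_true(all(tr$records$responder == 0))
  expect_equal(tr$records$final_y, tr$records$baseline, tolerance = 1e-9)
})
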
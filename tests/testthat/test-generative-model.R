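test_that("receptive-group means recover the pilot marginal means", {
  expect_equal(round(derive_receptive_means(0.92, 0.60), 2), 1.53)
  expect_equal(round(derive_receptive_means(0.56, 0.60), 2), 0.93)
  expect_equal(derive_receptive_means(0.56, 0.60), 0.56 / 0.6)
  expect_equal(derive_receptive_means(0.92, 1.0), 0.92)
  expect_error(derive_receptive_means(0.92, 0), "receptive_fraction")
  expect_error(derive_receptive_means(0.92, 1.2), "receptive_fraction")
})

test_that("residual combination probability solves the averaged target", {
  q <- derive_combo_residual(0.51, 0.69, 0.75)
  expect_equal(q, 0.375)
  # brute-force enumeration over the four receptiveness cells
  expect_equal(oracle_combo_average(0.51, 0.69, q), 0.75)
  expect_equal(derive_combo_residual(0.5, 0.5, 0.5), 0)
  expect_warning(q1 <- derive_combo_residual(1, 1, 0.75), "unidentified")
  expect_equal(q1, 0)
  expect_warning(q2 <- derive_combo_residual(0.9, 0.9, 0.2), "clamping")
  expect_equal(q2, 0)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(generative_params(p_receptive_app = 1.3), "p_receptive_app")
  expect_error(generative_params(stage1_sd = 0), "stage1_sd")
  expect_error(generative_params(baseline_floor = 10), "baseline_floor")
  gp <- generative_params()
  expect_equal(gp$combo_residual_q, 0.375)
  expect_warning(generative_params(stage1_receptive_mean = 2.5),
                 "does not reproduce the pilot mean")
})

test_that("baseline draws match closed-form truncated-normal moments", {
  gp <- generative_params()
  set.seed(101)
  n <- 2e5
  y0 <- draw_baseline(n, gp)
  expect_gte(min(y0), 7.5)
  m <- smartsim:::.tnorm_mean(9.73, 1.37, 7.5)
  v <- smartsim:::.tnorm_var(9.73, 1.37, 7.5)
  expect_equal(m, 9.73 + 1.37 * dnorm((7.5 - 9.73) / 1.37) /
                 (1 - pnorm((7.5 - 9.73) / 1.37)))
  expect_lt(abs(mean(y0) - m), 3 * sqrt(v / n))
  # variance of the sample variance ~ 2 v^2 / n for near-normal tails
  expect_lt(abs(var(y0) - v), 3 * sqrt(2 * v^2 / n))
  # closed form against numerical integration
  f <- function(x) x * dnorm(x, 9.73, 1.37) / (1 - pnorm(7.5, 9.73, 1.37))
  expect_equal(m, integrate(f, 7.5, Inf)$value, tolerance = 1e-8)
})

test_that("disabling the floor recovers the plain normal baseline", {
  gp <- generative_params(baseline_floor = NA)
  set.seed(7)
  y0 <- draw_baseline(2e5, gp)
  expect_lt(abs(mean(y0) - 9.73), 3 * 1.37 / sqrt(2e5))
  expect_lt(min(y0), 7.5)
  expect_error(draw_baseline(0, gp), "positive count")
})

test_that("receptiveness rates, independence, and the combination average", {
  gp <- generative_params()
  set.seed(202)
  n <- 4e5
  rc <- assign_receptiveness(n, gp)
  se_p <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(rc$rc_app) - 0.51), 3 * se_p(0.51))
  expect_lt(abs(mean(rc$rc_nurse) - 0.69), 3 * se_p(0.69))
  expect_lt(abs(cor(rc$rc_app, rc$rc_nurse)), 3 / sqrt(n))
  # anyone receptive to a single intervention is receptive to the combination
  expect_true(all(rc$rc_combo[rc$rc_app == 1 | rc$rc_nurse == 1] == 1))
  # average combination receptiveness among the initially non-receptive
  avg <- (mean(rc$rc_combo[rc$rc_app == 0]) +
            mean(rc$rc_combo[rc$rc_nurse == 0])) / 2
  expect_lt(abs(avg - 0.75), 0.005)
})

test_that("certain receptiveness propagates to every indicator", {
  expect_warning(gp <- generative_params(p_receptive_app = 1,
                                         p_receptive_nurse = 1),
                 "unidentified")
  set.seed(1)
  rc <- assign_receptiveness(50, gp)
  expect_true(all(rc$rc_app == 1 & rc$rc_nurse == 1 & rc$rc_combo == 1))
})

test_that("stage changes follow the receptiveness-conditional normals", {
  gp <- generative_params()
  set.seed(303)
  n <- 2e5
  d_r1 <- draw_stage_change(rep(1, n), 1, gp)
  expect_lt(abs(mean(d_r1) - 1.53), 3 * 0.71 / sqrt(n))
  expect_lt(abs(sd(d_r1) - 0.71), 0.01)
  d_n2 <- draw_stage_change(rep(0, n), 2, gp)
  expect_lt(abs(mean(d_n2)), 3 * 0.77 / sqrt(n))
  expect_lt(abs(sd(d_n2) - 0.77), 0.01)
  # near-degenerate SD pins the receptive stage-2 draw at its mean
  gp0 <- generative_params(stage2_sd = 1e-12)
  expect_equal(draw_stage_change(c(1, 1), 2, gp0), c(0.94, 0.94),
               tolerance = 1e-9)
  expect_error(draw_stage_change(c(0, 2), 1, gp), "binary")
  expect_error(draw_stage_change(1, 3, gp), "stage")
})

test_that("the receptiveness mixture reproduces the pilot marginal mean", {
  gp <- generative_params()
  set.seed(404)
  n <- 4e5
  rc <- rbinom(n, 1, gp$assumed_receptive_fraction)
  d1 <- draw_stage_change(rc, 1, gp)
  # marginal SD: sqrt(sigma1^2 + mu1^2 p (1-p))
  s_marg <- sqrt(0.71^2 + 1.53^2 * 0.6 * 0.4)
  expect_lt(abs(mean(d1) - 0.92), 3 * s_marg / sqrt(n) + 0.002)
})

test_that("identical seeds give bit-identical subject streams", {
  gp <- generative_params()
  set.seed(99); a <- list(draw_baseline(100, gp), assign_receptiveness(100, gp))
  set.seed(99); b <- list(draw_baseline(100, gp), assign_receptiveness(100, gp))
  expect_identical(a, b)
})
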
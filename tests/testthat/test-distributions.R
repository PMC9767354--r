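test_that("point-mass components are sampled exactly", {
  set.seed(11)
  d1 <- effect_distribution("dichotomous", w_b = 1)
  expect_identical(sample_effects(d1, 3), c(1, 1, 1))
  d0 <- effect_distribution("dichotomous", w_b = 0)
  expect_identical(sample_effects(d0, 5), rep(0, 5))
  expect_error(sample_effects(d1, 0), "positive integer")
})

test_that("sampled moments match mixture moments within 3 standard errors", {
  set.seed(12)
  n <- 1e5
  # mixture mean of a 50:50 dichotomous mixture is w_b * mu_b = 0.5
  es <- sample_effects(effect_distribution("dichotomous", w_b = 0.5), n)
  se_mean <- 0.5 / sqrt(n) # mixture SD is exactly 0.5
  expect_lt(abs(mean(es) - 0.5), 3 * se_mean)
  # standard normal: sample SD ~ 1, SE(SD) ~ sd / sqrt(2n)
  es <- sample_effects(effect_distribution("single_normal", sd_a = 1), n)
  expect_lt(abs(sd(es) - 1), 3 / sqrt(2 * n))
})

test_that("closed-form prevalence matches normal tail masses and point masses", {
  sn <- effect_distribution("single_normal", sd_a = 1)
  expect_equal(true_prevalence(sn, 0.5), 2 * pnorm(-0.5), tolerance = 1e-12)
  expect_equal(round(true_prevalence(sn, 0.5), 3), 0.617)
  # half the mass at ES = 1, which is beyond 0.5
  expect_equal(true_prevalence(effect_distribution("dichotomous", w_b = 0.5)), 0.5)
  # narrow normal N(0, 0.2): two-tailed mass beyond 0.5 is 2(1 - Phi(2.5))
  narrow <- effect_distribution("single_normal", sd_a = 0.2)
  expect_equal(true_prevalence(narrow, 0.5), 2 * pnorm(-2.5), tolerance = 1e-12)
  expect_equal(round(true_prevalence(narrow, 0.5), 5), 0.01242)
})

test_that("Monte-Carlo prevalence of samples agrees with the analytic value", {
  set.seed(13)
  n <- 1e5
  for (d in list(effect_distribution("two_peaks", w_b = 0.3),
                 effect_distribution("two_normals", w_b = 0.5),
                 effect_distribution("single_normal", sd_a = 0.8))) {
    p <- true_prevalence(d)
    phat <- mean(abs(sample_effects(d, n)) > 0.5)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("prevalence solvers are exact and round-trip", {
  # two_peaks at 50%: narrow component ~0 tail mass, wide ~1, so w ~ 0.5
  w <- solve_weight_for_prevalence("two_peaks", 0.5)
  expect_equal(w, 0.5, tolerance = 1e-6)
  # boundary: target equal to component A's own mass gives weight 0
  b <- prevalence_bounds("overlapping_peaks")
  expect_equal(solve_weight_for_prevalence("overlapping_peaks", b[["lower"]]), 0)
  # round-trip over an achievable grid, all models, to 1e-10
  for (model in c("dichotomous", "two_peaks", "overlapping_peaks", "two_normals")) {
    b <- prevalence_bounds(model)
    targets <- seq(b[["lower"]] + 1e-4, b[["upper"]] - 1e-4, length.out = 7)
    for (p in targets) {
      d <- distribution_for_prevalence(model, p)
      expect_equal(true_prevalence(d), p, tolerance = 1e-10)
    }
  }
  for (p in c(0.001, 0.25, 0.617, 0.9, 0.99)) {
    d <- distribution_for_prevalence("single_normal", p)
    expect_equal(true_prevalence(d), p, tolerance = 1e-10)
  }
})

test_that("unachievable prevalence targets raise a classed error carrying the bounds", {
  err <- expect_error(
    solve_weight_for_prevalence("two_normals", 2 / 3),
    class = "litsim_unachievable_prevalence"
  )
  expect_equal(err$upper, 2 * pnorm(-0.5), tolerance = 1e-12)
  expect_lt(err$lower, 1e-5)
  # narrow 0.1% prevalence is below the overlapping-peaks floor
  expect_error(
    solve_weight_for_prevalence("overlapping_peaks", 0.001),
    class = "litsim_unachievable_prevalence"
  )
})

test_that("single-normal SD solver inverts the tail-mass formula", {
  expect_equal(solve_sd_for_prevalence(2 * pnorm(-0.5)), 1, tolerance = 1e-10)
  expect_equal(solve_sd_for_prevalence(2 * pnorm(-0.5 / 0.3)), 0.3, tolerance = 1e-10)
  # a ~90% prevalence needs an SD of about 4
  expect_equal(solve_sd_for_prevalence(0.9), 3.98, tolerance = 0.01)
  expect_error(solve_sd_for_prevalence(1), "strictly between")
  expect_error(solve_sd_for_prevalence(0), "strictly between")
})

test_that("prevalence is monotone in the free parameter", {
  sds <- c(0.3, 0.5, 0.8, 1.5, 4)
  prevs <- vapply(sds, function(s)
    true_prevalence(effect_distribution("single_normal", sd_a = s)), numeric(1))
  expect_true(all(diff(prevs) > 0))
  ws <- seq(0.1, 0.9, by = 0.2)
  prevs_w <- vapply(ws, function(w)
    true_prevalence(effect_distribution("two_peaks", w_b = w)), numeric(1))
  expect_true(all(diff(prevs_w) > 0)) # p_B > p_A for two_peaks
})

test_that("typical true effect matches truncated-normal oracles", {
  expect_equal(typical_true_effect(effect_distribution("dichotomous", w_b = 0.5)), 1)
  # N(0,1): E[|X| | |X| > 0.5] = phi(0.5) / (1 - Phi(0.5)) by symmetry
  sn <- effect_distribution("single_normal", sd_a = 1)
  expect_equal(typical_true_effect(sn),
               dnorm(0.5) / pnorm(0.5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(typical_true_effect(sn), 3), 1.141)
  # two_peaks mass above 0.5 is dominated by N(1, 0.1)
  tp <- effect_distribution("two_peaks", w_b = 0.5)
  expect_equal(typical_true_effect(tp), 1, tolerance = 0.01)
})

test_that("Monte-Carlo typical effect agrees with the analytic value", {
  set.seed(14)
  for (d in list(effect_distribution("overlapping_peaks", w_b = 0.5),
                 effect_distribution("single_normal", sd_a = 1))) {
    a <- typical_true_effect(d)
    # MC standard error estimated from the draws themselves
    es <- sample_effects(d, 1e5)
    kept <- abs(es[abs(es) > 0.5])
    mc_se <- sd(kept) / sqrt(length(kept))
    mc <- typical_true_effect(d, method = "monte_carlo")
    expect_lt(abs(mc - a), 3 * mc_se)
  }
})

test_that("typical true effect is never below the minimum of interest", {
  set.seed(15)
  for (i in 1:20) {
    model <- sample(c("two_peaks", "overlapping_peaks", "two_normals", "single_normal"), 1)
    if (model == "single_normal") {
      p <- runif(1, 0.05, 0.55)
    } else {
      b <- prevalence_bounds(model)
      p <- runif(1, b[["lower"]] + 0.01, min(b[["upper"]] - 0.01, 0.55))
    }
    d <- distribution_for_prevalence(model, p)
    m <- runif(1, 0.2, 0.8)
    if (true_prevalence(d, m) > 0) {
      expect_gte(typical_true_effect(d, m), m)
    }
  }
})

test_that("constructor enforces model invariants and presets", {
  expect_error(effect_distribution("dichotomous", w_b = 0.5, sd_a = 0.1), "point masses")
  expect_error(effect_distribution("single_normal", sd_a = 1, w_b = 0.2), "w_b")
  expect_error(effect_distribution("two_peaks"), "w_b")
  expect_error(effect_distribution("two_peaks", w_b = 1.5), "probability")
  tp <- effect_distribution("two_peaks", w_b = 0.3)
  expect_equal(tp[c("sd_a", "mu_b", "sd_b")], list(sd_a = 0.1, mu_b = 1, sd_b = 0.1))
  tn <- effect_distribution("two_normals", w_b = 0.3)
  expect_equal(tn[c("sd_a", "mu_b", "sd_b")], list(sd_a = 0.1, mu_b = 0, sd_b = 1))
})
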
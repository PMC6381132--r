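make_series <- function(atd_s, phase, cycle, t_stim = NULL) {
  out <- data.frame(beat_index = seq_along(atd_s),
                    t_stim_s = if (is.null(t_stim))
                      (seq_along(atd_s) - 1) * 0.4 else t_stim,
                    atd_s = atd_s, phase = phase, cycle = cycle)
  class(out) <- c("atd_series", "data.frame")
  out
}

test_that("per-cycle modulation uses the preceding relaxed reference", {
  s <- make_series(
    atd_s = c(rep(6.851e-3, 3), rep(7.004e-3, 2), rep(6.851e-3, 2),
              rep(7.010e-3, 2)),
    phase = c("baseline", "baseline", "relaxed", "strained", "strained",
              "relaxed", "relaxed", "strained", "strained"),
    cycle = c(NA, NA, 0, 1, 1, 1, 1, 2, 2))
  m <- atd_modulation(s)
  # the worked control/strained pair: 6.851 -> 7.004 ms is +2.23%
  expect_equal(m$modulation[1], 7.004 / 6.851 - 1, tolerance = 1e-12)
  expect_equal(round(100 * m$modulation[1], 2), 2.23)
  expect_equal(m$atd_ref_s[2], 6.851e-3)
  expect_equal(m$n_beats, c(2, 2))

  # without any strain the modulation vanishes
  s0 <- make_series(rep(5e-3, 6),
                    c("baseline", "relaxed", "strained", "strained",
                      "relaxed", "strained"),
                    c(NA, 0, 1, 1, 1, 2))
  expect_equal(atd_modulation(s0)$modulation, c(0, 0))

  # a cycle with no reference is skipped with a warning
  s2 <- make_series(c(5e-3, 5.1e-3), c("strained", "strained"), c(2, 2))
  expect_warning(m2 <- atd_modulation(s2), "no reference")
  expect_equal(nrow(m2), 0)
})

test_that("the origin-constrained slope recovers alpha from the exact law", {
  eps <- c(0.002, 0.01, 0.03, 0.05, 0.08, 0.10)
  mod <- theoretical_atd_ratio(eps, 0.29) - 1
  a <- fit_alpha(mod, eps)
  expect_equal(round(a$alpha, 2), 0.30)
  # including compression points (the law is smooth through zero)
  eps_all <- c(-0.02, -0.01, eps)
  mod_all <- theoretical_atd_ratio(eps_all, 0.29) - 1
  a_all <- fit_alpha(mod_all, eps_all, "all")
  expect_gt(a_all$alpha, 0.29); expect_lt(a_all$alpha, 0.32)
  expect_equal(fit_alpha(rep(0, 4), c(0.01, 0.02, 0.05, 0.1))$alpha, 0)
  expect_error(fit_alpha(c(0, 1), c(0.1, 0.2)), "3 strain levels")
  # diagnostic variant exposes the intercept
  ai <- fit_alpha(mod, eps, intercept = TRUE)
  expect_lt(abs(ai$intercept), 1e-3)
})

test_that("inverting the secant relation recovers the resistance partition", {
  expect_equal(round(invert_alpha_to_f(0.30, 0.10), 2), 0.29)
  expect_equal(invert_alpha_to_f(0, 0.10), 0)
  # exact round trip through the secant slope, any f
  for (f in seq(0.1, 0.9, by = 0.1)) {
    alpha <- (theoretical_atd_ratio(0.10, f) - 1) / 0.10
    expect_equal(invert_alpha_to_f(alpha, 0.10), f, tolerance = 1e-12)
  }
  # round trip through the fitted slope on the full law
  eps <- seq(0.01, 0.10, by = 0.01)
  for (f in seq(0.1, 0.9, by = 0.2)) {
    alpha <- fit_alpha(theoretical_atd_ratio(eps, f) - 1, eps)$alpha
    expect_lt(abs(invert_alpha_to_f(alpha, 0.10) - f), 0.005)
  }
})

test_that("the velocity-strain curve matches the closed form", {
  vc <- velocity_strain_curve(eps = c(0, 0.10), atd = c(1, 1.0302) * 6.851e-3,
                              atd0 = 6.851e-3, alpha = 0.302)
  expect_equal(vc$theta_ratio[1], 1)
  expect_equal(vc$theta_ratio[2], 1.1 / 1.0302, tolerance = 1e-12)
  expect_equal(vc$theta_ratio_law[2],
               theoretical_velocity_ratio(0.10, 0.302, "alpha"))
  # the printed cross-study comparison point: +7.1% at 10.5% strain
  expect_equal(round(100 * (theoretical_velocity_ratio(0.105, 0.30,
                                                       "alpha") - 1), 1),
               7.1)
})

test_that("compression follows the linearised law to quadratic order", {
  mod <- theoretical_atd_ratio(-0.014, 0.29) - 1
  expect_lt(abs(100 * mod - 100 * (-0.29 * 0.014)), 0.01)  # < 0.01 pp
})

test_that("rate independence is detected and rate effects are flagged", {
  rates <- c(0.5, 1.7, 4.25, 8.5, 17)
  same <- rep(0.302, 5)
  r <- rate_independence_test(same, rates)
  expect_equal(r$slope, 0)
  expect_equal(r$verdict, "independent")
  expect_equal(r$alpha_sd, 0)

  jit <- 0.302 + c(0.003, -0.002, 0.001, -0.003, 0.001)
  r2 <- rate_independence_test(jit, rates)
  expect_equal(r2$verdict, "independent")

  dep <- c(0.30, 0.30, 0.30, 0.30, 0.33)   # +10% at the fastest rate
  r3 <- rate_independence_test(dep, rates)
  expect_equal(r3$verdict, "dependent")
  expect_error(rate_independence_test(c(0.3, 0.3), c(1, 2)), "3 ramp")
})

test_that("the Lapicque hyperbola is fitted exactly and robustly", {
  tt <- c(0.5, 1, 2, 4, 6, 8)
  ii <- 5.55 * (1 + 2.1 / tt)
  f <- fit_strength_duration(tt, ii)
  expect_equal(f$rheobase_uA, 5.55, tolerance = 1e-9)
  expect_equal(f$chronaxie_ms, 2.1, tolerance = 1e-9)
  expect_equal(2 * f$rheobase_uA, 11.1, tolerance = 1e-9)

  # 5% multiplicative noise, 8 points: typical recovery within 10%
  set.seed(20)
  tt8 <- c(0.3, 0.5, 1, 1.5, 2, 4, 6, 10)
  errs <- t(replicate(200, {
    iin <- 5.55 * (1 + 2.1 / tt8) * (1 + rnorm(8, 0, 0.05))
    fn <- fit_strength_duration(tt8, iin)
    c(abs(fn$rheobase_uA / 5.55 - 1), abs(fn$chronaxie_ms / 2.1 - 1))
  }))
  expect_lt(median(errs[, 1]), 0.1)
  expect_lt(median(errs[, 2]), 0.1)
  expect_gt(mean(errs[, 1] < 0.1 & errs[, 2] < 0.1), 0.75)
  expect_error(fit_strength_duration(tt, rev(ii)), "non-hyperbolic")
  expect_error(fit_strength_duration(1:2, c(2, 3)), "3 points")
})

test_that("actuation without strain shows no ATD effect, strain does", {
  set.seed(31)
  imm <- rnorm(10, 0, 1e-3)           # immobilized: noise around zero
  free <- rnorm(10, 0.030, 1e-3)      # free: ~3% modulation
  cmp <- dea_control_comparison(free, imm)
  expect_gt(cmp$p_immobilized, 0.05)
  expect_lt(cmp$p_between, 1e-6)
  expect_false(cmp$immobilized_effect)
  # identical inputs in both arms give an exact null
  same <- rep(0.01, 6)
  expect_equal(dea_control_comparison(same, same)$p_between, 1)
})
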
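test_that("labeled-fraction model reproduces hand-evaluated anchor points", {
  p1 <- cell_cycle_params(T_C = 100, T_S = 10, T_G2M = 5, GF = 1, r = 1)
  expect_equal(rprime(0, p1), 0.10)                 # labeling index T_S/T_C
  expect_equal(rprime(90, p1), 1)                   # saturation at T_C - T_S
  p2 <- cell_cycle_params(T_C = 119, T_S = 20, T_G2M = 9, GF = 1, r = 2)
  expect_equal(rprime(99, p2), 1)
  expect_equal(rprime(0, p2),
               (2^(29 / 119) - 2^(9 / 119)) / 1)    # S-phase fraction

  expect_equal(growth_fraction(c(0, 50, 1000),
                               cell_cycle_params(100, 10, 5, GF = 1, r = 2)),
               rep(1, 3))
  expect_equal(growth_fraction(500, cell_cycle_params(100, 10, 5,
                                                      GF = 0.8, r = 1)), 0.8)
  expect_equal(growth_fraction(100, cell_cycle_params(100, 10, 5,
                                                      GF = 0.5, r = 2)), 2 / 3)

  p3 <- cell_cycle_params(T_C = 100, T_S = 10, T_G2M = 5, GF = 0.8, r = 1)
  expect_equal(labeled_fraction(c(90, 120, 500), p3), rep(0.8, 3))
  expect_equal(labeled_fraction(0, cell_cycle_params(100, 10, 5, 1, 1)), 0.1)
})

test_that("R'(t) is continuous at both breakpoints and monotone", {
  set.seed(31)
  for (p in random_params(100)) {
    eps <- 1e-10
    g <- p$T_G2M
    expect_lt(abs(rprime(max(g - eps, 0), p) - rprime(g, p)), 1e-9)
    expect_lt(abs(rprime(p$T_C - p$T_S - eps, p) - 1), 1e-9)
    tt <- seq(0, 1.5 * p$T_C, length.out = 200)
    expect_false(is.unsorted(rprime(tt, p) + 1e-12))
    rt <- labeled_fraction(tt, p)
    if (p$r == 2) expect_false(is.unsorted(rt + 1e-12))
    expect_true(all(rt >= 0 & rt <= 1 + 1e-12))
  }
})

test_that("the r -> 1 limit of the piecewise form recovers the linear form", {
  set.seed(32)
  for (p1 in random_params(25, r = 1)) {
    pr <- cell_cycle_params(p1$T_C, p1$T_S, p1$T_G2M, p1$GF, r = 1 + 1e-6)
    tt <- seq(0, p1$T_C, length.out = 100)
    expect_lt(max(abs(rprime(tt, pr) - rprime(tt, p1))), 1e-4)
  }
})

test_that("weighted SSE follows its definition", {
  p <- cell_cycle_params(100, 10, 5, 0.8, 1)
  tt <- c(0, 20, 50)
  tc <- data.frame(time_h = tt, fraction_labeled = labeled_fraction(tt, p),
                   sd = 0.02)
  expect_equal(labeling_sse(tc, p), 0)
  tc1 <- data.frame(time_h = 20,
                    fraction_labeled = labeled_fraction(20, p) + 0.02,
                    sd = 0.02)
  expect_equal(labeling_sse(tc1, p), 1)
  # 3-point hand-built evaluation
  tc3 <- data.frame(time_h = c(0, 10, 30), fraction_labeled = c(0.1, 0.2, 0.4),
                    sd = c(0.01, 0.02, 0.04))
  manual <- sum(((c(0.1, 0.2, 0.4) -
                  labeled_fraction(c(0, 10, 30), p)) / c(0.01, 0.02, 0.04))^2)
  expect_equal(labeling_sse(tc3, p), manual)
  # replicated measurements weight each timepoint n-fold
  tc3$n_animals <- c(5, 5, 5)
  expect_equal(labeling_sse(tc3, p), 5 * manual)
  tc3$sd[1] <- 0
  expect_error(labeling_sse(tc3, p), "positive")
  expect_equal(labeling_sse(tc3, p, unweighted = TRUE),
               sum(5 * (c(0.1, 0.2, 0.4) -
                        labeled_fraction(c(0, 10, 30), p))^2 /
                     c(1, 0.02, 0.04)^2))
})

test_that("fitting exact model output recovers the generating parameters", {
  truth <- cell_cycle_params(T_C = 119, T_S = 88, T_G2M = 9, GF = 0.96, r = 2)
  tt <- seq(0, 120, by = 12)
  tc <- data.frame(time_h = tt, fraction_labeled = labeled_fraction(tt, truth),
                   sd = 0.01)
  fit <- fit_cell_cycle(tc, r = 2, fixed = list(T_G2M = 9))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$T_C - 119), 0.1)
  expect_lt(abs(fit$params$T_S - 88), 0.1)
  expect_lt(abs(fit$params$GF - 0.96), 1e-3)
  expect_lt(fit$sse, 1e-6)
  expect_true(all(fit$ci68[fit$free] > 0))

  truth1 <- cell_cycle_params(T_C = 324, T_S = 132, T_G2M = 9,
                              GF = 0.80, r = 1)
  tt1 <- seq(0, 220, by = 24)
  tc1 <- data.frame(time_h = tt1,
                    fraction_labeled = labeled_fraction(tt1, truth1),
                    sd = 0.01)
  fit1 <- fit_cell_cycle(tc1, r = 1, fixed = list(T_G2M = 9))
  expect_lt(abs(fit1$params$T_C - 324) / 324, 1e-3)
  expect_lt(abs(fit1$params$GF - 0.80), 1e-3)
})

test_that("phase-length derivation propagates errors linearly", {
  tc <- data.frame(time_h = seq(0, 120, 12),
                   fraction_labeled = labeled_fraction(
                     seq(0, 120, 12),
                     cell_cycle_params(100, 30, 9, 0.9, 2)),
                   sd = 0.01)
  fit <- fit_cell_cycle(tc, r = 2)
  # override to the hand-worked configuration
  fit$params <- cell_cycle_params(T_C = 100, T_S = 30, T_G2M = 9,
                                  GF = 0.9, r = 2)
  fit$ci68 <- c(T_C = 10, T_S = 4, GF = 0.01)
  fit$free <- c("T_C", "T_S", "GF")
  pl <- derive_phase_lengths(fit, mi = 0.02, dmi = 0)
  expect_equal(pl$T_M, 2)
  expect_equal(pl$dT_M, 0.2)
  expect_equal(pl$T_G1, 61)
  expect_equal(pl$dT_G1, sqrt(10^2 + 4^2), tolerance = 1e-10)

  fit$ci68 <- c(T_C = 0, T_S = 0, GF = 0)
  fit$params <- cell_cycle_params(T_C = 119, T_S = 30, T_G2M = 9,
                                  GF = 0.9, r = 2)
  pl2 <- derive_phase_lengths(fit, mi = 0.05, dmi = 0.01)
  expect_equal(pl2$T_M, 5.95)
  expect_equal(pl2$dT_M, 1.19)
  pl0 <- derive_phase_lengths(fit, mi = 0)
  expect_equal(pl0$T_M, 0)
  expect_error(derive_phase_lengths(fit, mi = 1.2), "\\[0, 1\\]")
})

test_that("T_G2+M is the earliest sustained labeled-mitoses saturation", {
  expect_equal(estimate_tg2m(data.frame(
    time_h = c(3, 6, 9, 12), fraction_labeled = c(0.2, 0.8, 1, 1))), 9)
  expect_equal(estimate_tg2m(data.frame(
    time_h = 1, fraction_labeled = 1)), 1)
  # a dip after saturation postpones the estimate
  expect_equal(estimate_tg2m(data.frame(
    time_h = c(3, 6, 9, 12), fraction_labeled = c(1, 0.9, 1, 1))), 9)
  expect_error(estimate_tg2m(data.frame(
    time_h = c(3, 6), fraction_labeled = c(0.5, 0.9))), "saturat")
})

test_that("full-cycle extrapolation scales linearly and caps at 1", {
  r <- extrapolate_full_cycle_differentiation(0.16, 0.5)
  expect_equal(r$f_full, 0.32)
  expect_equal(r$retained, 0.68)
  expect_equal(extrapolate_full_cycle_differentiation(0, 0.3)$f_full, 0)
  expect_equal(extrapolate_full_cycle_differentiation(0.3, 1)$f_full, 0.3)
  expect_equal(extrapolate_full_cycle_differentiation(0.8, 0.5)$f_full, 1)
  expect_error(extrapolate_full_cycle_differentiation(0.2, 0), "\\(0, 1\\]")
})

test_that("parameter constraints are enforced", {
  expect_error(cell_cycle_params(100, 80, 30), "smaller than T_C")
  expect_error(cell_cycle_params(100, 10, 5, GF = 0), "\\(0, 1\\]")
  expect_error(cell_cycle_params(100, 10, 5, r = 3), "\\[1, 2\\]")
  expect_error(rprime(-1, cell_cycle_params(100, 10, 5)), "non-negative")
})
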
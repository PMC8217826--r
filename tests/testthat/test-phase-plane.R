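test_that("Jacobian matches central finite differences of the vector field", {
  set.seed(7)
  h <- 1e-6
  contexts <- list(
    list(cfg = m2, gamma = m2$inputs$gamma_on, I_T = 0, I_N = 0),
    list(cfg = m3, gamma = m3$inputs$gamma_on, I_T = 2, I_N = 1.5))
  for (ctx in contexts) {
    for (k in 1:25) {
      x <- runif(1, 0.05, 0.95)
      s <- runif(1, -1.5, 1.5)
      J <- jacobian_xs(ctx$cfg, x, s, ctx$gamma,
                       tone_on = ctx$I_T > 0, noise_on = ctx$I_N > 0,
                       I_T = ctx$I_T, I_N = ctx$I_N)
      f <- function(x_, s_) phase_rhs(ctx$cfg, x_, s_, ctx$gamma,
                                      tone_on = ctx$I_T > 0,
                                      noise_on = ctx$I_N > 0,
                                      I_T = ctx$I_T, I_N = ctx$I_N)
      Jfd <- cbind((f(x + h, s) - f(x - h, s)) / (2 * h),
                   (f(x, s + h) - f(x, s - h)) / (2 * h))
      expect_lt(max(abs(J - Jfd)), 1e-6 * max(1, max(abs(J))))
      expect_identical(J[2, 1], 0)
      expect_equal(J[2, 2], -1 / ctx$cfg$population$tau)
    }
  }
})

test_that("saddle Jacobian has one unstable direction and eigenvalue -1/tau", {
  fp <- find_equilibria(m2)
  J <- jacobian_xs(m2, fp$x[2], 0, m2$inputs$gamma_on)
  expect_gt(J[1, 1], 0)
  ev <- sort(eigen(J)$values)
  expect_equal(ev, sort(c(J[1, 1], -1 / m2$population$tau)))
})

test_that("eigenvector construction equals the closed-form separatrix slope", {
  # (J22 - J11)/J12 is the stable-manifold slope; with equal time
  # constants it collapses to -(a_E + a_I I_N)/gamma exactly
  contexts <- list(
    list(cfg = m2, gamma = m2$inputs$gamma_on, I_T = 0, I_N = 0),
    list(cfg = m3, gamma = m3$inputs$gamma_on, I_T = 2, I_N = 1.5),
    list(cfg = m3, gamma = m3$inputs$gamma_off, I_T = 0, I_N = 3))
  for (ctx in contexts) {
    sep <- linear_separatrix(ctx$cfg, ctx$gamma, ctx$I_T, ctx$I_N)
    J <- jacobian_xs(ctx$cfg, sep$x_S, 0, ctx$gamma,
                     tone_on = ctx$I_T > 0, noise_on = ctx$I_N > 0,
                     I_T = ctx$I_T, I_N = ctx$I_N)
    expect_equal((J[2, 2] - J[1, 1]) / J[1, 2], -sep$slope_scale,
                 tolerance = 1e-12)
  }
})

test_that("linear separatrix slope scales with noise as predicted", {
  s0 <- linear_separatrix(m3, m3$inputs$gamma_on, I_T = 2, I_N = 0)
  s1 <- linear_separatrix(m3, m3$inputs$gamma_on, I_T = 2, I_N = 1.5)
  expect_equal(s1$slope_scale / s0$slope_scale,
               1 + m3$inputs$a_I * 1.5 / m3$population$a_E,
               tolerance = 1e-12)
  expect_equal(separatrix_height(s1, s1$x_S), 0)
  expect_error(linear_separatrix(m3, m3$inputs$gamma_on, I_T = 0, I_N = 0),
               "monostable")
})

test_that("numeric separatrix confirms the linear form within tolerance", {
  contexts <- list(
    list(cfg = m2, gamma = m2$inputs$gamma_on, I_T = 0, I_N = 0),
    list(cfg = m3, gamma = m3$inputs$gamma_on, I_T = 1.2, I_N = 0),
    list(cfg = m3, gamma = m3$inputs$gamma_off, I_T = 0, I_N = 3))
  for (ctx in contexts) {
    lin <- linear_separatrix(ctx$cfg, ctx$gamma, ctx$I_T, ctx$I_N)
    num <- numeric_separatrix(ctx$cfg, ctx$gamma, ctx$I_T, ctx$I_N)
    expect_equal(num$x[1], lin$x_S)
    expect_equal(num$s[1], 0)
    sfun <- separatrix_fun(num)
    # near the saddle: within 2 percent
    xs <- seq(max(lin$x_S - 0.1, min(num$x)),
              min(lin$x_S + 0.1, max(num$x)), length.out = 101)
    lv <- separatrix_height(lin, xs)
    expect_lt(max(abs(sfun(xs) - lv)) / max(abs(lv)), 0.02)
    # full inactive-to-active span: within 15 percent
    xs <- seq(max(lin$x_I, min(num$x)), min(lin$x_A, max(num$x)),
              length.out = 101)
    lv <- separatrix_height(lin, xs)
    expect_lt(max(abs(sfun(xs) - lv)) / max(abs(lv)), 0.15)
  }
})

test_that("forward simulation respects the numeric separatrix basins", {
  set.seed(11)
  lin <- linear_separatrix(m2, m2$inputs$gamma_on)
  num <- numeric_separatrix(m2, m2$inputs$gamma_on)
  sfun <- separatrix_fun(num)
  n_ok <- 0
  n <- 200
  for (k in seq_len(n)) {
    x0 <- runif(1, lin$x_I + 0.01, lin$x_A - 0.01)
    base <- sfun(x0)
    s0 <- base + runif(1, -1, 1) * (0.1 * abs(base) + 0.02)
    xf <- forward_final_x(m2, x0, s0, m2$inputs$gamma_on)
    n_ok <- n_ok + ((xf > 0.5) == (s0 > base))
  }
  expect_equal(n_ok, n)
})

test_that("gamma calibration reproduces the caption values and threshold convention", {
  g2 <- calibrate_gamma_on(m2)
  expect_equal(round(g2, 1), 5.2)
  g3 <- calibrate_gamma_on(m3)
  expect_equal(round(g3, 1), 9.6)
  # the calibration pins the separatrix height at the rest state to 1
  sep <- linear_separatrix(m2, g2)
  expect_equal(separatrix_height(sep, sep$x_I), 1, tolerance = 1e-9)
  expect_error(calibrate_gamma_on(m1), "disabled")
})

test_that("separatrix crossing predicate reports both sides and the boundary", {
  sep <- linear_separatrix(m2, m2$inputs$gamma_on)
  expect_identical(crosses_separatrix(sep$x_I, 1 + 1e-6, sep, "up"),
                   "crosses")
  expect_identical(crosses_separatrix(sep$x_I, 1 - 1e-6, sep, "up"),
                   "stays")
  expect_identical(crosses_separatrix(sep$x_S, 0, sep, "up"),
                   "at-threshold")
  # suppressed offset at the active state stays in the active basin
  s_off <- -(3 - (2 / 3) * 3.2)
  expect_identical(crosses_separatrix(sep$x_A, s_off, sep, "down"),
                   "stays")
})
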
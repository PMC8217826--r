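test_that("bistable-variant thresholds follow their closed forms", {
  beta <- m2$inputs$beta
  expect_equal(masking_threshold(m2, 3), (3 - 1) / beta, tolerance = 1e-8)
  expect_equal(masking_threshold(m2, 1), 0, tolerance = 1e-7)
  expect_equal(continuity_threshold(m2, c(1.5, 2, 4)),
               (c(1.5, 2, 4) - 1) / beta, tolerance = 1e-7)
  expect_error(masking_threshold(m2, 0.8), "below")
  expect_error(continuity_threshold(m2, 6), "I_T_max")
})

test_that("hysteresis-variant masking rises with tone level, continuity is flat", {
  expect_lt(masking_threshold(m1, 1.5), 1) # I_N = 1 masks a 1.5 tone
  M <- masking_threshold(m1, c(1.5, 2, 3, 4, 5))
  expect_true(all(diff(M) > 0))
  C <- continuity_threshold(m1, c(1.5, 2, 3, 4, 5))
  expect_equal(max(C) - min(C), 0, tolerance = 1e-12)
  expect_lte(C[1], 8)
  expect_gte(C[1], min(M)) # continuity compensates for masking
})

test_that("the masking slope approximation matches the curve at low noise", {
  x_R0 <- knee_x(m1$population$a_E)$x_R
  sl <- model1_masking_slope_approx(m1$inputs$a_I, m1$inputs$alpha, x_R0)
  expect_equal(sl, 1.40, tolerance = 0.005)
  secant <- diff(masking_threshold(m1, c(1.05, 1.5))) / 0.45
  expect_lt(abs(sl - secant) / sl, 0.1)
  expect_error(model1_masking_slope_approx(1.124, 2, x_R0), "impossible")
})

test_that("combined-variant thresholds need both saddle survival and weak offsets", {
  # continuity is undefined until the gap noise restores bistability
  onset_IN <- stats::uniroot(function(IN) {
    equilibrium_IT(knee_x(m3$population$a_E, m3$inputs$a_I, IN)$x_L,
                   m3$population, m3$inputs, IN)
  }, c(0, 10), tol = 1e-10)$root
  C <- continuity_threshold(m3, c(1.5, 3, 5))
  expect_true(all(C > onset_IN))
  expect_true(all(diff(C) > 0))
  M <- masking_threshold(m3, c(1.5, 3, 5))
  expect_true(all(diff(M) > 0))
  expect_true(all(C > M))
})

test_that("threshold curves tabulate analytic and bisection methods", {
  tab <- threshold_curve(m2, "masking", I_T = c(2, 3, 4))
  expect_named(tab, c("I_T", "I_N_threshold", "kind", "method"))
  expect_equal(tab$I_N_threshold, (c(2, 3, 4) - 1) / m2$inputs$beta,
               tolerance = 1e-7)
  # undefined points are NA, not errors
  tab <- threshold_curve(m1, "masking", I_T = c(0.5, 2))
  expect_true(is.na(tab$I_N_threshold[1]) && !is.na(tab$I_N_threshold[2]))
  tab <- threshold_curve(m2, "masking", I_T = c(2, 3), method = "bisection")
  expect_equal(tab$I_N_threshold, c(1.5, 3), tolerance = 2e-3)
})

test_that("feasibility report passes the hysteresis preset and flags violations", {
  rep <- feasibility_report(m1)
  expect_true(all(rep$pass[!is.na(rep$pass)]))
  bad <- feasibility_report(
    model_config(m1$population,
                 input_params(alpha = 2, a_I = 1.124),
                 sustained = TRUE, transient = FALSE, inhib = TRUE))
  expect_false(bad$pass[bad$check == "alpha_constraint"])
  weak_off <- feasibility_report(
    model_config(m2$population,
                 input_params(beta = 2 / 3,
                              gamma_on = m2$inputs$gamma_on,
                              gamma_off = 0.5 * m2$inputs$gamma_on),
                 sustained = FALSE, transient = TRUE, inhib = FALSE))
  expect_false(
    weak_off$pass[weak_off$check == "offset_not_weaker_than_onset"])
  # the combined preset deactivates without an offset: check not applicable
  rep3 <- feasibility_report(m3)
  expect_true(is.na(rep3$pass[rep3$check == "offset_not_weaker_than_onset"]))
})

test_that("the (a_I, alpha) sweep marks the feasible wedge", {
  sw <- sweep_aI_alpha(m1, a_I = c(0.8, 1.124, 1.4),
                       alpha = c(0.168, 1.2))
  ref <- sw[sw$a_I == 1.124 & sw$alpha == 0.168, ]
  expect_true(ref$feasible)
  expect_true(is.finite(ref$M_max) && is.finite(ref$C_max))
  expect_gte(ref$C_max, ref$M_max)
  # alpha above a_I (1 - x_R(0)) makes masking impossible
  x_R0 <- knee_x(m1$population$a_E)$x_R
  over <- sw[sw$alpha > sw$a_I * (1 - x_R0), ]
  expect_true(all(!over$feasible))
  # stronger inhibition lowers the masking threshold
  at_alpha <- sw[sw$alpha == 0.168, ]
  expect_true(all(diff(at_alpha$M_max[order(at_alpha$a_I)]) < 0))
})

test_that("the gamma_off family interpolates between flat and steep continuity", {
  sw <- sweep_gamma_off(m3, gamma_off = c(0.01, 0.88, 2),
                        I_T = c(1.5, 2, 2.5))
  flat <- sw$I_N_threshold[sw$gamma_off == 0.01]
  expect_lt(max(flat) - min(flat), 0.05) # no-offset limit: constant
  mid <- sw$I_N_threshold[sw$gamma_off == 0.88]
  expect_equal(mid, continuity_threshold(m3, c(1.5, 2, 2.5)),
               tolerance = 1e-7)
  steep <- sw$I_N_threshold[sw$gamma_off == 2]
  expect_true(all(steep > mid)) # pointwise monotone in gamma_off
  expect_gt(diff(range(steep)), diff(range(mid))) # and steeper in I_T
})
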
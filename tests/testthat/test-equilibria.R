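test_that("equilibrium relation is the exact inverse of the drive map", {
  expect_equal(equilibrium_IT(0.5, m1$population),
               m1$population$m - m1$population$a_E / 2)
  # inverse consistency across the open interval and noise levels
  p <- m1$population; i <- m1$inputs
  for (IN in c(0, 2, 8)) {
    for (x in seq(0.01, 0.99, length.out = 25)) {
      IT <- equilibrium_IT(x, p, i, IN)
      u <- p$a_E * x + IT + i$alpha * IN - i$a_I * IN * (1 - x)
      expect_equal(sigmoid(u, p), x, tolerance = 1e-10)
    }
  }
  expect_error(equilibrium_IT(0, m1$population), "strictly inside")
})

test_that("knee rates obey the closed form and the x_L + x_R = 1 identity", {
  k <- knee_x(4)
  expect_equal(k$x_L, 0.5)
  expect_equal(k$x_R, 0.5)
  k <- knee_x(5.9)
  expect_equal(k$x_L, 0.78374, tolerance = 1e-4)
  expect_equal(k$x_R, 0.21626, tolerance = 1e-4)
  k <- knee_x(5.9, a_I = 1.124, I_N = 8)
  expect_equal(k$x_L, 0.928, tolerance = 1e-3)
  expect_error(knee_x(3.5), "not S-shaped")
  for (a_E in seq(4.1, 20, length.out = 13)) {
    for (IN in c(0, 1, 5)) {
      k <- knee_x(a_E, a_I = 0.8, I_N = IN)
      expect_equal(k$x_L + k$x_R, 1)
      expect_true(k$x_R < 0.5 && k$x_L > 0.5)
    }
  }
})

test_that("preset knees sit at their placed tone levels with IT_L < IT_R", {
  k1 <- knee_IT(m1$population, m1$inputs)
  expect_equal(c(k1$IT_L, k1$IT_R), c(0.2, 1.0), tolerance = 1e-9)
  k2 <- knee_IT(m2$population, m2$inputs)
  expect_equal(c(k2$IT_L, k2$IT_R), c(-2, 2), tolerance = 1e-9)
  k3 <- knee_IT(m3$population, m3$inputs)
  expect_equal(c(k3$IT_L, k3$IT_R), c(0.2, 6), tolerance = 1e-9)
})

test_that("noise raises the activation knee and lets the deactivation knee cross zero", {
  IN <- seq(0, 10, by = 1)
  ks <- lapply(IN, function(n) knee_IT(m1$population, m1$inputs, n))
  IT_R <- vapply(ks, `[[`, numeric(1), "IT_R")
  IT_L <- vapply(ks, `[[`, numeric(1), "IT_L")
  expect_true(all(diff(IT_R) > 0)) # masking: activation gets harder
  # continuity: at high gap noise the left knee drops below its
  # noise-free level and below zero, so no tone is needed to stay active
  expect_lt(IT_L[IN == 8], IT_L[1])
  expect_lt(IT_L[IN == 8], 0)
  expect_true(all(IT_L < IT_R))
})

test_that("region classification follows the knee positions", {
  expect_identical(classify_region(5.9, 3.6), "IIIa")
  expect_identical(classify_region(10.5, 5.2), "IV")
  expect_identical(classify_region(12.7, 9.5), "IIIb")
  expect_identical(classify_region(3.0, 2.0), "I")
  expect_identical(classify_region(8, 13), "II")
  expect_identical(classify_region(8, -1), "V")
})

test_that("knee placement solve round-trips and reproduces the printed presets", {
  sol <- solve_knee_placement(0.2, 1.0)
  expect_equal(round(sol$a_E, 1), 5.9)
  expect_equal(round(sol$m, 1), 3.6)
  sol2 <- solve_knee_placement(-2, 2)
  expect_equal(round(sol2$a_E, 1), 10.5)
  expect_equal(sol2$m, sol2$a_E / 2) # symmetric targets
  sol3 <- solve_knee_placement(0.2, 6)
  expect_equal(round(sol3$a_E, 1), 12.7)
  expect_error(solve_knee_placement(1, 1), "below")

  for (a in c(-3, -1, 0.2, 2)) {
    for (b in c(a + 0.5, a + 2, 7)) {
      sol <- solve_knee_placement(a, b)
      expect_gt(sol$a_E, 4)
      k <- knee_IT(population_params(sol$a_E, sol$m))
      expect_equal(c(k$IT_L, k$IT_R), c(a, b), tolerance = 1e-8)
    }
  }
})

test_that("fixed points match the closed-form curve and carry stability", {
  fp <- find_equilibria(m2)
  expect_equal(nrow(fp), 3)
  expect_identical(fp$stability, c("stable", "unstable", "stable"))
  expect_true(fp$x[1] < fp$x[2] && fp$x[2] < fp$x[3])

  fp <- find_equilibria(m1, tone_on = TRUE, I_T = 1.5)
  expect_equal(nrow(fp), 1)
  expect_identical(fp$stability, "stable")
  expect_gt(fp$x, 0.5)
  fp <- find_equilibria(m1)
  expect_equal(nrow(fp), 1)
  expect_lt(fp$x, 0.5)

  # brute-force oracle: fixed points are the crossings of the closed-form
  # equilibrium curve at the imposed tone level
  for (IT in c(0.5, 0.8)) {
    fp <- find_equilibria(m1, tone_on = TRUE, I_T = IT)
    xs <- seq(1e-4, 1 - 1e-4, length.out = 20001)
    g <- equilibrium_IT(xs, m1$population) - IT
    idx <- which(sign(g[-length(g)]) * sign(g[-1]) < 0)
    crossings <- vapply(idx, function(i) {
      stats::uniroot(function(x) equilibrium_IT(x, m1$population) - IT,
                     c(xs[i], xs[i + 1]), tol = 1e-14)$root
    }, numeric(1))
    expect_equal(fp$x, sort(crossings), tolerance = 1e-8)
  }
})

test_that("symmetric configurations have mirror-image fixed points", {
  for (a_E in c(8, 10.487925853, 14)) {
    cfg <- model_config(population_params(a_E, a_E / 2),
                        input_params(), sustained = FALSE,
                        transient = FALSE, inhib = FALSE)
    fp <- find_equilibria(cfg)
    expect_equal(nrow(fp), 3)
    expect_equal(fp$x[2], 0.5, tolerance = 1e-9)
    expect_equal(fp$x[1] + fp$x[3], 1, tolerance = 1e-9)
  }
})

test_that("equilibrium branches label the middle segment unstable", {
  br <- equilibrium_branch(m1$population, m1$inputs)
  expect_named(br, c("x", "I_T", "stability"))
  kx <- knee_x(m1$population$a_E)
  mid <- br$x > kx$x_R & br$x < kx$x_L
  expect_true(all(br$stability[mid] == "unstable"))
  expect_true(all(br$stability[!mid] == "stable"))
})

test_that("the S-shape boundary is recovered at a_E = 4 by scanning", {
  expect_equal(sshape_boundary(), 4, tolerance = 1e-6)
})
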
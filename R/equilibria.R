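#' Equilibrium tone level for a given firing rate
#'
#' Setting `x' = 0` in the model with constant inputs and solving for the
#' tone level gives the closed-form equilibrium relation
#' `I_T(x, I_N) = m - log(1/x - 1) - a_E x + a_I I_N (1 - x) - alpha I_N`.
#' With `I_N = 0` this reduces to the tone-only relation whose critical
#' points are the saddle-node knees.
#'
#' @param x firing rate(s), strictly inside (0, 1).
#' @param pop a [population_params()] object.
#' @param inputs an [input_params()] object; may be `NULL` when `I_N = 0`.
#' @param I_N noise level.
#' @return Tone level(s) on the equilibrium curve.
#' @export
equilibrium_IT <- function(x, pop, inputs = NULL, I_N = 0) {
  stopifnot(inherits(pop, "tg_population"))
  if (any(x <= 0 | x >= 1)) stop("'x' must lie strictly inside (0, 1)")
  base <- pop$m - pop$k * log(1 / x - 1) - pop$a_E * x
  if (I_N == 0) return(base)
  if (is.null(inputs)) stop("'inputs' needed when I_N > 0")
  base + inputs$a_I * I_N * (1 - x) - inputs$alpha * I_N
}

#' Firing rates at the saddle-node knees
#'
#' The knees of the S-shaped equilibrium curve sit at
#' `x = (1 +/- sqrt(1 - 4 / (a_E + a_I I_N))) / 2` (left knee takes the
#' plus sign). They satisfy `x_L + x_R = 1` exactly and merge at
#' `x = 1/2` when `a_E + a_I I_N = 4`; below that the curve is monotone
#' and no knees exist.
#'
#' @param a_E recurrent excitation strength.
#' @param a_I noise-to-inhibition weight.
#' @param I_N noise level.
#' @return List with elements `x_L` and `x_R`.
#' @export
knee_x <- function(a_E, a_I = 0, I_N = 0) {
  g <- a_E + a_I * I_N
  if (g < 4)
    stop("no knees: equilibrium curve is not S-shaped (a_E + a_I*I_N < 4)")
  d <- sqrt(1 - 4 / g)
  list(x_L = (1 + d) / 2, x_R = (1 - d) / 2)
}

#' Tone levels at the knees
#'
#' Composes [knee_x()] with [equilibrium_IT()]. `IT_R` (right knee) is the
#' activation threshold for sustained input and `IT_L` (left knee) the
#' deactivation threshold; hysteresis is the gap between them.
#'
#' @inheritParams equilibrium_IT
#' @return List with `x_L`, `x_R`, `IT_L`, `IT_R`.
#' @export
knee_IT <- function(pop, inputs = NULL, I_N = 0) {
  a_I <- if (is.null(inputs)) 0 else inputs$a_I
  kx <- knee_x(pop$a_E, a_I, I_N)
  list(x_L = kx$x_L, x_R = kx$x_R,
       IT_L = equilibrium_IT(kx$x_L, pop, inputs, I_N),
       IT_R = equilibrium_IT(kx$x_R, pop, inputs, I_N))
}

#' Classify (a_E, m) parameter space by knee position
#'
#' Regions: `I` no knees (`a_E < 4`); `II` both knees above `I_T_max`
#' (activation impossible); `IIIa` both knees inside `(0, I_T_max)`
#' (hysteresis, sustained activation possible); `IIIb` left knee inside,
#' right knee above `I_T_max` (activation needs combined inputs); `IV`
#' knees straddle 0 (bistable at rest); `V` both knees negative (active
#' forever once on). Boundary cases are assigned to the first matching
#' region in this order.
#'
#' @param a_E,m population parameters.
#' @param I_T_max maximum tone level.
#' @return Region label as a character scalar.
#' @export
classify_region <- function(a_E, m, I_T_max = 5) {
  if (a_E <= 0) stop("'a_E' must be positive")
  if (a_E < 4) return("I")
  pop <- population_params(a_E, m)
  k <- knee_IT(pop)
  if (k$IT_L > I_T_max && k$IT_R > I_T_max) return("II")
  if (k$IT_L > 0 && k$IT_L < I_T_max && k$IT_R > 0 && k$IT_R < I_T_max)
    return("IIIa")
  if (k$IT_L > 0 && k$IT_L < I_T_max && k$IT_R >= I_T_max) return("IIIb")
  if (k$IT_L < 0 && k$IT_R > 0) return("IV")
  if (k$IT_L < 0 && k$IT_R < 0) return("V")
  # exactly-on-boundary leftovers: fold into the first compatible region
  if (k$IT_L >= I_T_max) "II" else if (k$IT_L >= 0) "IIIa" else "IV"
}

#' Solve for (a_E, m) from target knee tone levels
#'
#' Places the left and right knees of the tone-only equilibrium curve at
#' prescribed tone levels. The 2x2 nonlinear system reduces exactly to a
#' 1-D problem: with `d = sqrt(1 - 4/a_E)` and knee rates
#' `x_{L,R} = (1 +/- d)/2`, the knee separation satisfies
#' `a_E d + 2 log(x_R / x_L) = IT_R - IT_L`, which is solved for `a_E` by
#' bracketed root finding on (4, 100); then `m = (IT_L + IT_R + a_E) / 2`.
#'
#' @param IT_L,IT_R target tone levels at the left and right knees
#'   (`IT_L < IT_R`).
#' @param tol root tolerance on `a_E`.
#' @return List with full-precision `a_E` and `m`.
#' @export
solve_knee_placement <- function(IT_L, IT_R, tol = 1e-12) {
  if (!(IT_L < IT_R)) stop("left knee must be below right knee")
  gap <- IT_R - IT_L
  fn <- function(a_E) {
    d <- sqrt(1 - 4 / a_E)
    a_E * d + 2 * log((1 - d) / (1 + d)) - gap
  }
  a_E <- stats::uniroot(fn, c(4 + 1e-9, 100), tol = tol)$root
  list(a_E = a_E, m = (IT_L + IT_R + a_E) / 2)
}

# x grid for fixed-point bracketing: uniform core plus log-spaced points
# near both edges (strong inhibition can push the inactive state below
# 1e-6, outside a uniform grid).
fp_grid <- function(n = 2001) {
  edges <- 10^seq(-14, -6, by = 0.5)
  sort(unique(c(edges, seq(1e-6, 1 - 1e-6, length.out = n), 1 - edges)))
}

frozen_drift <- function(config, tone_on, noise_on, I_T, I_N) {
  p <- config$population; i <- config$inputs
  sus <- if (config$sustained)
    sustained_input(tone_on, noise_on, I_T, I_N, i) else 0
  function(x) {
    u <- p$a_E * x + sus
    if (config$inhib) u <- u - inhib_input(x, noise_on, I_N, i)
    -x + sigmoid(u, p)
  }
}

frozen_drift_slope <- function(config, noise_on, I_N) {
  p <- config$population; i <- config$inputs
  gain <- p$a_E +
    if (config$inhib) i$a_I * I_N * as.numeric(noise_on) else 0
  function(x, drift_x) {
    # d/dx [-x + f(u(x))]; f'(u) recovered from f(u) = x + drift
    f <- x + drift_x
    -1 + gain * f * (1 - f) / p$k
  }
}

#' Fixed points of the frozen (constant-input) system
#'
#' Finds all equilibria of `x' = -x + f(drive(x))` for constant tone and
#' noise levels with the transient variables at zero, by sign-change
#' bracketing on a dense grid followed by root polishing, and classifies
#' each by the sign of the linearized drift (negative slope: stable).
#' Between one and three fixed points exist; in the bistable regime the
#' inactive state `x_I`, saddle `x_S` and active state `x_A` appear in
#' increasing order.
#'
#' @param config a [model_config()].
#' @param tone_on,noise_on constant indicator values.
#' @param I_T,I_N constant levels.
#' @return `data.frame` with columns `x` and `stability`
#'   (`"stable"`/`"unstable"`/`"marginal"`), ordered by `x`.
#' @export
find_equilibria <- function(config, tone_on = FALSE, noise_on = FALSE,
                            I_T = 0, I_N = 0) {
  stopifnot(inherits(config, "tg_config"))
  drift <- frozen_drift(config, tone_on, noise_on, I_T, I_N)
  slope <- frozen_drift_slope(config, noise_on, I_N)
  xs <- fp_grid()
  v <- drift(xs)
  roots <- numeric(0)
  for (i in which(sign(v[-length(v)]) * sign(v[-1]) < 0)) {
    roots <- c(roots,
               stats::uniroot(drift, c(xs[i], xs[i + 1]), tol = 1e-14)$root)
  }
  # roots beyond the grid edges: the drift is positive at x = 0+ and
  # negative at x = 1-, so a negative (positive) sign at the first (last)
  # grid point brackets an equilibrium outside the grid
  if (v[1] < 0)
    roots <- c(roots,
               stats::uniroot(drift, c(1e-300, xs[1]), tol = 1e-16)$root)
  if (v[length(v)] > 0)
    roots <- c(roots,
               stats::uniroot(drift, c(xs[length(xs)], 1 - 1e-16),
                              tol = 1e-16)$root)
  # exact zeros on the grid (degenerate but possible)
  roots <- sort(unique(c(roots, xs[v == 0])))
  st <- vapply(roots, function(r) {
    s <- slope(r, drift(r))
    if (abs(s) < 1e-10) "marginal" else if (s < 0) "stable" else "unstable"
  }, character(1))
  data.frame(x = roots, stability = st)
}

#' Sample an equilibrium branch for plotting/export
#'
#' Evaluates the closed-form equilibrium curve `I_T(x, I_N)` on a firing
#' rate grid and labels each sample stable or unstable (the branch between
#' the knees is the unstable middle branch).
#'
#' @inheritParams equilibrium_IT
#' @param n number of samples.
#' @return `data.frame` with columns `x`, `I_T`, `stability`.
#' @export
equilibrium_branch <- function(pop, inputs = NULL, I_N = 0, n = 401) {
  xs <- seq(0.001, 0.999, length.out = n)
  it <- equilibrium_IT(xs, pop, inputs, I_N)
  a_I <- if (is.null(inputs)) 0 else inputs$a_I
  stab <- rep("stable", n)
  if (pop$a_E + a_I * I_N >= 4) {
    kx <- knee_x(pop$a_E, a_I, I_N)
    stab[xs > kx$x_R & xs < kx$x_L] <- "unstable"
  }
  data.frame(x = xs, I_T = it, stability = stab)
}

#' Smallest recurrent excitation giving an S-shaped equilibrium curve
#'
#' Scans for the appearance of two critical points of the tone-only
#' equilibrium relation (the two knees) and bisects the boundary of the
#' existence set. The analytic boundary is `a_E = 4`; this routine
#' recovers it numerically from the curve shape itself.
#'
#' @param lower,upper scan bracket for `a_E`.
#' @param n number of grid points for critical-point counting.
#' @param tol bisection tolerance.
#' @return Boundary value of `a_E`.
#' @export
sshape_boundary <- function(lower = 1, upper = 10, n = 20001, tol = 1e-9) {
  xs <- seq(1e-4, 1 - 1e-4, length.out = n)
  dIT <- function(a_E) 1 / (xs * (1 - xs)) - a_E # d I_T / dx at I_N = 0
  has_knees <- function(a_E) {
    sum(diff(sign(dIT(a_E))) != 0) >= 2
  }
  if (has_knees(lower) || !has_knees(upper))
    stop("bracket does not straddle the S-shape boundary")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_knees(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
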
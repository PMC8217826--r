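#' Right-hand side of the reduced (x, s) phase-plane system
#'
#' Between acoustic edges the model with a single active transient reduces
#' to `tau x' = -x + f(a_E x + I_sus - I_inhib + gamma s)`,
#' `tau s' = -s`, with the sustained and inhibitory terms frozen at the
#' current tone/noise levels. `s` is signed: onset analysis uses
#' `gamma = gamma_on` and positive `s`, offset analysis `gamma_off` and
#' negative `s`.
#'
#' @param config a [model_config()].
#' @param x,s state.
#' @param gamma transient scaling used in this reduction.
#' @param tone_on,noise_on frozen indicators.
#' @param I_T,I_N frozen levels.
#' @return `c(dx, ds)`.
#' @export
phase_rhs <- function(config, x, s, gamma, tone_on = FALSE,
                      noise_on = FALSE, I_T = 0, I_N = 0) {
  p <- config$population
  u <- phase_drive(config, x, s, gamma, tone_on, noise_on, I_T, I_N)
  c(dx = (-x + sigmoid(u, p)) / p$tau, ds = -s / p$tau)
}

phase_drive <- function(config, x, s, gamma, tone_on, noise_on, I_T, I_N) {
  p <- config$population; i <- config$inputs
  u <- p$a_E * x + gamma * s
  if (config$sustained)
    u <- u + sustained_input(tone_on, noise_on, I_T, I_N, i)
  if (config$inhib) # raw form: solver trial steps may leave [0, 1]
    u <- u - i$a_I * I_N * (1 - x) * as.numeric(noise_on)
  u
}

#' Jacobian of the (x, s) system
#'
#' The transient equation is autonomous, so `J21 = 0` and `J22 = -1/tau`;
#' the rate row is `J11 = (-1 + (a_E + a_I I_N) f'(u)) / tau` (the
#' inhibition term contributes `+ a_I I_N f'(u)` through its `(1 - x)`
#' factor when that pathway carries noise) and `J12 = gamma f'(u) / tau`.
#'
#' @inheritParams phase_rhs
#' @return 2x2 numeric matrix.
#' @export
jacobian_xs <- function(config, x, s, gamma, tone_on = FALSE,
                        noise_on = FALSE, I_T = 0, I_N = 0) {
  p <- config$population; i <- config$inputs
  u <- phase_drive(config, x, s, gamma, tone_on, noise_on, I_T, I_N)
  fp <- sigmoid_slope(u, p)
  gain <- p$a_E +
    if (config$inhib) i$a_I * I_N * as.numeric(noise_on) else 0
  matrix(c((-1 + gain * fp) / p$tau, 0,
           gamma * fp / p$tau, -1 / p$tau),
         nrow = 2)
}

#' Linear approximation to the separatrix
#'
#' In the bistable phase plane the stable manifold of the saddle
#' `(x_S, 0)` divides the basins of the inactive and active states.
#' Because the rate and transient variables share one time constant, the
#' eigenvector construction collapses to the exact line
#' `S(x) = c (x_S - x)` with `c = (a_E + a_I I_N) / gamma` (the `a_I I_N`
#' term present only when the inhibition pathway carries noise). An onset
#' transient activates the population iff `s(t_on) > S(x_I)`.
#'
#' @param config a [model_config()].
#' @param gamma transient scaling (`gamma_on` for onsets, `gamma_off` for
#'   offsets).
#' @param I_T,I_N frozen input levels; the indicators are taken as
#'   "on" whenever the corresponding level is positive.
#' @return Object of class `tg_separatrix` with `x_S`, `slope_scale`, the
#'   flanking stable states `x_I`/`x_A` and the context used.
#' @export
linear_separatrix <- function(config, gamma, I_T = 0, I_N = 0) {
  stopifnot(inherits(config, "tg_config"))
  if (gamma <= 0) stop("'gamma' must be positive")
  fp <- find_equilibria(config, tone_on = I_T > 0, noise_on = I_N > 0,
                        I_T = I_T, I_N = I_N)
  if (nrow(fp) < 3)
    stop("monostable regime: no saddle for these constant inputs")
  i <- config$inputs
  slope <- (config$population$a_E +
              if (config$inhib && I_N > 0) i$a_I * I_N else 0) / gamma
  structure(list(x_S = fp$x[2], x_I = fp$x[1], x_A = fp$x[3],
                 slope_scale = slope, gamma = gamma,
                 I_T = I_T, I_N = I_N),
            class = "tg_separatrix")
}

#' Height of a linear separatrix at given firing rates
#'
#' @param sep a [linear_separatrix()] object.
#' @param x firing rate(s).
#' @export
separatrix_height <- function(sep, x) {
  sep$slope_scale * (sep$x_S - x)
}

#' Numerically integrated separatrix (stable manifold of the saddle)
#'
#' Tracks the saddle's stable manifold by integrating the (x, s) system in
#' reversed time from `(x_S, 0) +/- eps * v`, where `v` is the
#' stable-manifold eigenvector. Used as an oracle for the linear
#' approximation, which is exact only at the saddle.
#'
#' @inheritParams linear_separatrix
#' @param eps displacement along the eigenvector.
#' @param x_lim integration is truncated when `x` leaves this interval.
#' @return `data.frame` with columns `x`, `s`, `branch`; the first row is
#'   the saddle itself.
#' @export
numeric_separatrix <- function(config, gamma, I_T = 0, I_N = 0,
                               eps = 1e-6, x_lim = c(0.001, 0.999)) {
  sep <- linear_separatrix(config, gamma, I_T, I_N)
  tau <- config$population$tau
  c0 <- sep$slope_scale
  v <- c(1, -c0) / sqrt(1 + c0^2) # stable eigenvector (lambda = -1/tau)
  s_max <- 2 * c0 * max(abs(sep$x_S - x_lim))
  derivs <- function(t, y, parms) {
    list(-phase_rhs(config, y[1], y[2], gamma,
                    tone_on = I_T > 0, noise_on = I_N > 0,
                    I_T = I_T, I_N = I_N))
  }
  rootfun <- function(t, y, parms) {
    c(y[1] - x_lim[1], y[1] - x_lim[2], abs(y[2]) - s_max)
  }
  run <- function(sgn) {
    y0 <- c(sep$x_S, 0) + sgn * eps * v
    times <- seq(0, 30 * tau, length.out = 1500)
    out <- deSolve::lsodar(y0, times, derivs, parms = NULL,
                           rootfunc = rootfun,
                           rtol = 1e-10, atol = 1e-12)
    data.frame(x = out[, 2], s = out[, 3])
  }
  lower <- run(+1)  # x decreasing branch (s > 0)
  upper <- run(-1)  # x increasing branch (s < 0)
  rbind(data.frame(x = sep$x_S, s = 0, branch = "saddle"),
        cbind(lower, branch = "inactive_side"),
        cbind(upper, branch = "active_side"))
}

#' Calibrate the onset scaling so the tone threshold is 1
#'
#' Convention: a tone of unit level is exactly at activation threshold.
#' For a transient-only (bistable) configuration this fixes
#' `gamma_on = a_E (x_S - x_I)` using the input-free fixed points. When
#' sustained inputs are present the saddle itself moves with the tone, so
#' the calibration uses the saddle of the system with sustained drive
#' `I_T = 1`: `gamma_on = a_E (x_S(1, 0) - x_I(0, 0))`.
#'
#' @param config a [model_config()]; the transient pathway must be
#'   enabled.
#' @return Calibrated `gamma_on` at full precision.
#' @export
calibrate_gamma_on <- function(config) {
  stopifnot(inherits(config, "tg_config"))
  if (!config$transient)
    stop("transient pathway disabled: nothing to calibrate")
  a_E <- config$population$a_E
  rest <- find_equilibria(config)
  if (!config$sustained) {
    if (nrow(rest) < 3)
      stop("input-free system is not bistable: saddle absent")
    return(a_E * (rest$x[2] - rest$x[1]))
  }
  x_I <- rest$x[1]
  fp <- find_equilibria(config, tone_on = TRUE, I_T = 1)
  if (nrow(fp) < 3)
    stop("no saddle at unit tone level: cannot calibrate")
  a_E * (fp$x[2] - x_I)
}

#' Does an initial state cross the separatrix?
#'
#' @param x0,s0 initial state (signed `s0`; offsets are negative).
#' @param sep a [linear_separatrix()].
#' @param direction `"up"` for activation (crossing requires
#'   `s0 > S(x0)`), `"down"` for deactivation (`s0 < S(x0)`).
#' @return `"crosses"`, `"stays"` or `"at-threshold"`.
#' @export
crosses_separatrix <- function(x0, s0, sep,
                               direction = c("up", "down")) {
  direction <- match.arg(direction)
  h <- s0 - separatrix_height(sep, x0)
  if (h == 0) return("at-threshold")
  hit <- if (direction == "up") h > 0 else h < 0
  if (hit) "crosses" else "stays"
}
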
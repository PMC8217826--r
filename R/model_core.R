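#' Population-level parameters of the firing-rate equation
#'
#' The model describes the activity `x` of a tone-tuned neural population by
#' `tau * x' = -x + f(a_E * x + I(t))`, where `f` is a logistic sigmoid with
#' half-maximum `m` and slope scale `k`, and `a_E` is the strength of
#' recurrent excitation within the population. All levels are unitless;
#' `tau` is in seconds and sets the time scale of both the firing rate and
#' the transient input variables.
#'
#' @param a_E recurrent excitation strength (> 0). Values above 4 give an
#'   S-shaped equilibrium curve with two saddle-node knees.
#' @param m sigmoid half-maximum.
#' @param k sigmoid slope scale. Fixed at 1 in all standard configurations;
#'   changing it rescales every unitless level in the model.
#' @param tau time constant in seconds. Equilibrium and threshold analytics
#'   are independent of `tau`; it only sets simulation time scales.
#' @return An object of class `tg_population`.
#' @seealso [input_params()], [model_config()], [model_preset()]
#' @export
population_params <- function(a_E, m, k = 1, tau = 0.01) {
  stopifnot(is.numeric(a_E), length(a_E) == 1L, is.finite(a_E),
            is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (a_E <= 0) stop("'a_E' must be positive")
  if (k <= 0) stop("'k' must be positive")
  if (tau <= 0) stop("'tau' must be positive")
  structure(list(a_E = a_E, m = m, k = k, tau = tau),
            class = "tg_population")
}

#' Input-pathway weights
#'
#' Collects the weights of the four sound-driven input components:
#' the sustained tone drive `I_T`, the sustained noise leak into the tone
#' channel (`alpha`), the suppression of transient onset/offset amplitudes
#' by coincident noise (`beta`), the noise-driven mutual inhibition
#' (`a_I`), and the scaling of the exponentially decaying onset and offset
#' transients (`gamma_on`, `gamma_off`).
#'
#' @param alpha noise-to-sustained-excitation weight (>= 0).
#' @param beta noise-to-transient-suppression weight (>= 0); a transient
#'   triggered while noise is on has amplitude `max(0, I_T - beta * I_N)`.
#' @param a_I noise-to-inhibition weight (>= 0); the inhibitory drive is
#'   `a_I * I_N * (1 - x)` while noise is on, vanishing as the population
#'   saturates (mutual inhibition).
#' @param gamma_on,gamma_off scalings applied once to the onset and offset
#'   transient variables inside the total drive.
#' @param I_T_max,I_N_max caps on tone and noise levels (defaults 5 and 10).
#' @return An object of class `tg_inputs`.
#' @export
input_params <- function(alpha = 0, beta = 0, a_I = 0,
                         gamma_on = 0, gamma_off = 0,
                         I_T_max = 5, I_N_max = 10) {
  w <- c(alpha = alpha, beta = beta, a_I = a_I,
         gamma_on = gamma_on, gamma_off = gamma_off)
  if (!all(is.finite(w)) || any(w < 0))
    stop("input weights must be finite and non-negative")
  if (!is.numeric(I_T_max) || I_T_max <= 1)
    stop("'I_T_max' must exceed 1 (tone threshold is 1 by convention)")
  if (!is.numeric(I_N_max) || I_N_max <= 0)
    stop("'I_N_max' must be positive")
  structure(list(alpha = alpha, beta = beta, a_I = a_I,
                 gamma_on = gamma_on, gamma_off = gamma_off,
                 I_T_max = I_T_max, I_N_max = I_N_max),
            class = "tg_inputs")
}

#' Full model configuration
#'
#' Bundles population parameters, input weights and the set of enabled
#' input pathways. The three standard variants differ only in which
#' pathways are active: the hysteresis variant uses sustained excitation
#' and inhibition, the bistable variant uses transients only, and the
#' combined variant uses all three.
#'
#' @param population a [population_params()] object.
#' @param inputs an [input_params()] object.
#' @param sustained,transient,inhib logical pathway flags.
#' @param label variant label, one of `"model1"`, `"model2"`, `"model3"`,
#'   `"custom"`.
#' @return An object of class `tg_config`.
#' @export
model_config <- function(population, inputs = input_params(),
                         sustained = TRUE, transient = TRUE, inhib = TRUE,
                         label = "custom") {
  stopifnot(inherits(population, "tg_population"),
            inherits(inputs, "tg_inputs"),
            is.logical(sustained), is.logical(transient), is.logical(inhib))
  label <- match.arg(label, c("custom", "model1", "model2", "model3"))
  structure(list(population = population, inputs = inputs,
                 sustained = isTRUE(sustained),
                 transient = isTRUE(transient),
                 inhib = isTRUE(inhib),
                 label = label),
            class = "tg_config")
}

#' @export
print.tg_config <- function(x, ...) {
  p <- x$population; i <- x$inputs
  cat("<tg_config>", x$label, "\n")
  cat(sprintf("  population: a_E = %.6g, m = %.6g, k = %g, tau = %g s\n",
              p$a_E, p$m, p$k, p$tau))
  cat(sprintf("  inputs: alpha = %g, beta = %g, a_I = %g, gamma_on = %.6g, gamma_off = %.6g\n",
              i$alpha, i$beta, i$a_I, i$gamma_on, i$gamma_off))
  cat(sprintf("  pathways: sustained=%s transient=%s inhib=%s\n",
              x$sustained, x$transient, x$inhib))
  invisible(x)
}

#' Instantaneous state of the driven system
#'
#' @param x firing rate, strictly inside (0, 1).
#' @param s_on,s_off non-negative transient variables; `s_off` is applied
#'   with a negative sign in the total drive.
#' @return Named numeric vector of class `tg_state`.
#' @export
drive_state <- function(x, s_on = 0, s_off = 0) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (x <= 0 || x >= 1) stop("'x' must lie strictly inside (0, 1)")
  if (s_on < 0 || s_off < 0) stop("transient variables must be non-negative")
  structure(c(x = x, s_on = s_on, s_off = s_off), class = "tg_state")
}

#' Sigmoid activation function
#'
#' `f(u) = 1 / (1 + exp(-(u - m)/k))`: strictly increasing, mapping the
#' real line onto the open interval (0, 1), with `f(m) = 1/2`.
#'
#' @param u drive level (any real number; vectorized).
#' @param pop a [population_params()] object.
#' @return activation in (0, 1).
#' @export
sigmoid <- function(u, pop) {
  1 / (1 + exp(-(u - pop$m) / pop$k))
}

#' Derivative of the sigmoid with respect to its argument
#'
#' For `k = 1` this is `f(u) * (1 - f(u))`.
#'
#' @inheritParams sigmoid
#' @export
sigmoid_slope <- function(u, pop) {
  f <- sigmoid(u, pop)
  f * (1 - f) / pop$k
}

#' Rectifier
#'
#' `[u]_+ = max(0, u)`, applied elementwise.
#'
#' @param u signed level(s).
#' @export
rectify <- function(u) {
  pmax(0, u)
}

#' Initial amplitude of a tone-edge transient
#'
#' A tone onset (or offset) starting in silence triggers a transient of
#' amplitude `I_T`. If noise is on at the edge, the acoustic edge is
#' obscured and the amplitude is reduced to `max(0, I_T - beta * I_N)`.
#' The `gamma` scaling is applied later, once, in [total_drive()]; the
#' transient variable itself carries the raw rectified amplitude.
#'
#' @param I_T tone level in `[0, I_T_max]`.
#' @param I_N noise level in `[0, I_N_max]`.
#' @param noise_coincident is noise on at the edge time?
#' @param inputs an [input_params()] object.
#' @return Non-negative transient amplitude.
#' @export
transient_amplitude <- function(I_T, I_N, noise_coincident, inputs) {
  stopifnot(inherits(inputs, "tg_inputs"), is.logical(noise_coincident))
  if (I_T < 0 || I_N < 0) stop("levels must be non-negative")
  if (I_T > inputs$I_T_max) stop("'I_T' exceeds I_T_max")
  if (I_N > inputs$I_N_max) stop("'I_N' exceeds I_N_max")
  if (isTRUE(noise_coincident)) rectify(I_T - inputs$beta * I_N) else I_T
}

#' Sustained (piecewise-constant) excitatory drive
#'
#' `I_T` while a tone is on plus the partial noise contribution
#' `alpha * I_N` while noise is on.
#'
#' @param tone_on,noise_on logical indicators at the current time.
#' @param I_T,I_N tone and noise levels.
#' @param inputs an [input_params()] object.
#' @export
sustained_input <- function(tone_on, noise_on, I_T, I_N, inputs) {
  I_T * as.numeric(tone_on) + inputs$alpha * I_N * as.numeric(noise_on)
}

#' Noise-driven inhibitory drive with mutual inhibition
#'
#' `a_I * I_N * (1 - x)` while noise is on; the `(1 - x)` factor expresses
#' suppression of the inhibitory subpopulation by the active tone
#' population, so the inhibition vanishes as `x` approaches 1.
#'
#' @param x firing rate in `[0, 1]`.
#' @inheritParams sustained_input
#' @export
inhib_input <- function(x, noise_on, I_N, inputs) {
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
  inputs$a_I * I_N * (1 - x) * as.numeric(noise_on)
}

#' Total drive entering the sigmoid
#'
#' Assembles `u = a_E * x + I(t)` from the enabled pathways:
#' sustained excitation, onset transient (`+ gamma_on * s_on`), offset
#' transient (`- gamma_off * s_off`) and noise-driven inhibition.
#'
#' @param state a [drive_state()] (or named vector with `x`, `s_on`,
#'   `s_off`).
#' @param tone_on,noise_on logical indicators at the current time.
#' @param I_T,I_N tone and noise levels.
#' @param config a [model_config()] object.
#' @return Scalar drive level `u`.
#' @export
total_drive <- function(state, tone_on, noise_on, I_T, I_N, config) {
  p <- config$population; i <- config$inputs
  x <- unname(state[["x"]])
  u <- p$a_E * x
  if (config$sustained)
    u <- u + sustained_input(tone_on, noise_on, I_T, I_N, i)
  if (config$transient)
    u <- u + i$gamma_on * unname(state[["s_on"]]) -
      i$gamma_off * unname(state[["s_off"]])
  if (config$inhib) # raw form: integrator trial steps may leave [0, 1]
    u <- u - i$a_I * I_N * (1 - x) * as.numeric(noise_on)
  u
}

#' Right-hand side of the model equations
#'
#' Time derivatives of `(x, s_on, s_off)`:
#' `x' = (-x + f(u)) / tau` with `u` from [total_drive()], and
#' `s' = -s / tau` for both transients (their decay shares the firing-rate
#' time constant).
#'
#' @inheritParams total_drive
#' @return Named numeric vector of derivatives.
#' @export
model_rhs <- function(state, tone_on, noise_on, I_T, I_N, config) {
  p <- config$population
  u <- total_drive(state, tone_on, noise_on, I_T, I_N, config)
  c(x = (-unname(state[["x"]]) + sigmoid(u, p)) / p$tau,
    s_on = -unname(state[["s_on"]]) / p$tau,
    s_off = -unname(state[["s_off"]]) / p$tau)
}
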
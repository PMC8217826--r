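#' Standard model variants
#'
#' Builds one of the three reference configurations, each defined by where
#' the knees of its tone-only equilibrium curve sit (so that a unit tone
#' is always the activation threshold) and by which input pathways it
#' uses:
#'
#' * `model1` — hysteresis variant (Region IIIa): knees at tone levels
#'   0.2 and 1.0; sustained excitation and noise-driven inhibition only
#'   (`alpha = 0.168`, `a_I = 1.124`). Continuity rides on hysteresis:
#'   gap noise keeps the active branch alive.
#' * `model2` — bistable variant (Region IV): knees at -2 and 2, making
#'   the population bistable with no input; transient inputs only
#'   (`beta = 2/3`), with `gamma_on = gamma_off` calibrated so the
#'   tone-only threshold is 1 (value 5.2 to one decimal). Continuity rides
#'   on noise suppressing the offset transient.
#' * `model3` — combined variant (Region IIIb): knees at 0.2 and 6, so
#'   neither sustained nor transient input alone can activate it; all
#'   pathways (`alpha = 0.5`, `beta = 0.05`, `a_I = 7`,
#'   `gamma_off = 0.88`, `gamma_on` calibrated, 9.6 to one decimal).
#'
#' Population parameters are stored at full knee-placed precision; the
#' conventional one-decimal roundings (e.g. `a_E = 5.9`, `m = 3.6` for
#' `model1`) are attached as the `printed` element for reporting.
#'
#' @param variant `"model1"`, `"model2"` or `"model3"`.
#' @param tau time constant in seconds.
#' @return A [model_config()] with an extra `printed` element.
#' @export
model_preset <- function(variant = c("model1", "model2", "model3"),
                         tau = 0.01) {
  variant <- match.arg(variant)
  if (variant == "model1") {
    kp <- solve_knee_placement(0.2, 1.0)
    cfg <- model_config(
      population_params(kp$a_E, kp$m, tau = tau),
      input_params(alpha = 0.168, a_I = 1.124),
      sustained = TRUE, transient = FALSE, inhib = TRUE,
      label = "model1")
    printed <- list(a_E = 5.9, m = 3.6, region = "IIIa")
  } else if (variant == "model2") {
    kp <- solve_knee_placement(-2, 2)
    base <- model_config(
      population_params(kp$a_E, kp$m, tau = tau),
      input_params(beta = 2 / 3, gamma_on = 1, gamma_off = 1),
      sustained = FALSE, transient = TRUE, inhib = FALSE,
      label = "model2")
    g <- calibrate_gamma_on(base)
    cfg <- model_config(
      base$population,
      input_params(beta = 2 / 3, gamma_on = g, gamma_off = g),
      sustained = FALSE, transient = TRUE, inhib = FALSE,
      label = "model2")
    printed <- list(a_E = 10.5, m = 5.2, gamma_on = 5.2, gamma_off = 5.2,
                    region = "IV")
  } else {
    kp <- solve_knee_placement(0.2, 6)
    base <- model_config(
      population_params(kp$a_E, kp$m, tau = tau),
      input_params(alpha = 0.5, beta = 0.05, a_I = 7,
                   gamma_on = 1, gamma_off = 0.88),
      sustained = TRUE, transient = TRUE, inhib = TRUE,
      label = "model3")
    g <- calibrate_gamma_on(base)
    cfg <- model_config(
      base$population,
      input_params(alpha = 0.5, beta = 0.05, a_I = 7,
                   gamma_on = g, gamma_off = 0.88),
      sustained = TRUE, transient = TRUE, inhib = TRUE,
      label = "model3")
    printed <- list(a_E = 12.7, m = 9.5, gamma_on = 9.6, gamma_off = 0.88,
                    region = "IIIb")
  }
  cfg$printed <- printed
  cfg
}
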
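# Shared fixtures: the three standard configurations, built once per run.
m1 <- model_preset("model1")
m2 <- model_preset("model2")
m3 <- model_preset("model3")

# forward integration of the frozen (x, s) phase-plane system; used as an
# independent oracle for basin membership
forward_final_x <- function(config, x0, s0, gamma, I_T = 0, I_N = 0,
                            horizon = 60) {
  tau <- config$population$tau
  derivs <- function(t, y, p) {
    list(phase_rhs(config, y[1], y[2], gamma,
                   tone_on = I_T > 0, noise_on = I_N > 0,
                   I_T = I_T, I_N = I_N))
  }
  out <- deSolve::ode(c(x0, s0), seq(0, horizon * tau, length.out = 40),
                      derivs, NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), 2])
}

# interpolator over a numeric separatrix table
separatrix_fun <- function(num) {
  num <- num[order(num$x), ]
  stats::approxfun(num$x, num$s)
}

verdict_of <- function(config, kind, I_T, I_N = 0) {
  sim <- simulate_model(config, build_scenario(kind, I_T = I_T, I_N = I_N))
  classify_response(sim)$verdict
}
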
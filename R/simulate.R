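#' Event-driven simulation of a stimulus response
#'
#' Integrates the full `(x, s_on, s_off)` system across a stimulus.
#' Integration proceeds piecewise between acoustic edges (tone and noise
#' boundaries), where the right-hand side is smooth; at each tone onset
#' (offset) the corresponding transient variable is reset to its
#' [transient_amplitude()], reduced if noise is on at — or abuts exactly
#' at — the edge. The firing rate starts from the inactive fixed point of
#' the input-free system unless `x0` is given.
#'
#' Transients are carried as state variables rather than closed-form
#' exponentials so that `(x, s)` phase-plane trajectories fall out of the
#' result directly.
#'
#' @param config a [model_config()].
#' @param stim a [build_scenario()] stimulus.
#' @param x0 optional initial firing rate in (0, 1).
#' @param dt output grid spacing in seconds.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param check_caps validate stimulus levels against the configured caps.
#' @return Object of class `tg_simulation`: `times`, `x`, `s_on`, `s_off`,
#'   a `drive` data frame with the four input components, and echoes of
#'   the stimulus, config and solver settings.
#' @export
simulate_model <- function(config, stim, x0 = NULL, dt = 1e-3,
                           rtol = 1e-7, atol = 1e-9, check_caps = TRUE) {
  stopifnot(inherits(config, "tg_config"), inherits(stim, "tg_stimulus"))
  i <- config$inputs
  if (check_caps) {
    if (stim$I_T > i$I_T_max) stop("stimulus tone level exceeds I_T_max")
    if (stim$I_N > i$I_N_max) stop("stimulus noise level exceeds I_N_max")
  }
  if (is.null(x0)) {
    x0 <- find_equilibria(config)$x[1]
  } else if (x0 <= 0 || x0 >= 1) stop("'x0' must lie strictly inside (0, 1)")

  ev <- edge_events(stim)
  breaks <- sort(unique(c(0, stim$duration,
                          as.vector(stim$tone), as.vector(stim$noise))))
  state <- c(x = x0, s_on = 0, s_off = 0)
  tau <- config$population$tau

  times_all <- numeric(0)
  traj <- NULL
  flags <- NULL
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    mid <- (t0 + t1) / 2
    ind <- indicators(stim, mid)
    # transient resets at the segment's left edge
    here <- ev[abs(ev$time - t0) < 1e-12, , drop = FALSE]
    for (r in seq_len(nrow(here))) {
      amp <- transient_amplitude(stim$I_T, stim$I_N,
                                 here$noise_coincident[r], i)
      if (here$kind[r] == "onset") state[["s_on"]] <- amp
      else state[["s_off"]] <- amp
    }
    derivs <- function(t, y, parms) {
      list(unname(model_rhs(y, ind$tone_on, ind$noise_on,
                            stim$I_T, stim$I_N, config)))
    }
    times <- unique(c(seq(t0, t1, by = dt), t1))
    out <- deSolve::ode(state, times, derivs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    state <- stats::setNames(as.numeric(out[nrow(out), 2:4]),
                             c("x", "s_on", "s_off"))
    keep <- if (is.null(traj)) seq_len(nrow(out)) else seq(2, nrow(out))
    times_all <- c(times_all, out[keep, 1])
    traj <- rbind(traj, out[keep, 2:4, drop = FALSE])
    flags <- rbind(flags, matrix(c(ind$tone_on, ind$noise_on),
                                 nrow = length(keep), ncol = 2,
                                 byrow = TRUE))
  }
  x <- traj[, 1]; s_on <- traj[, 2]; s_off <- traj[, 3]
  tone_on <- flags[, 1]; noise_on <- flags[, 2]
  drive <- data.frame(
    I_sustain = if (config$sustained)
      sustained_input(tone_on, noise_on, stim$I_T, stim$I_N, i) else 0,
    I_onset = if (config$transient) i$gamma_on * s_on else 0,
    I_offset = if (config$transient) i$gamma_off * s_off else 0,
    I_inhib = if (config$inhib)
      inhib_input(x, noise_on, stim$I_N, i) else 0)
  structure(list(times = times_all, x = x, s_on = s_on, s_off = s_off,
                 drive = drive, stimulus = stim, config = config,
                 solver = list(dt = dt, rtol = rtol, atol = atol,
                               x0 = x0)),
            class = "tg_simulation")
}

#' @export
print.tg_simulation <- function(x, ...) {
  cat("<tg_simulation>", x$stimulus$kind,
      sprintf("(%d samples over %g s), x range [%.4f, %.4f]\n",
              length(x$times), max(x$times), min(x$x), max(x$x)))
  invisible(x)
}

#' Firing rate at a given time (linear interpolation)
#'
#' @param sim a [simulate_model()] result.
#' @param t time(s) within the simulated window.
#' @export
rate_at <- function(sim, t) {
  if (any(t < min(sim$times) | t > max(sim$times)))
    stop("probe time outside the simulated window")
  stats::approx(sim$times, sim$x, xout = t)$y
}

#' Classify a simulated response
#'
#' Probes the firing rate 1 ms before the end of each meaningful segment
#' ("active" means `x` above `x_active`, default 0.5, which separates the
#' basins in every standard regime) and derives a scenario verdict:
#'
#' * tone_only / masking: `"activated"` if active at tone end, otherwise
#'   `"inactive"` (reported as `"masked"` for the masking scenario).
#' * continuity: `"continuous"` if active at the ends of the first tone,
#'   the gap and the second tone; `"discontinuous"` if the first tone
#'   activates but the rate falls during the gap; `"inactive"` if the
#'   first tone never activates.
#'
#' @param sim a [simulate_model()] result.
#' @param x_active activity criterion on the firing rate.
#' @param probe_offset probe lead time before each segment end (s).
#' @return List with `verdict` and the per-probe table.
#' @export
classify_response <- function(sim, x_active = 0.5, probe_offset = 1e-3) {
  stim <- sim$stimulus
  if (stim$kind == "continuity") {
    pt <- c(tone1_end = stim$tone[1, 2], gap_end = stim$tone[2, 1],
            tone2_end = stim$tone[2, 2]) - probe_offset
  } else {
    pt <- c(tone_end = stim$tone[1, 2]) - probe_offset
  }
  xv <- rate_at(sim, pt)
  active <- xv > x_active
  probes <- data.frame(probe = names(pt), time = unname(pt),
                       x = unname(xv), active = unname(active))
  verdict <- if (stim$kind == "continuity") {
    if (!active[1]) "inactive"
    else if (all(active)) "continuous"
    else if (!active[2]) "discontinuous"
    else "interrupted"
  } else if (stim$kind == "masking") {
    if (active[1]) "activated" else "masked"
  } else {
    if (active[1]) "activated" else "inactive"
  }
  list(verdict = verdict, probes = probes)
}

#' Measure a threshold by bisection on simulated responses
#'
#' Bisects a stimulus level against a monotone response predicate:
#'
#' * `"activation"`: tone-only scenario, varying `I_T`; threshold tone
#'   level for activation.
#' * `"masking"`: masking scenario at fixed `I_T`, varying `I_N`;
#'   threshold noise level at which the tone fails to activate.
#' * `"continuity"`: continuity scenario at fixed `I_T`, varying `I_N`;
#'   threshold noise level at which the response persists through the gap.
#'
#' The predicate is checked at both bracket ends; if it does not differ
#' the function returns `NA` with attribute `reason = "no threshold in
#' range"` rather than a bogus midpoint (this also covers non-monotone
#' regimes, which are not bisected).
#'
#' @param config a [model_config()].
#' @param kind threshold kind (see above).
#' @param I_T tone level (fixed level for masking/continuity).
#' @param bracket numeric length-2 search interval; defaults to
#'   `[0, I_T_max]` or `[0, I_N_max]`.
#' @param tol absolute tolerance on the level.
#' @param ... passed to [simulate_model()].
#' @return Threshold level (midpoint of the final bracket), or `NA`.
#' @export
threshold_by_bisection <- function(config,
                                   kind = c("activation", "masking",
                                            "continuity"),
                                   I_T = NULL, bracket = NULL,
                                   tol = 1e-3, ...) {
  kind <- match.arg(kind)
  i <- config$inputs
  if (kind != "activation" && is.null(I_T))
    stop("'I_T' must be given for masking/continuity thresholds")
  if (is.null(bracket))
    bracket <- c(0, if (kind == "activation") i$I_T_max else i$I_N_max)
  pred <- switch(kind,
    activation = function(v) {
      s <- simulate_model(config, build_scenario("tone_only", I_T = v), ...)
      classify_response(s)$verdict == "activated"
    },
    masking = function(v) {
      s <- simulate_model(config,
                          build_scenario("masking", I_T = I_T, I_N = v), ...)
      classify_response(s)$verdict == "masked"
    },
    continuity = function(v) {
      s <- simulate_model(config,
                          build_scenario("continuity", I_T = I_T, I_N = v),
                          ...)
      classify_response(s)$verdict == "continuous"
    })
  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- pred(lo); p_hi <- pred(hi)
  if (identical(p_lo, p_hi)) {
    out <- NA_real_
    attr(out, "reason") <- "no threshold in range"
    return(out)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(pred(mid), p_hi)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
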
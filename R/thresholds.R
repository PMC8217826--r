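config_type <- function(config) {
  if (config$transient && !config$sustained) "transient_only"
  else if (config$sustained && !config$transient) "sustained_only"
  else if (config$sustained && config$transient) "combined"
  else stop("no input pathways enabled")
}

update_inputs <- function(config, ...) {
  new <- utils::modifyList(unclass(config$inputs), list(...))
  model_config(config$population,
               do.call(input_params, new),
               sustained = config$sustained, transient = config$transient,
               inhib = config$inhib, label = "custom")
}

# tone-only activation threshold implied by the configuration
activation_level <- function(config) {
  type <- config_type(config)
  p <- config$population; i <- config$inputs
  if (type == "sustained_only") {
    knee_IT(p, config$inputs)$IT_R
  } else {
    # transient activation convention: s(t_on) must exceed S(x_I)
    rest <- find_equilibria(config)
    if (type == "transient_only") {
      if (nrow(rest) < 3) stop("input-free system is not bistable")
      p$a_E * (rest$x[2] - rest$x[1]) / i$gamma_on
    } else {
      1 # combined models are calibrated so the unit tone is threshold
    }
  }
}

# single sign-change root with a subdivision guard against multi-root
# brackets
root_scan <- function(f, lo, hi, n = 400, tol = 1e-9) {
  xs <- seq(lo, hi, length.out = n)
  v <- vapply(xs, f, numeric(1))
  idx <- which(sign(v[-n]) * sign(v[-1]) < 0)
  if (length(idx) == 0) return(NA_real_)
  stats::uniroot(f, c(xs[idx[1]], xs[idx[1] + 1]), tol = tol)$root
}

# boolean boundary by bisection: first level at which pred flips from its
# value at lo
bool_boundary <- function(pred, lo, hi, tol = 1e-9) {
  p_lo <- pred(lo)
  if (identical(pred(hi), p_lo)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(pred(mid), p_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Analytic masking threshold
#'
#' Minimum noise level that prevents a tone of level `I_T` from activating
#' the population when presented simultaneously. The mechanism depends on
#' the configuration:
#'
#' * sustained-only (hysteresis) variants: noise raises the right knee of
#'   the equilibrium curve; the threshold solves
#'   `I_T = I_T(x_R(I_N), I_N)` for `I_N`.
#' * transient-only (bistable) variants: noise shrinks the onset
#'   transient; closed form `M(I_T) = (I_T - 1) / beta` for the unit-tone
#'   calibration.
#' * combined variants: noise both shrinks the onset transient and steepens
#'   the separatrix; the threshold solves
#'   `I_T - beta I_N = S(x_I; I_T, I_N)` (or the noise abolishes the
#'   active state entirely).
#'
#' @param config a [model_config()].
#' @param I_T tone level(s) above the activation threshold and at most
#'   `I_T_max`.
#' @return Threshold noise level(s); `NA` where no threshold exists at or
#'   below `I_N_max`.
#' @export
masking_threshold <- function(config, I_T) {
  vapply(I_T, function(it) masking_threshold_1(config, it), numeric(1))
}

masking_threshold_1 <- function(config, I_T) {
  type <- config_type(config)
  p <- config$population; i <- config$inputs
  thr <- activation_level(config)
  if (I_T < thr - 1e-9)
    stop("tone below the activation threshold: masking undefined")
  if (I_T > i$I_T_max) stop("'I_T' exceeds I_T_max")
  if (type == "sustained_only") {
    f <- function(IN) equilibrium_IT(knee_x(p$a_E, i$a_I, IN)$x_R,
                                     p, i, IN) - I_T
    return(root_scan(f, 0, i$I_N_max))
  }
  if (type == "transient_only") {
    if (i$beta <= 0) return(NA_real_)
    M <- (I_T - thr) / i$beta
    return(if (M <= i$I_N_max) M else NA_real_)
  }
  # combined: activation needs both a saddle and a separatrix crossing
  x_I0 <- find_equilibria(config)$x[1]
  activates <- function(IN) {
    fp <- find_equilibria(config, tone_on = TRUE, noise_on = IN > 0,
                          I_T = I_T, I_N = IN)
    if (nrow(fp) < 3) return(FALSE)
    amp <- rectify(I_T - i$beta * IN)
    S <- (p$a_E + i$a_I * IN) / i$gamma_on * (fp$x[2] - x_I0)
    amp > S
  }
  if (!activates(0)) stop("tone fails to activate even without noise")
  bool_boundary(activates, 0, i$I_N_max)
}

#' Analytic continuity threshold
#'
#' Minimum gap-noise level for which the response persists through the
#' silent gap between two tones:
#'
#' * sustained-only variants: gap noise must push the left knee of the
#'   equilibrium curve below zero tone level; the threshold solves
#'   `I_T(x_L(I_N), I_N) = 0` and is exactly constant in tone level (no
#'   tone is present during the gap).
#' * transient-only variants: the offset transient must not cross the
#'   separatrix: `C(I_T) = (I_T - a_E (x_A - x_S) / gamma_off) / beta`.
#'   Under the symmetric calibration this coincides with the masking
#'   threshold.
#' * combined variants: the gap noise must both preserve the saddle and
#'   active state of the gap-time system and weaken the offset transient
#'   below the separatrix height at the offset-time rate (the active
#'   equilibrium under the preceding noise-free tone); solved numerically
#'   in `I_N`.
#'
#' @inheritParams masking_threshold
#' @export
continuity_threshold <- function(config, I_T) {
  vapply(I_T, function(it) continuity_threshold_1(config, it), numeric(1))
}

continuity_threshold_1 <- function(config, I_T) {
  type <- config_type(config)
  p <- config$population; i <- config$inputs
  thr <- activation_level(config)
  if (I_T < thr - 1e-9)
    stop("first tone below the activation threshold: continuity undefined")
  if (I_T > i$I_T_max) stop("'I_T' exceeds I_T_max")
  if (type == "sustained_only") {
    f <- function(IN) equilibrium_IT(knee_x(p$a_E, i$a_I, IN)$x_L, p, i, IN)
    return(root_scan(f, 0, i$I_N_max))
  }
  if (type == "transient_only") {
    if (i$beta <= 0) return(NA_real_)
    rest <- find_equilibria(config)
    if (nrow(rest) < 3) stop("input-free system is not bistable")
    C <- (I_T - p$a_E * (rest$x[3] - rest$x[2]) / i$gamma_off) / i$beta
    return(if (C <= i$I_N_max) max(C, 0) else NA_real_)
  }
  # rate at the moment of tone offset: the active equilibrium under the
  # preceding (noise-free) tone
  tone_fp <- find_equilibria(config, tone_on = TRUE, I_T = I_T)
  x_off <- tone_fp$x[nrow(tone_fp)]
  persists <- function(IN) {
    fp <- find_equilibria(config, noise_on = IN > 0, I_N = IN)
    if (nrow(fp) < 3) return(FALSE)
    amp <- rectify(I_T - i$beta * IN)
    S_mag <- (p$a_E + i$a_I * IN) / i$gamma_off * (x_off - fp$x[2])
    amp < S_mag
  }
  if (persists(0)) return(0)
  bool_boundary(persists, 0, i$I_N_max)
}

#' Slope approximation for the hysteresis masking curve
#'
#' For sustained-only variants the masking curve is nearly linear because
#' the right-knee rate barely moves with noise; neglecting that motion,
#' `dI_N/dI_T` at threshold is `1 / (a_I (1 - x_R(0)) - alpha)`. The
#' denominator is also the feasibility condition: if
#' `alpha >= a_I (1 - x_R(0))`, excitatory noise overwhelms inhibition and
#' masking is impossible.
#'
#' @param a_I noise-to-inhibition weight.
#' @param alpha noise-to-sustained-excitation weight.
#' @param x_R0 firing rate at the right knee without noise.
#' @return Approximate slope (noise level per unit tone level).
#' @export
model1_masking_slope_approx <- function(a_I, alpha, x_R0) {
  den <- a_I * (1 - x_R0) - alpha
  if (den <= 0)
    stop("masking impossible: alpha >= a_I * (1 - x_R(0))")
  1 / den
}

#' Threshold curve over a tone-level grid
#'
#' @param config a [model_config()].
#' @param kind `"masking"` or `"continuity"`.
#' @param I_T tone-level grid.
#' @param method `"analytic"` (closed form / root solve) or `"bisection"`
#'   (simulation-based, via [threshold_by_bisection()]).
#' @param ... passed to [threshold_by_bisection()] when
#'   `method = "bisection"`.
#' @return `data.frame` with columns `I_T`, `I_N_threshold`, `kind`,
#'   `method`.
#' @export
threshold_curve <- function(config, kind = c("masking", "continuity"),
                            I_T = seq(1.05, 5, by = 0.05),
                            method = c("analytic", "bisection"), ...) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  fn_analytic <- if (kind == "masking") masking_threshold else
    continuity_threshold
  vals <- vapply(I_T, function(it) {
    tryCatch({
      if (method == "analytic") fn_analytic(config, it)
      else threshold_by_bisection(config, kind, I_T = it, ...)
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(I_T = I_T, I_N_threshold = vals, kind = kind, method = method)
}

#' Parameter feasibility report
#'
#' Structured pass/fail checks for a configuration, reported rather than
#' thrown:
#' (i) with sustained + inhibitory noise pathways, masking must be
#' possible: `alpha < a_I (1 - x_R(0))`;
#' (ii) continuity may only occur at noise levels at least as high as the
#' masking threshold (continuity compensates for masking);
#' (iii) both thresholds must be attainable within the noise cap at the
#' maximum tone level;
#' (iv) for configurations that are bistable at rest and deactivate only
#' through the offset transient, `gamma_off >= gamma_on` (otherwise a tone
#' could activate the population for perpetuity).
#'
#' @param config a [model_config()].
#' @return `data.frame` with columns `check`, `pass` (logical, `NA` when
#'   not applicable) and `detail`.
#' @export
feasibility_report <- function(config) {
  p <- config$population; i <- config$inputs
  rows <- list()
  add <- function(check, pass, detail)
    rows[[length(rows) + 1]] <<- data.frame(check = check, pass = pass,
                                            detail = detail)

  if (config$sustained && config$inhib && i$a_I > 0 && p$a_E > 4) {
    xr0 <- knee_x(p$a_E)$x_R
    lim <- i$a_I * (1 - xr0)
    add("alpha_constraint", i$alpha < lim,
        sprintf("alpha = %.4g, a_I*(1 - x_R(0)) = %.4g", i$alpha, lim))
  } else {
    add("alpha_constraint", NA, "not applicable")
  }

  grid <- seq(max(1.2, activation_level_safe(config) + 0.1), i$I_T_max,
              length.out = 6)
  M <- tryCatch(masking_threshold(config, grid),
                error = function(e) rep(NA_real_, length(grid)))
  C <- tryCatch(continuity_threshold(config, grid),
                error = function(e) rep(NA_real_, length(grid)))
  both <- !is.na(M) & !is.na(C)
  add("continuity_not_below_masking",
      if (any(both)) all(C[both] >= M[both] - 1e-9) else NA,
      sprintf("checked at %d tone levels", sum(both)))

  Mmax <- tryCatch(masking_threshold(config, i$I_T_max),
                   error = function(e) NA_real_)
  Cmax <- tryCatch(continuity_threshold(config, i$I_T_max),
                   error = function(e) NA_real_)
  add("thresholds_within_noise_cap",
      !is.na(Mmax) && !is.na(Cmax) && Mmax <= i$I_N_max &&
        Cmax <= i$I_N_max,
      sprintf("M(I_T_max) = %.4g, C(I_T_max) = %.4g", Mmax, Cmax))

  if (config$transient && nrow(find_equilibria(config)) >= 3) {
    add("offset_not_weaker_than_onset", i$gamma_off >= i$gamma_on,
        sprintf("gamma_on = %.4g, gamma_off = %.4g", i$gamma_on,
                i$gamma_off))
  } else {
    add("offset_not_weaker_than_onset", NA,
        "not applicable (deactivation does not rely on the offset)")
  }
  do.call(rbind, rows)
}

activation_level_safe <- function(config) {
  tryCatch(activation_level(config), error = function(e) 1)
}

#' Sweep masking/continuity thresholds over the (a_I, alpha) plane
#'
#' For hysteresis-type configurations, tabulates the masking and
#' continuity thresholds at the maximum tone level over a grid of
#' inhibition and excitation noise weights, with a feasibility flag per
#' cell.
#'
#' @param config a sustained-only [model_config()] used as template.
#' @param a_I,alpha grids of weights.
#' @return Long-format `data.frame` with columns `a_I`, `alpha`, `M_max`,
#'   `C_max`, `feasible`.
#' @export
sweep_aI_alpha <- function(config,
                           a_I = seq(0.6, 1.6, by = 0.2),
                           alpha = seq(0, 0.4, by = 0.1)) {
  if (any(a_I <= 0) || any(alpha < 0)) stop("grids must be positive")
  it_max <- config$inputs$I_T_max
  grid <- expand.grid(a_I = a_I, alpha = alpha)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- update_inputs(config, a_I = grid$a_I[r], alpha = grid$alpha[r])
    M <- tryCatch(masking_threshold(cfg, it_max),
                  error = function(e) NA_real_)
    C <- tryCatch(continuity_threshold(cfg, it_max),
                  error = function(e) NA_real_)
    rep <- feasibility_report(cfg)
    feas <- !isFALSE(rep$pass[rep$check == "alpha_constraint"]) &&
      !is.na(M) && !is.na(C) && C >= M - 1e-9
    data.frame(a_I = grid$a_I[r], alpha = grid$alpha[r],
               M_max = M, C_max = C, feasible = feas)
  })
  do.call(rbind, res)
}

#' Family of continuity threshold curves over gamma_off
#'
#' For combined-input configurations, the offset scaling interpolates
#' between hysteresis-dominated continuity (small `gamma_off`: threshold
#' nearly constant in tone level) and transient-dominated continuity
#' (large `gamma_off`: threshold grows steeply with tone level).
#'
#' @param config a combined-input [model_config()] used as template.
#' @param gamma_off grid of offset scalings.
#' @param I_T tone-level grid.
#' @return Long-format `data.frame` with columns `gamma_off`, `I_T`,
#'   `I_N_threshold`.
#' @export
sweep_gamma_off <- function(config, gamma_off = c(0.2, 0.88, 2),
                            I_T = seq(1.2, 5, length.out = 12)) {
  if (any(gamma_off <= 0)) stop("grids must be positive")
  res <- lapply(gamma_off, function(g) {
    cfg <- update_inputs(config, gamma_off = g)
    data.frame(gamma_off = g, I_T = I_T,
               I_N_threshold = vapply(I_T, function(it) {
                 tryCatch(continuity_threshold(cfg, it),
                          error = function(e) NA_real_)
               }, numeric(1)))
  })
  do.call(rbind, res)
}
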
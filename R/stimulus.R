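#' Build an idealized stimulus scenario
#'
#' Three scenarios are used throughout: `tone_only` (a single tone in
#' silence), `masking` (tone and noise presented together), and
#' `continuity` (two tones separated by a noise-filled gap). Tones and
#' noise are idealized level traces, not audio waveforms: sustained drives
#' are piecewise constant and acoustic edges trigger exponentially
#' decaying transients.
#'
#' Default timing follows the standard protocol: 1-s tones and, for the
#' continuity scenario, a 0.5-s noise-filled gap whose noise abuts both
#' tones exactly. A 0.5-s lead silence lets trajectories start at rest;
#' trailing silence pads the window (1 s for single-tone scenarios, 0.5 s
#' for continuity). Padding is cosmetic and does not affect thresholds.
#'
#' @param kind one of `"tone_only"`, `"masking"`, `"continuity"`.
#' @param I_T tone level (unitless, >= 0).
#' @param I_N noise level (>= 0; forced to 0 for `tone_only`).
#' @param tone_duration,gap_duration durations in seconds (defaults 1 and
#'   0.5).
#' @param lead,trail lead/trail silence in seconds.
#' @return An object of class `tg_stimulus` with elements `tone` and
#'   `noise` (two-column interval matrices), `I_T`, `I_N`, `duration`,
#'   `kind`.
#' @export
build_scenario <- function(kind = c("tone_only", "masking", "continuity"),
                           I_T, I_N = 0,
                           tone_duration = 1, gap_duration = 0.5,
                           lead = 0.5, trail = NULL) {
  kind <- match.arg(kind)
  if (I_T < 0 || I_N < 0) stop("levels must be non-negative")
  if (tone_duration <= 0 || gap_duration <= 0 || lead < 0)
    stop("durations must be positive")
  if (is.null(trail)) trail <- if (kind == "continuity") 0.5 else 1.0
  if (trail < 0) stop("durations must be positive")
  if (kind == "tone_only") I_N <- 0
  t0 <- lead
  t1 <- lead + tone_duration
  if (kind == "continuity") {
    tone <- rbind(c(t0, t1),
                  c(t1 + gap_duration, t1 + gap_duration + tone_duration))
    noise <- rbind(c(t1, t1 + gap_duration))
  } else {
    tone <- rbind(c(t0, t1))
    noise <- if (kind == "masking") rbind(c(t0, t1)) else
      matrix(numeric(0), ncol = 2)
  }
  duration <- max(tone) + trail
  stim <- structure(list(tone = tone, noise = noise,
                         I_T = I_T, I_N = I_N,
                         duration = duration, kind = kind),
                    class = "tg_stimulus")
  validate_stimulus(stim)
  stim
}

validate_stimulus <- function(stim) {
  chk <- function(iv) {
    if (nrow(iv) == 0) return(invisible())
    if (any(iv[, 1] >= iv[, 2])) stop("intervals must have start < end")
    if (any(iv < 0) || any(iv > stim$duration))
      stop("intervals must lie within [0, duration]")
    if (nrow(iv) > 1) {
      o <- order(iv[, 1])
      if (any(iv[o, 2][-nrow(iv)] > iv[o, 1][-1]))
        stop("intervals within a list must be disjoint")
    }
  }
  chk(stim$tone); chk(stim$noise)
  invisible(stim)
}

#' @export
print.tg_stimulus <- function(x, ...) {
  cat("<tg_stimulus>", x$kind,
      sprintf("I_T = %g, I_N = %g, duration = %g s\n", x$I_T, x$I_N,
              x$duration))
  invisible(x)
}

in_intervals <- function(t, iv, closed = FALSE) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(iv))) {
    out <- out | if (closed) t >= iv[r, 1] & t <= iv[r, 2] else
      t >= iv[r, 1] & t < iv[r, 2]
  }
  out
}

#' Tone and noise indicator functions
#'
#' Interval membership uses the half-open convention `[start, end)`, so
#' indicators change value exactly at the edge times reported by
#' [edge_events()].
#'
#' @param stim a [build_scenario()] stimulus.
#' @param t time(s) in seconds within `[0, duration]`.
#' @return List with logical vectors `tone_on` and `noise_on`.
#' @export
indicators <- function(stim, t) {
  stopifnot(inherits(stim, "tg_stimulus"))
  if (any(t < 0 | t > stim$duration))
    stop("'t' outside the stimulus window")
  list(tone_on = in_intervals(t, stim$tone),
       noise_on = in_intervals(t, stim$noise))
}

#' Ordered tone-edge events
#'
#' One onset and one offset event per tone interval, sorted in time. Each
#' event carries a `noise_coincident` flag: noise that is on at, or abuts
#' exactly at, the edge time counts as coincident (closed-interval rule),
#' so in the continuity scenario both gap-adjacent transients are
#' suppressed by the gap noise.
#'
#' @param stim a [build_scenario()] stimulus.
#' @return `data.frame` with columns `time`, `kind` (`"onset"`/`"offset"`)
#'   and `noise_coincident`.
#' @export
edge_events <- function(stim) {
  stopifnot(inherits(stim, "tg_stimulus"))
  times <- as.vector(t(stim$tone))
  kinds <- rep(c("onset", "offset"), nrow(stim$tone))
  ev <- data.frame(time = times, kind = kinds,
                   noise_coincident = in_intervals(times, stim$noise,
                                                   closed = TRUE))
  ev[order(ev$time), , drop = FALSE]
}
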
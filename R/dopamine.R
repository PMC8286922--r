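#' Tonic + phasic dopamine schedule
#'
#' The circuit-wide dopamine level phi(t) is the sum of a constant tonic
#' component and a stimulus-locked phasic component: phi equals
#' `phi_tonic` at rest, jumps to `phi_tonic + phi_phasic` while the cortex
#' is stimulated, and decays exponentially back to the tonic level once
#' the stimulus ends. The two amplitudes must sum to at most 1 so that
#' phi(t) stays in `[0, 1]`.
#'
#' @param phi_tonic Tonic level, `>= 0`.
#' @param phi_phasic Peak phasic amplitude, `>= 0`;
#'   `phi_tonic + phi_phasic <= 1`.
#' @param stimulus_windows Two-column matrix (or list of length-2
#'   vectors) of stimulus `(start_ms, end_ms)` windows; may be empty.
#' @param decay_tau_ms Exponential decay time constant of the phasic
#'   component after stimulus offset (ms).
#' @return List of class `"dopamine_schedule"`.
#' @export
dopamine_schedule <- function(phi_tonic = 0.5, phi_phasic = 0,
                              stimulus_windows = NULL,
                              decay_tau_ms = 500) {
  stopifnot(is.finite(phi_tonic), is.finite(phi_phasic), decay_tau_ms > 0)
  if (phi_tonic < 0 || phi_phasic < 0)
    stop("phi_tonic and phi_phasic must be non-negative")
  if (phi_tonic + phi_phasic > 1)
    stop("phi_tonic + phi_phasic must lie in [0, 1], got ",
         phi_tonic + phi_phasic)
  win <- if (is.null(stimulus_windows)) {
    matrix(numeric(0), ncol = 2)
  } else if (is.list(stimulus_windows)) {
    do.call(rbind, stimulus_windows)
  } else {
    matrix(stimulus_windows, ncol = 2)
  }
  if (nrow(win)) {
    if (any(win[, 2] <= win[, 1])) stop("stimulus windows need end > start")
    win <- win[order(win[, 1]), , drop = FALSE]
    if (nrow(win) > 1 && any(win[-1, 1] < win[-nrow(win), 2]))
      stop("overlapping stimulus windows are ill-defined")
  }
  structure(list(phi_tonic = phi_tonic, phi_phasic = phi_phasic,
                 windows = win, decay_tau_ms = decay_tau_ms),
            class = "dopamine_schedule")
}

#' Dopamine level at time t
#'
#' Instantaneous rise to `phi_tonic + phi_phasic` inside a stimulus
#' window; exponential decay of the phasic part after the window closes;
#' `phi_tonic` elsewhere. Vectorised over `t`.
#'
#' @param schedule A [dopamine_schedule()].
#' @param t Time(s) in ms, `>= 0`.
#' @return phi value(s) in `[0, 1]`.
#' @export
phi_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "dopamine_schedule"))
  if (any(t < 0)) stop("t must be >= 0")
  win <- schedule$windows
  phasic <- numeric(length(t))
  if (schedule$phi_phasic > 0 && nrow(win)) {
    for (j in seq_along(t)) {
      tj <- t[j]
      if (any(tj >= win[, 1] & tj < win[, 2])) {
        phasic[j] <- schedule$phi_phasic
      } else {
        ends <- win[win[, 2] <= tj, 2]
        if (length(ends))
          phasic[j] <- schedule$phi_phasic *
            exp(-(tj - max(ends)) / schedule$decay_tau_ms)
      }
    }
  }
  pmin(schedule$phi_tonic + phasic, 1)
}

#' Split the circuit dopamine level into receptor-specific levels
#'
#' The D1- and D2-receptor populations see the same dopamine signal; this
#' seam exists so receptor-specific schedules can be configured later.
#'
#' @param phi Dopamine level in `[0, 1]`.
#' @return Named numeric vector `c(phi1, phi2)`.
#' @export
split_receptor_levels <- function(phi) {
  if (any(!is.finite(phi) | phi < 0 | phi > 1))
    stop("phi must lie in [0, 1]")
  c(phi1 = phi, phi2 = phi)
}
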
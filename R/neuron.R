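#' Construct a current-injection protocol
#'
#' @param durations_ms Segment durations (ms), all positive.
#' @param currents_pA Injected current per segment (pA), same length.
#' @param dopamine_level Constant dopamine level phi in `[0, 1]` held for
#'   the whole protocol (single-cell mode treats phi as a constant).
#' @return List of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(durations_ms, currents_pA, dopamine_level = 0.5) {
  stopifnot(length(durations_ms) == length(currents_pA),
            all(is.finite(durations_ms)), all(is.finite(currents_pA)))
  if (any(durations_ms <= 0)) stop("segment durations must be > 0")
  if (!is.finite(dopamine_level) || dopamine_level < 0 || dopamine_level > 1)
    stop("dopamine_level must lie in [0, 1]")
  structure(list(durations_ms = as.numeric(durations_ms),
                 currents_pA = as.numeric(currents_pA),
                 dopamine_level = dopamine_level),
            class = "stimulus_protocol")
}

# stability cap for the explicit Euler scheme (ms)
DT_MAX <- 1

check_dt <- function(dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")
  if (dt > DT_MAX) stop("dt = ", dt, " ms exceeds the stability cap of ",
                        DT_MAX, " ms for the explicit integrator")
  dt
}

#' One integration step of a single neuron
#'
#' Advances the membrane potential, the recovery variable (and, for TC
#' relay cells, the second slow variable) by one explicit Euler step and
#' applies the auxiliary reset when the voltage reaches the spike-detection
#' cutoff. Pure R reference implementation of the step used by the
#' compiled integrators.
#'
#' @param state Named list with `v`, `u`, `w` (mV, pA, pA) and optionally
#'   `last_spike_time`.
#' @param params A [neuron_params()] object.
#' @param injected_current Injected current (pA).
#' @param phi Dopamine level in `[0, 1]`.
#' @param dt Step (ms), at most 1 ms.
#' @param t Current time (ms), used to stamp `last_spike_time`.
#' @return List with the updated `state` and logical `spike`.
#' @export
step_neuron <- function(state, params, injected_current, phi = 0.5,
                        dt = 0.1, t = 0) {
  check_dt(dt)
  if (!is.finite(phi) || phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  for (f in c("v", "u")) if (!is.finite(state[[f]]))
    stop("non-finite state field: ", f)
  p <- params
  has_w <- p$slow2_rate > 0
  w <- if (has_w) state$w else 0
  d_eff <- p$after_spike_pA * (1 - p$da_d_scale * phi)
  I <- injected_current + p$bias_pA - p$da_hyper_pA * phi
  v0 <- state$v
  dv <- (p$quad_gain * (v0 - p$resting_mV) * (v0 - p$threshold_mV) -
           state$u - (if (has_w) w else 0) + I) / p$capacitance_pF
  v <- max(v0 + dt * dv, -100) # hyperpolarisation floor, as compiled core
  u <- state$u + dt * p$recovery_rate *
    (p$recovery_sens * (v0 - p$resting_mV) - state$u)
  if (has_w)
    w <- w + dt * p$slow2_rate * (p$slow2_sens * (v0 - p$resting_mV) - w)
  spike <- v >= p$peak_mV
  if (spike) {
    v <- p$reset_mV
    u <- u + d_eff
    if (has_w) w <- w + p$slow2_jump_pA
  }
  list(state = list(v = v, u = u, w = if (has_w) w else NULL,
                    last_spike_time = if (spike) t else state$last_spike_time),
       spike = spike)
}

resting_state <- function(params) {
  list(v = params$resting_mV, u = 0,
       w = if (params$slow2_rate > 0) 0 else NULL, last_spike_time = NULL)
}

#' Simulate a single neuron under a current-injection protocol
#'
#' Deterministic forward-Euler integration of one cell; returns the full
#' voltage trace and the ordered spike times (start-of-step convention).
#'
#' @inheritParams step_neuron
#' @param protocol A [stimulus_protocol()].
#' @param dt Integration step (ms); default 0.1 ms for single-cell work.
#' @return List of class `"neuron_trace"`: `time_ms`, `v_mV`, `u`, `w`,
#'   `spike_times`, `dt`.
#' @export
simulate_neuron <- function(params, protocol, dt = 0.1) {
  check_dt(dt)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  validate_neuron_params(params)
  nseg <- pmax(1L, as.integer(round(protocol$durations_ms / dt)))
  current <- rep(protocol$currents_pA, times = nseg)
  s0 <- resting_state(params)
  out <- .simulate_neuron_cpp(param_vector(params), current,
                              protocol$dopamine_level, dt,
                              s0$v, s0$u, if (is.null(s0$w)) 0 else s0$w)
  structure(list(time_ms = seq(0, by = dt, length.out = length(current) + 1),
                 v_mV = out$v, u = out$u,
                 w = if (params$slow2_rate > 0) out$w else NULL,
                 spike_times = out$spike_times, dt = dt),
            class = "neuron_trace")
}

# steady-state frequency: inverse mean ISI over the final half of the trial
steady_rate <- function(spike_times, trial_ms) {
  late <- spike_times[spike_times >= trial_ms / 2]
  if (length(late) < 2) return(0)
  1000 / mean(diff(late))
}

#' f-I curve
#'
#' Steady-state firing frequency against injected DC current. Frequency is
#' the inverse mean inter-spike interval over the final half of the trial,
#' discarding the adaptation/latency transient; below rheobase the
#' frequency is 0 Hz.
#'
#' @inheritParams simulate_neuron
#' @param phi Dopamine level held constant.
#' @param current_grid Ascending currents (pA).
#' @param trial_duration Trial length per current (ms).
#' @return data.frame with `current_pA` and `rate_hz`.
#' @export
f_i_curve <- function(params, phi = 0.5, current_grid,
                      trial_duration = 2000, dt = 0.1) {
  if (!length(current_grid)) stop("current_grid is empty")
  if (is.unsorted(current_grid)) stop("current_grid must be ascending")
  rates <- vapply(current_grid, function(I) {
    tr <- simulate_neuron(params,
                          stimulus_protocol(trial_duration, I, phi), dt)
    steady_rate(tr$spike_times, trial_duration)
  }, numeric(1))
  data.frame(current_pA = current_grid, rate_hz = rates)
}

#' Rheobase current by bisection
#'
#' Minimal injected DC current that elicits sustained spiking (at least
#' one spike in the second half of the trial), bracketed to `tol` by
#' bisection between a subthreshold and a suprathreshold current.
#'
#' @inheritParams f_i_curve
#' @param tol Bracket width (pA).
#' @param lower,upper Initial search bounds (pA); the lower bound is
#'   pushed down automatically for spontaneously active cells.
#' @return Rheobase estimate (pA, midpoint of the final bracket).
#' @export
find_rheobase <- function(params, phi = 0.5, dt = 0.1, tol = 1,
                          lower = -400, upper = 800,
                          trial_duration = 2000) {
  if (tol <= 0) stop("tol must be > 0")
  fires <- function(I) {
    tr <- simulate_neuron(params,
                          stimulus_protocol(trial_duration, I, phi), dt)
    any(tr$spike_times >= trial_duration / 2)
  }
  if (!fires(upper))
    stop("no sustained spiking up to the search bound of ", upper, " pA")
  if (fires(lower))
    stop("cell still fires at the lower search bound of ", lower, " pA")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}

# planar subsystem right-hand sides (second slow variable frozen at its
# fixed point w* = slow2_sens * (v - resting)); used for nullclines,
# equilibria and the bifurcation scan
planar_equilibria <- function(params, injected_current, phi = 0.5) {
  p <- params
  I <- injected_current + p$bias_pA - p$da_hyper_pA * phi
  # equilibria solve k(v-vr)(v-vt) - (b + b2)(v-vr) + I = 0, a quadratic
  b_tot <- p$recovery_sens + p$slow2_sens
  k <- p$quad_gain; vr <- p$resting_mV; vt <- p$threshold_mV
  # k v^2 - k(vr+vt) v + k vr vt - b_tot v + b_tot vr + I = 0
  A <- k; B <- -k * (vr + vt) - b_tot; C <- k * vr * vt + b_tot * vr + I
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

classify_equilibrium <- function(params, v_eq) {
  p <- params
  J11 <- p$quad_gain * (2 * v_eq - p$resting_mV - p$threshold_mV) /
    p$capacitance_pF
  J12 <- -1 / p$capacitance_pF
  J21 <- p$recovery_rate * p$recovery_sens
  J22 <- -p$recovery_rate
  ev <- eigen(matrix(c(J11, J21, J12, J22), 2, 2), only.values = TRUE)$values
  re <- Re(ev)
  if (all(re < 0)) "stable"
  else if (prod(re) < 0 && all(Im(ev) == 0)) "saddle"
  else "unstable"
}

#' Phase-plane analysis of the planar subsystem
#'
#' Nullclines, equilibria and their stability for the (v, u) subsystem at
#' a fixed injected current. For TC relay cells the second slow variable
#' is frozen at its voltage-dependent fixed point. Equilibria of the
#' quadratic voltage nullcline are found in closed form; stability comes
#' from the Jacobian eigenvalues.
#'
#' @inheritParams f_i_curve
#' @param injected_current DC current (pA).
#' @param v_range Voltage interval (mV) on which to sample the nullclines.
#' @return List with `nullclines` (data.frame `v`, `u_vnull`, `u_unull`)
#'   and `equilibria` (data.frame `v`, `u`, `stability`).
#' @export
phase_portrait <- function(params, injected_current = 0, phi = 0.5,
                           v_range = c(-100, -20)) {
  p <- params
  v <- seq(v_range[1], v_range[2], length.out = 400)
  I <- injected_current + p$bias_pA - p$da_hyper_pA * phi
  b_tot <- p$recovery_sens + p$slow2_sens
  u_vnull <- p$quad_gain * (v - p$resting_mV) * (v - p$threshold_mV) + I -
    p$slow2_sens * (v - p$resting_mV)
  u_unull <- p$recovery_sens * (v - p$resting_mV)
  v_eq <- planar_equilibria(params, injected_current, phi)
  v_eq <- v_eq[v_eq >= v_range[1] & v_eq <= v_range[2]]
  eq <- data.frame(v = v_eq,
                   u = p$recovery_sens * (v_eq - p$resting_mV),
                   stability = vapply(v_eq, function(x)
                     classify_equilibrium(params, x), character(1)))
  list(nullclines = data.frame(v = v, u_vnull = u_vnull, u_unull = u_unull),
       equilibria = eq)
}

#' Saddle-node bifurcation scan over injected current
#'
#' Reports the number of subthreshold equilibria along a current grid and
#' the current at which they disappear (the saddle-node point, which for
#' these cells coincides with the rheobase current).
#'
#' @inheritParams phase_portrait
#' @param current_grid Ascending currents (pA).
#' @return List with `counts` (data.frame `current_pA`, `n_equilibria`)
#'   and `bifurcation_current` (`NA` if no change on the grid).
#' @export
bifurcation_scan <- function(params, current_grid, phi = 0.5) {
  n_eq <- vapply(current_grid, function(I)
    length(planar_equilibria(params, I, phi)), integer(1))
  chg <- which(diff(n_eq) != 0)
  bif <- if (length(chg)) mean(current_grid[chg[1] + 0:1]) else NA_real_
  list(counts = data.frame(current_pA = current_grid, n_equilibria = n_eq),
       bifurcation_current = bif)
}
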
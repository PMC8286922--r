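#' Network simulation configuration
#'
#' @param duration_ms Total simulated time. The reference protocol runs
#'   10 minutes and analyses the final 7 s once activity has stabilised;
#'   shorter warm-ups give scaled-down runs with the same analysed window.
#' @param dt Integration step for network mode (ms); default 0.5 ms.
#' @param record_window `(start, end)` ms kept for analysis; defaults to
#'   the final 7 s.
#' @param stdp_interval_ms Batch interval at which STDP is applied to the
#'   plastic projections using the spikes since the previous batch.
#' @param seed Integer seed governing every random element of the run
#'   (Poisson background, rewiring draws).
#' @param stimulus List with `amplitude_pA` and `window_ms = c(start, end)`
#'   describing the external cortical step input (delivered to both
#'   cortical populations), or `NULL` for no stimulus.
#' @param stdp_profiles Named profiles, see [default_stdp_profiles()].
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(duration_ms = 600000, dt = 0.5,
                              record_window = c(duration_ms - 7000,
                                                duration_ms),
                              stdp_interval_ms = 1000,
                              seed = 1L, stimulus = NULL,
                              stdp_profiles = default_stdp_profiles()) {
  check_dt(dt)
  stopifnot(duration_ms > 0, length(record_window) == 2)
  if (record_window[1] < 0 || record_window[2] > duration_ms ||
      record_window[1] >= record_window[2])
    stop("record_window must be an increasing interval inside [0, duration]")
  if (!is.null(stimulus)) {
    stopifnot(is.list(stimulus), length(stimulus$window_ms) == 2,
              is.finite(stimulus$amplitude_pA))
  }
  structure(list(duration_ms = duration_ms, dt = dt,
                 record_window = record_window,
                 stdp_interval_ms = stdp_interval_ms,
                 seed = as.integer(seed), stimulus = stimulus,
                 stdp_profiles = stdp_profiles),
            class = "simulation_config")
}

#' Homogeneous Poisson background events
#'
#' Independent event trains per neuron, used as the external drive that
#' stands in for afferents outside the modelled circuit.
#'
#' @param rate Events per second per neuron (Hz), `>= 0`.
#' @param n_neurons Number of trains.
#' @param duration_ms Window length.
#' @param seed Integer seed.
#' @return List of ascending event-time vectors (ms), one per neuron.
#' @export
poisson_background <- function(rate, n_neurons, duration_ms, seed = 1L) {
  stopifnot(rate >= 0, n_neurons >= 0, duration_ms >= 0)
  withr_seed(seed, {
    counts <- rpois(n_neurons, rate * duration_ms / 1000)
    lapply(counts, function(k) sort(runif(k, 0, duration_ms)))
  })
}

#' Run a network simulation
#'
#' Forward-integrates the whole network: per step the dopamine level
#' phi(t), delayed synaptic pulses, Poisson background and (inside its
#' window) the external cortical step current are combined and every
#' neuron advanced by one Euler step; spikes are logged and delivered to
#' their targets after the edge conduction delay. Every
#' `stdp_interval_ms` the plastic projections receive a batched STDP
#' update (with structural rewiring). Deterministic given the seed.
#'
#' @param network A [build_network()] object.
#' @param schedule A [dopamine_schedule()].
#' @param config A [simulation_config()].
#' @return Object of class `"spike_record"`: `events` data.frame
#'   (`population`, `neuron`, `time_ms`, time-sorted), population sizes,
#'   duration, and the final network (weights after plasticity).
#' @export
run_simulation <- function(network, schedule, config) {
  stopifnot(inherits(network, "bg_network"),
            inherits(schedule, "dopamine_schedule"),
            inherits(config, "simulation_config"))
  dt <- config$dt
  n <- network$n_total
  pops <- pop_of(network)
  ptab <- network$param_table
  # one parameter column per neuron (the compiled core reads columns)
  par_mat <- vapply(pops, function(pn)
    param_vector(neuron_params(pn, ptab)), numeric(15))
  has_w <- par_mat[11, ] > 0

  bg_rate <- setNames(network$populations$bg_rate_hz,
                      network$populations$name)[pops]
  bg_w <- setNames(network$populations$bg_weight_pA,
                   network$populations$name)[pops]
  stim_target <- pops %in% c("CTX_RS", "CTX_FS")

  n_steps_total <- as.integer(round(config$duration_ms / dt))
  chunk_steps <- max(1L, as.integer(round(config$stdp_interval_ms / dt)))
  plastic <- network$projections[network$projections$plastic, , drop = FALSE]

  sp_time <- list(); sp_neuron <- list(); ci <- 0L
  withr_seed(config$seed, {
    # staggered initial potentials so pacemaker populations do not start
    # in artificial lockstep
    state <- cbind(v = par_mat[3, ] - runif(n, 0, 10), u = 0, w = 0)
    csr <- build_csr(network, dt)
    D <- csr$D
    buf_plain <- matrix(0, D, n); buf_d1 <- matrix(0, D, n)
    buf_d2 <- matrix(0, D, n)
    ring_pos <- 0L
    done <- 0L
    while (done < n_steps_total) {
      ns <- min(chunk_steps, n_steps_total - done)
      tt <- (done + seq_len(ns) - 1) * dt
      phi <- phi_at(schedule, tt)
      gains <- da_input_gains(phi)
      g1 <- gains$g1; g2 <- gains$g2
      stim <- numeric(ns)
      if (!is.null(config$stimulus)) {
        w <- config$stimulus$window_ms
        stim[tt >= w[1] & tt < w[2]] <- config$stimulus$amplitude_pA
      }
      poi <- draw_poisson_events(bg_rate, bg_w, ns, dt)
      res <- .step_network_chunk(state, par_mat, has_w,
                                 csr$src_ptr, csr$tgt, csr$w, csr$delay,
                                 csr$class, buf_plain, buf_d1, buf_d2,
                                 ring_pos, phi, g1, g2, stim, stim_target,
                                 poi$step, poi$neuron, poi$weight,
                                 dt, ns, done * dt)
      ring_pos <- res$ring_pos
      ci <- ci + 1L
      sp_time[[ci]] <- res$spike_time
      sp_neuron[[ci]] <- res$spike_neuron + 1L
      if (nrow(plastic)) {
        network <- apply_stdp_batch(network, config, res, (done + ns) * dt)
        csr <- build_csr(network, dt)
      }
      done <- done + ns
    }
  })
  ev <- data.frame(neuron_global = unlist(sp_neuron),
                   time_ms = unlist(sp_time))
  ev <- ev[order(ev$time_ms, ev$neuron_global), ]
  events <- data.frame(population = pops[ev$neuron_global],
                       neuron = ev$neuron_global -
                         network$offsets[pops[ev$neuron_global]],
                       time_ms = ev$time_ms)
  rownames(events) <- NULL
  structure(list(events = events, sizes = network$sizes,
                 duration_ms = config$duration_ms,
                 record_window = config$record_window,
                 dt = dt, seed = config$seed, network = network),
            class = "spike_record")
}

# CSR edge arrays ordered by source, delays rounded to whole steps (>= 1)
build_csr <- function(network, dt) {
  e <- network$edges
  ord <- order(e$src)
  e <- e[ord, ]
  delay <- pmax(1L, as.integer(round(e$delay_ms / dt)))
  cls <- integer(nrow(e))
  cls[e$proj == "CTX_RS->D1_MSN"] <- 1L
  cls[e$proj == "CTX_RS->D2_MSN"] <- 2L
  src_ptr <- c(0L, cumsum(tabulate(e$src, nbins = network$n_total)))
  list(src_ptr = as.integer(src_ptr), tgt = as.integer(e$tgt - 1L),
       w = e$weight, delay = delay, class = cls, D = max(delay) + 1L)
}

draw_poisson_events <- function(bg_rate, bg_w, ns, dt) {
  n <- length(bg_rate)
  lam <- bg_rate * ns * dt / 1000
  counts <- rpois(n, lam)
  tot <- sum(counts)
  if (!tot)
    return(list(step = integer(0), neuron = integer(0), weight = numeric(0)))
  neuron <- rep.int(seq_len(n), counts)
  step <- sample.int(ns, tot, replace = TRUE) - 1L
  ord <- order(step)
  list(step = step[ord], neuron = neuron[ord] - 1L,
       weight = bg_w[neuron[ord]])
}

apply_stdp_batch <- function(network, config, res, time_ms) {
  pr <- network$projections
  pops <- pop_of(network)
  spikes_by_neuron <- split(res$spike_time,
                            factor(res$spike_neuron + 1L,
                                   levels = seq_len(network$n_total)))
  for (i in which(pr$plastic)) {
    prof <- config$stdp_profiles[[pr$stdp_profile[i]]]
    if (is.null(prof)) stop("missing STDP profile: ", pr$stdp_profile[i])
    pre <- spikes_by_neuron[pop_ids(network, pr$source[i])]
    post <- spikes_by_neuron[pop_ids(network, pr$target[i])]
    network <- stdp_update(network, prof, pre, post,
                           paste(pr$source[i], pr$target[i], sep = "->"),
                           time_ms = time_ms)
  }
  network
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record> ", nrow(x$events), " spikes over ",
      x$duration_ms / 1000, " s (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a spike record as delimited text
#'
#' @param record A `spike_record`.
#' @param path File path.
#' @return `write_spike_record` the path, invisibly; `read_spike_record`
#'   a data.frame (`population`, `neuron`, `time_ms`).
#' @export
write_spike_record <- function(record, path) {
  write.table(record$events, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) read.delim(path,
                                               stringsAsFactors = FALSE)
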
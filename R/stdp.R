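#' STDP profile
#'
#' Pair-based additive spike-timing-dependent plasticity: a pre-before-post
#' pair separated by `dt > 0` potentiates by `a_plus * exp(-dt/tau_plus)`,
#' a post-before-pre pair depresses by `a_minus * exp(dt/tau_minus)`;
#' coincident spikes (`dt == 0`) contribute nothing. All pre/post pairs in
#' the update window enter the sum, and the result is clipped to the
#' weight bounds (the anti-instability clamp). Intra-cortical and
#' cortico-striatal synapses use distinct profiles.
#'
#' @param a_plus,a_minus Potentiation/depression amplitudes (pA per pair).
#' @param tau_plus,tau_minus Time constants (ms), positive.
#' @param allow_rewiring If `TRUE`, an edge clipped to zero weight becomes
#'   prunable and may be replaced by a fresh edge elsewhere in the same
#'   projection (structural/wiring plasticity).
#' @param rewire_prob Per-update probability that a pruned edge is
#'   replaced by a new edge between a uniformly chosen unconnected pair.
#' @param rewire_init_frac New edges start at this fraction of the
#'   projection's weight bound (the minimum positive weight).
#' @return List of class `"stdp_profile"`.
#' @export
stdp_profile <- function(a_plus = 0.5, a_minus = 0.55,
                         tau_plus = 20, tau_minus = 20,
                         allow_rewiring = TRUE,
                         rewire_prob = 0.05, rewire_init_frac = 0.02) {
  stopifnot(tau_plus > 0, tau_minus > 0, a_plus >= 0, a_minus >= 0,
            rewire_prob >= 0, rewire_prob <= 1, rewire_init_frac > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, allow_rewiring = allow_rewiring,
                 rewire_prob = rewire_prob,
                 rewire_init_frac = rewire_init_frac),
            class = "stdp_profile")
}

#' Default STDP profiles
#'
#' The intra-cortical and cortico-striatal plasticity rules differ: the
#' cortico-striatal profile has a faster potentiation window and a slower,
#' weaker depression window than the intra-cortical one.
#'
#' @return Named list of two [stdp_profile()] objects, `cortical` and
#'   `corticostriatal`.
#' @export
default_stdp_profiles <- function() {
  list(cortical = stdp_profile(a_plus = 0.5, a_minus = 0.55,
                               tau_plus = 20, tau_minus = 20),
       corticostriatal = stdp_profile(a_plus = 0.8, a_minus = 0.5,
                                      tau_plus = 15, tau_minus = 30))
}

#' Apply one STDP update to a projection
#'
#' Computes the all-pairs additive weight change for every edge of a
#' plastic projection from the pre- and postsynaptic spike trains since
#' the previous update, clips to the projection's bounds, and (when the
#' profile allows rewiring) prunes zero-weight edges and instantiates
#' replacement edges between unconnected pairs.
#'
#' @param network A `bg_network`.
#' @param profile An [stdp_profile()].
#' @param pre_spikes,post_spikes Lists of spike-time vectors indexed by
#'   local neuron id within the source/target population.
#' @param projection Projection name, e.g. `"CTX_RS->D1_MSN"`.
#' @param time_ms Simulation time stamped into the rewiring log.
#' @return The network with updated weights (and possibly rewired edges).
#' @export
stdp_update <- function(network, profile, pre_spikes, post_spikes,
                        projection, time_ms = NA_real_) {
  pr <- network$projections
  key <- paste(pr$source, pr$target, sep = "->")
  row <- which(key == projection)
  if (!length(row)) stop("unknown projection: ", projection)
  if (!pr$plastic[row]) stop("projection ", projection, " is not plastic")
  src_pop <- pr$source[row]; tgt_pop <- pr$target[row]
  sel <- which(network$edges$proj == projection)
  if (!length(sel)) return(network)
  e <- network$edges[sel, ]
  pre_local <- e$src - network$offsets[[src_pop]]
  post_local <- e$tgt - network$offsets[[tgt_pop]]
  pre_spikes <- pad_spike_list(pre_spikes, network$sizes[[src_pop]])
  post_spikes <- pad_spike_list(post_spikes, network$sizes[[tgt_pop]])
  dw <- .stdp_delta_cpp(as.integer(pre_local), as.integer(post_local),
                        pre_spikes, post_spikes,
                        profile$a_plus, profile$a_minus,
                        profile$tau_plus, profile$tau_minus)
  w_bound <- pr$w_max_abs[row]
  if (pr$sign[row] > 0) {
    w_new <- pmin(pmax(e$weight + dw, 0), w_bound)
  } else {
    # inhibitory plastic edges update in magnitude, preserving sign
    w_new <- -pmin(pmax(-e$weight - dw, 0), w_bound)
  }
  network$edges$weight[sel] <- w_new
  if (profile$allow_rewiring)
    network <- rewire_pruned(network, profile, row, projection, time_ms)
  network
}

pad_spike_list <- function(lst, n) {
  if (length(lst) < n) lst <- c(lst, rep(list(numeric(0)), n - length(lst)))
  lapply(lst, as.numeric)
}

# structural plasticity: each zero-weight edge of the projection is, with
# the profile's probability, moved to a uniformly chosen unconnected pair
# and restarted at the minimum positive weight; both events are logged
rewire_pruned <- function(network, profile, prow, projection, time_ms) {
  sel <- which(network$edges$proj == projection)
  dead <- sel[network$edges$weight[sel] == 0]
  if (!length(dead)) return(network)
  pr <- network$projections[prow, ]
  src_ids <- pop_ids(network, pr$source)
  tgt_ids <- pop_ids(network, pr$target)
  w0 <- profile$rewire_init_frac * pr$w_max_abs * pr$sign
  have <- paste(network$edges$src[sel], network$edges$tgt[sel])
  for (ed in dead) {
    if (runif(1) >= profile$rewire_prob) next
    for (try in 1:50) {
      s <- sample(src_ids, 1); tg <- sample(tgt_ids, 1)
      if (s == tg || paste(s, tg) %in% have) next
      network$rewire_log <- rbind(network$rewire_log,
        data.frame(time_ms = time_ms, proj = projection,
                   action = c("prune", "form"),
                   src = c(network$edges$src[ed], s),
                   tgt = c(network$edges$tgt[ed], tg)))
      have[match(paste(network$edges$src[ed], network$edges$tgt[ed]),
                 have)] <- paste(s, tg)
      network$edges$src[ed] <- s
      network$edges$tgt[ed] <- tg
      network$edges$weight[ed] <- w0
      break
    }
  }
  network
}
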
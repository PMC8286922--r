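#' Default population table
#'
#' Population sizes follow the anatomy used throughout: an
#' excitatory-to-inhibitory cortical ratio of 4:1 (800 regular-spiking to
#' 200 fast-spiking cells), 200 D1- and 200 D2-type medium spiny neurons,
#' and 100 cells in each of GPe, GPi, STN and the thalamic relay
#' population. Each population also carries its Poisson background drive
#' (rate and pulse weight) standing in for afferents outside the model.
#'
#' @param path Optional alternative tab-delimited table.
#' @return data.frame with `name`, `size`, `bg_rate_hz`, `bg_weight_pA`.
#' @export
population_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "populations.tsv", package = "bgloop")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "size", "bg_rate_hz", "bg_weight_pA") %in%
                  names(tab)))
  if (!all(tab$name %in% CELL_TYPES))
    stop("unknown population name(s): ",
         paste(setdiff(tab$name, CELL_TYPES), collapse = ", "))
  tab
}

#' Default projection table
#'
#' The wiring diagram of the circuit: directed projections with sign
#' (+1 excitatory, -1 inhibitory), independent connection probability,
#' initial weight distribution, magnitude bound, conduction delay,
#' plasticity flag and dopamine-modulation class (`d1`/`d2` for the
#' cortico-striatal projections whose efficacy scales with phi). The
#' direct (D1 -> GPi -> thalamus), indirect (D2 -> GPe -> STN -> GPi) and
#' hyperdirect (cortex -> STN -> GPi) routes are all present.
#'
#' @param path Optional alternative tab-delimited table.
#' @return data.frame, one row per projection.
#' @export
projection_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "projections.tsv", package = "bgloop")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$plastic <- as.logical(tab$plastic)
  if (any(tab$p < 0 | tab$p > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (any(tab$delay_ms <= 0)) stop("conduction delays must be > 0")
  if (any(!tab$sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  # Dale-like consistency: all outgoing projections of a population share
  # one sign
  sgn <- tapply(tab$sign, tab$source, function(s) length(unique(s)))
  if (any(sgn > 1))
    stop("a population cannot host both signs on its efferents")
  tab
}

#' Build a random-graph network
#'
#' Every (pre, post) pair of each projection is connected independently
#' with the projection's probability; self-connections within a
#' population are excluded. Weights are drawn from a normal distribution
#' (mean, sd from the table), clipped to the magnitude bound, and signed
#' by the projection. Construction is deterministic given `seed`.
#'
#' @param populations Population table ([population_table()]).
#' @param projections Projection table ([projection_table()]).
#' @param seed Integer seed for the wiring RNG.
#' @param param_table Cell-parameter table ([neuron_param_table()]).
#' @return Object of class `"bg_network"`: populations, per-neuron
#'   global index ranges, and an edge data.frame
#'   (`src`, `tgt` global ids, `weight`, `delay_ms`, `proj`).
#' @export
build_network <- function(populations = population_table(),
                          projections = projection_table(),
                          seed = 1L,
                          param_table = neuron_param_table()) {
  stopifnot(all(projections$source %in% populations$name),
            all(projections$target %in% populations$name))
  offsets <- setNames(cumsum(c(0, head(populations$size, -1))),
                      populations$name)
  sizes <- setNames(populations$size, populations$name)
  n_total <- sum(populations$size)
  edges <- withr_seed(seed, {
    lst <- lapply(seq_len(nrow(projections)), function(i) {
      pr <- projections[i, ]
      ns <- sizes[[pr$source]]; nt <- sizes[[pr$target]]
      if (pr$p == 0) return(NULL)
      pairs <- which(matrix(runif(ns * nt) < pr$p, ns, nt), arr.ind = TRUE)
      if (pr$source == pr$target)
        pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
      if (!nrow(pairs)) return(NULL)
      w <- abs(rnorm(nrow(pairs), pr$weight_mean, pr$weight_sd))
      w <- pmin(pmax(w, 0), pr$w_max_abs) * pr$sign
      data.frame(src = offsets[[pr$source]] + pairs[, 1],
                 tgt = offsets[[pr$target]] + pairs[, 2],
                 weight = w, delay_ms = pr$delay_ms,
                 proj = paste(pr$source, pr$target, sep = "->"))
    })
    do.call(rbind, lst)
  })
  rownames(edges) <- NULL
  structure(list(populations = populations, projections = projections,
                 offsets = offsets, sizes = sizes, n_total = n_total,
                 edges = edges, seed = seed,
                 param_table = param_table,
                 rewire_log = data.frame(time_ms = numeric(0),
                                         proj = character(0),
                                         action = character(0),
                                         src = integer(0), tgt = integer(0))),
            class = "bg_network")
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' @export
print.bg_network <- function(x, ...) {
  cat("<bg_network> ", x$n_total, " neurons in ", nrow(x$populations),
      " populations, ", nrow(x$edges), " synapses (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

# global id range of a population
pop_ids <- function(network, population) {
  off <- network$offsets[[population]]
  if (is.null(off)) stop("unknown population: ", population)
  seq.int(off + 1L, off + network$sizes[[population]])
}

# population name per global id
pop_of <- function(network) {
  rep(network$populations$name, network$populations$size)
}

#' Delayed synaptic input at a time point
#'
#' Reference implementation of the synaptic current each neuron receives
#' at time `t`: the sum of delta-pulse weights over all edges whose
#' presynaptic spike time plus conduction delay lands in the integration
#' step containing `t`. Cortico-striatal contributions are scaled by the
#' dopamine input gains (up onto D1, down onto D2 as phi rises). The
#' compiled network loop implements the same rule through ring buffers.
#'
#' @param network A [build_network()] object.
#' @param spikes data.frame with `neuron` (global id) and `time_ms`.
#' @param phi Dopamine level at `t`.
#' @param t Query time (ms).
#' @param dt Step width that defines pulse coincidence (ms).
#' @return Numeric vector of per-neuron input currents (pA).
#' @export
synaptic_input <- function(network, spikes, phi, t, dt = 0.5) {
  if (nrow(spikes) && t < min(spikes$time_ms))
    stop("query time precedes the spike history")
  gains <- da_input_gains(phi)
  out <- numeric(network$n_total)
  if (!nrow(spikes)) return(out)
  e <- network$edges
  da_mod <- proj_da_mod(network)
  for (i in seq_len(nrow(spikes))) {
    sp <- spikes$neuron[i]; ts <- spikes$time_ms[i]
    sel <- which(e$src == sp)
    if (!length(sel)) next
    arr <- ts + e$delay_ms[sel]
    hit <- sel[abs(arr - t) < dt / 2]
    for (j in hit) {
      g <- switch(da_mod[[e$proj[j]]], d1 = gains$g1,
                  d2 = gains$g2, 1)
      out[e$tgt[j]] <- out[e$tgt[j]] + g * e$weight[j]
    }
  }
  out
}

# dopamine gain on cortico-striatal efficacy: up onto D1, down onto D2;
# vectorised over phi
da_input_gains <- function(phi, slope = 0.6) {
  list(g1 = 1 + slope * phi, g2 = 1 - slope * phi)
}

proj_da_mod <- function(network) {
  pr <- network$projections
  setNames(as.list(pr$da_mod), paste(pr$source, pr$target, sep = "->"))
}

#' Export / import the network edge list
#'
#' Plain-text round trip of the wiring: one line per synapse with
#' source/target population and local index, weight and delay.
#'
#' @param network A `bg_network`.
#' @param path Output (input) file.
#' @return `write_edge_list` returns the path invisibly;
#'   `read_edge_list` a data.frame.
#' @export
write_edge_list <- function(network, path) {
  pops <- pop_of(network)
  off <- network$offsets[pops]
  e <- network$edges
  out <- data.frame(source_pop = pops[e$src],
                    source_id = e$src - network$offsets[pops[e$src]],
                    target_pop = pops[e$tgt],
                    target_id = e$tgt - network$offsets[pops[e$tgt]],
                    weight = e$weight, delay_ms = e$delay_ms)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) read.delim(path, stringsAsFactors = FALSE)
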
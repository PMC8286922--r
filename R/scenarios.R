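#' The five experimental scenarios
#'
#' Ready-to-run protocol presets:
#' \describe{
#'   \item{1}{Default (resting) mode: `phi = phi_tonic = 0.5`, no
#'     stimulus.}
#'   \item{2}{Direct pathway enabled: `phi_tonic = 0.5`,
#'     `phi_phasic = 0.5`, 2 s cortical stimulus; the gate opens and the
#'     thalamus relays the cortical input.}
#'   \item{3}{Indirect pathway dominant: `phi_tonic = 0.5`,
#'     `phi_phasic = 0`, stimulus on; the gate stays shut.}
#'   \item{4}{Parkinsonian selection: `phi_tonic = 0.5`,
#'     `phi_phasic = 0.4`, stimulus on; attenuated phasic dopamine gives
#'     an inadequate thalamic response.}
#'   \item{5}{Parkinsonian resting state: `phi = phi_tonic = 0`, no
#'     stimulus, and the GPi-to-thalamus weights scaled down (default
#'     factor 0.1) with no plasticity on that projection.}
#' }
#' The stimulus window sits at 2-4 s of the analysed segment. Twenty
#' repetitions with independently wired networks is the reference
#' protocol; `n_reps` scales this down.
#'
#' @param id Scenario id, 1 to 5.
#' @param duration_ms Total simulated time per repetition (warm-up plus
#'   the analysed final 7 s).
#' @param n_reps Number of repetitions (fresh random network each).
#' @param gpi_thalamus_scale Multiplier on GPi->TC weights (scenario 5
#'   only; must be < 1 there, 1 elsewhere).
#' @param stim_amplitude_pA Cortical step amplitude.
#' @param dt Integration step (ms).
#' @return List of class `"scenario_config"`.
#' @export
scenario_config <- function(id, duration_ms = 600000, n_reps = 20,
                            gpi_thalamus_scale = if (id == 5) 0.1 else 1,
                            stim_amplitude_pA = 250, dt = 0.5) {
  id <- as.integer(id)
  stopifnot(id %in% 1:5, n_reps >= 1, duration_ms >= 8000)
  preset <- list(
    `1` = list(phi_tonic = 0.5, phi_phasic = 0,   stim = FALSE),
    `2` = list(phi_tonic = 0.5, phi_phasic = 0.5, stim = TRUE),
    `3` = list(phi_tonic = 0.5, phi_phasic = 0,   stim = TRUE),
    `4` = list(phi_tonic = 0.5, phi_phasic = 0.4, stim = TRUE),
    `5` = list(phi_tonic = 0,   phi_phasic = 0,   stim = FALSE)
  )[[as.character(id)]]
  if (id == 5 && gpi_thalamus_scale >= 1)
    stop("scenario 5 requires gpi_thalamus_scale < 1")
  if (id != 5 && gpi_thalamus_scale != 1)
    stop("gpi_thalamus_scale is reserved for scenario 5")
  analysed_start <- duration_ms - 7000
  stim_window <- analysed_start + c(2000, 4000)
  structure(list(id = id, phi_tonic = preset$phi_tonic,
                 phi_phasic = preset$phi_phasic,
                 stimulus_enabled = preset$stim,
                 stim_window = stim_window,
                 stim_amplitude_pA = stim_amplitude_pA,
                 gpi_thalamus_scale = gpi_thalamus_scale,
                 duration_ms = duration_ms, n_reps = n_reps, dt = dt),
            class = "scenario_config")
}

#' Dopamine schedule of a scenario
#' @param scenario A [scenario_config()].
#' @return A [dopamine_schedule()].
#' @export
scenario_schedule <- function(scenario) {
  dopamine_schedule(
    phi_tonic = scenario$phi_tonic, phi_phasic = scenario$phi_phasic,
    stimulus_windows = if (scenario$stimulus_enabled &&
                           scenario$phi_phasic > 0)
      matrix(scenario$stim_window, 1) else NULL)
}

# repetition k of scenario s under master seed m gets its own wiring and
# noise seed; kept below 2^31 and recorded in the run metadata
derive_seed <- function(master_seed, scenario_id, rep) {
  as.integer((as.numeric(master_seed) * 7919 + scenario_id * 1009 +
                rep * 9973) %% .Machine$integer.max)
}

#' Run one repetition of a scenario
#'
#' Builds a fresh random network from the derived seed, applies the
#' scenario's GPi-to-thalamus scaling, and simulates it under the
#' scenario's dopamine schedule and stimulus.
#'
#' @param scenario A [scenario_config()].
#' @param master_seed Master seed for the batch.
#' @param rep Repetition index (1-based).
#' @param populations,projections,param_table Optional overrides of the
#'   default configuration tables.
#' @return A `spike_record`.
#' @export
run_scenario_rep <- function(scenario, master_seed = 1L, rep = 1L,
                             populations = population_table(),
                             projections = projection_table(),
                             param_table = neuron_param_table()) {
  seed <- derive_seed(master_seed, scenario$id, rep)
  net <- build_network(populations, projections, seed = seed,
                       param_table = param_table)
  if (scenario$gpi_thalamus_scale != 1) {
    sel <- net$edges$proj == "GPi->TC"
    net$edges$weight[sel] <- net$edges$weight[sel] *
      scenario$gpi_thalamus_scale
  }
  cfg <- simulation_config(
    duration_ms = scenario$duration_ms, dt = scenario$dt,
    seed = seed,
    stimulus = if (scenario$stimulus_enabled)
      list(amplitude_pA = scenario$stim_amplitude_pA,
           window_ms = scenario$stim_window) else NULL)
  run_simulation(net, scenario_schedule(scenario), cfg)
}

#' Run all repetitions of a scenario
#'
#' Each repetition uses an independently wired network (derived seed); a
#' failing repetition is reported and skipped rather than aborting the
#' batch.
#'
#' @inheritParams run_scenario_rep
#' @return List of `spike_record`s (failed repetitions carry the error
#'   condition instead).
#' @export
run_scenario <- function(scenario, master_seed = 1L,
                         populations = population_table(),
                         projections = projection_table(),
                         param_table = neuron_param_table()) {
  lapply(seq_len(scenario$n_reps), function(k) {
    tryCatch(run_scenario_rep(scenario, master_seed, k, populations,
                              projections, param_table),
             error = function(e) {
               warning("repetition ", k, " failed: ", conditionMessage(e))
               e
             })
  })
}
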
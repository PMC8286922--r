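#' Load, validate and save run configurations
#'
#' A run configuration is a small YAML document describing a scenario
#' run: scenario id, dopamine levels, durations, repetitions, stimulus
#' amplitude and master seed. Unknown keys are rejected and every
#' violated invariant is reported (dopamine levels must be non-negative
#' and sum to at most 1; scenario presets pin their own phi values).
#'
#' @param path YAML file.
#' @return Validated list of class `"bg_config"` with a
#'   `scenario_config` in `$scenario` and the master seed in `$seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) stop("empty configuration file")
  validate_config(raw)
}

validate_config <- function(raw) {
  allowed <- c("scenario_id", "duration_ms", "n_reps",
               "gpi_thalamus_scale", "stim_amplitude_pA", "dt", "seed",
               "phi_tonic", "phi_phasic")
  problems <- character(0)
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  if (is.null(raw$scenario_id))
    problems <- c(problems, "scenario_id is required")
  pt <- raw$phi_tonic; pp <- raw$phi_phasic
  if (!is.null(pt) && (pt < 0)) problems <- c(problems, "phi_tonic < 0")
  if (!is.null(pp) && (pp < 0)) problems <- c(problems, "phi_phasic < 0")
  if (!is.null(pt) && !is.null(pp) && pt + pp > 1)
    problems <- c(problems,
                  sprintf("phi_tonic + phi_phasic = %.3f exceeds 1",
                          pt + pp))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  args <- raw[intersect(names(raw),
                        c("duration_ms", "n_reps", "gpi_thalamus_scale",
                          "stim_amplitude_pA", "dt"))]
  sc <- do.call(scenario_config, c(list(id = raw$scenario_id), args))
  # explicit phi values, if given, must agree with the preset
  if (!is.null(pt) && pt != sc$phi_tonic)
    stop("phi_tonic = ", pt, " conflicts with the scenario ", sc$id,
         " preset (", sc$phi_tonic, ")")
  if (!is.null(pp) && pp != sc$phi_phasic)
    stop("phi_phasic = ", pp, " conflicts with the scenario ", sc$id,
         " preset (", sc$phi_phasic, ")")
  structure(list(scenario = sc, seed = as.integer(raw$seed %||% 1L)),
            class = "bg_config")
}

#' @rdname load_config
#' @param config A `bg_config`.
#' @export
save_config <- function(config, path) {
  sc <- config$scenario
  yaml::write_yaml(list(scenario_id = sc$id,
                        phi_tonic = sc$phi_tonic,
                        phi_phasic = sc$phi_phasic,
                        duration_ms = sc$duration_ms,
                        n_reps = sc$n_reps,
                        gpi_thalamus_scale = sc$gpi_thalamus_scale,
                        stim_amplitude_pA = sc$stim_amplitude_pA,
                        dt = sc$dt,
                        seed = config$seed), path)
  invisible(path)
}

#' Run manifest
#'
#' Reproducibility metadata for a batch of repetitions: the configuration
#' snapshot, per-repetition derived seeds and output paths, software
#' version and timestamps. Sufficient to re-run any repetition
#' bit-identically.
#'
#' @param config A `bg_config`.
#' @param out_paths Per-repetition output paths (may be `NA`).
#' @return List of class `"run_manifest"`.
#' @export
run_manifest <- function(config, out_paths = NULL) {
  sc <- config$scenario
  reps <- seq_len(sc$n_reps)
  structure(list(config = config,
                 seeds = vapply(reps, function(k)
                   derive_seed(config$seed, sc$id, k), integer(1)),
                 out_paths = out_paths %||% rep(NA_character_,
                                                length(reps)),
                 version = as.character(utils::packageVersion("bgloop")),
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 warnings = character(0)),
            class = "run_manifest")
}
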
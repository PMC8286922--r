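#!/usr/bin/env Rscript
# Calibration sweep for the scenario-5 GPi-to-thalamus reduction factor:
# runs the Parkinsonian resting scenario at several factors and reports
# the thalamic rebound-burst yield. The packaged default (0.1) is the
# largest factor at which tremor-like bursting appears reliably.
# Usage: Rscript scripts/sweep_gpi_thalamus_scale.R [--seed S]

suppressPackageStartupMessages(library(bgloop))
args <- commandArgs(trailingOnly = TRUE)
i <- match("--seed", args)
seed <- if (is.na(i)) 1L else as.integer(args[i + 1])

for (scale in c(0.5, 0.35, 0.2, 0.15, 0.1, 0.05)) {
  sc <- scenario_config(5, duration_ms = 17000, n_reps = 2,
                        gpi_thalamus_scale = scale)
  recs <- lapply(1:2, function(k) run_scenario_rep(sc, seed, k))
  bs <- lapply(recs, burst_stats, population = "TC")
  cat(sprintf("scale %.2f: max burst %d, rebound bursts %d\n", scale,
              max(vapply(bs, `[[`, integer(1), "max_burst_len")),
              sum(vapply(bs, `[[`, integer(1), "n_rebound_bursts"))))
}
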
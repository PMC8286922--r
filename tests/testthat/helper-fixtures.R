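# shared fixtures: small networks for unit tests, cached scenario runs for
# the acceptance suite (built once, reused across blocks)

param_tab <- neuron_param_table()

# a miniature two-population excitatory/inhibitory net for wiring tests
tiny_populations <- function() {
  data.frame(name = c("CTX_RS", "CTX_FS"), size = c(20, 10),
             bg_rate_hz = c(100, 100), bg_weight_pA = c(200, 200))
}

tiny_projections <- function(p_rr = 0.5, p_rf = 0.5) {
  data.frame(source = c("CTX_RS", "CTX_FS"),
             target = c("CTX_RS", "CTX_RS"),
             sign = c(1, -1), p = c(p_rr, p_rf),
             weight_mean = c(50, 80), weight_sd = c(10, 10),
             w_max_abs = c(150, 200), delay_ms = c(2, 1),
             plastic = c(TRUE, FALSE),
             da_mod = c("none", "none"),
             stdp_profile = c("cortical", "none"))
}

# scaled-down scenario runs used by several acceptance blocks; cached so
# each scenario is simulated once per test session
.scen_cache <- new.env(parent = emptyenv())

TEST_DURATION_MS <- 17000 # 10 s warm-up + the analysed final 7 s
TEST_REPS <- 2L
TEST_MASTER_SEED <- 1L

scenario_runs <- function(id) {
  key <- paste0("s", id)
  if (is.null(.scen_cache[[key]])) {
    sc <- scenario_config(id, duration_ms = TEST_DURATION_MS,
                          n_reps = TEST_REPS)
    .scen_cache[[key]] <- lapply(seq_len(TEST_REPS), function(k)
      run_scenario_rep(sc, TEST_MASTER_SEED, k))
  }
  .scen_cache[[key]]
}

scenario_cfg <- function(id) scenario_config(id,
                                             duration_ms = TEST_DURATION_MS,
                                             n_reps = TEST_REPS)

# averaged fine-grid rate and its spectral summary for one population
scen_spectrum <- function(id, population, window = NULL) {
  recs <- scenario_runs(id)
  avg <- average_rates(lapply(recs, firing_rate, population = population,
                              window_ms = 2, stride_ms = 2,
                              window = window))
  spectral_summary(avg)
}

scen_mean_rate <- function(id, population, window = NULL) {
  recs <- scenario_runs(id)
  mean(vapply(recs, function(r)
    mean(firing_rate(r, population, window = window)$rate_hz), numeric(1)))
}

# a custom (phi_tonic, gpi_thalamus_scale) arm sharing scenario-5 seeds,
# for the two-factor comparison
necessity_arm <- function(phi_tonic, scale) {
  lapply(seq_len(TEST_REPS), function(k) {
    seed <- bgloop:::derive_seed(TEST_MASTER_SEED, 5L, k)
    net <- build_network(seed = seed)
    sel <- net$edges$proj == "GPi->TC"
    net$edges$weight[sel] <- net$edges$weight[sel] * scale
    run_simulation(net, dopamine_schedule(phi_tonic, 0),
                   simulation_config(duration_ms = TEST_DURATION_MS,
                                     seed = seed))
  })
}

total_rebound_bursts <- function(recs) {
  sum(vapply(recs, function(r)
    burst_stats(r, "TC")$n_rebound_bursts, integer(1)))
}

# independent oracle: plain O(n^2) pair sum over the STDP kernel
brute_stdp <- function(pre, post, prof) {
  dw <- 0
  for (tp in pre) for (tq in post) {
    d <- tq - tp
    if (d > 0) dw <- dw + prof$a_plus * exp(-d / prof$tau_plus)
    else if (d < 0) dw <- dw - prof$a_minus * exp(d / prof$tau_minus)
  }
  dw
}
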
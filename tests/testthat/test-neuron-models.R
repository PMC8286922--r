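test_that("parameter table loads and validates all cell types", {
  for (ct in c("D1_MSN", "D2_MSN", "GPe", "GPi", "STN", "CTX_RS",
               "CTX_FS", "TC")) {
    p <- neuron_params(ct, param_tab)
    expect_s3_class(p, "neuron_params")
    expect_lt(p$reset_mV, p$threshold_mV)
    expect_lt(p$threshold_mV, p$peak_mV)
  }
  # second slow variable is a TC-only feature
  bad <- param_tab
  bad$slow2_rate[bad$cell_type == "GPe"] <- 0.01
  expect_error(neuron_params("GPe", bad), "slow variable")
  expect_error(neuron_params("D1_MSN",
                             transform(param_tab, da_d_scale = 0)),
               "dopamine")
})

test_that("reset is applied whenever the step crosses the cutoff", {
  p <- neuron_params("CTX_RS", param_tab)
  st <- list(v = p$peak_mV + 1, u = 0, w = NULL, last_spike_time = NULL)
  out <- step_neuron(st, p, injected_current = 0, phi = 0.5, dt = 0.1,
                     t = 3.2)
  expect_true(out$spike)
  expect_identical(out$state$v, p$reset_mV)
  expect_identical(out$state$last_spike_time, 3.2)
  # and in a full trace, v right after each spike equals the reset value
  tr <- simulate_neuron(neuron_params("GPe", param_tab),
                        stimulus_protocol(500, 100), dt = 0.1)
  idx <- round(tr$spike_times / tr$dt) + 2 # sample following the step
  expect_true(all(abs(tr$v_mV[idx] - (-50)) < 1e-9))
  expect_true(all(tr$v_mV <= neuron_params("GPe", param_tab)$peak_mV))
})

test_that("step_neuron rejects bad inputs", {
  p <- neuron_params("STN", param_tab)
  st <- list(v = p$resting_mV, u = 0)
  expect_error(step_neuron(st, p, 0, phi = 1.5), "phi")
  expect_error(step_neuron(st, p, 0, dt = 2), "stability cap")
  expect_error(step_neuron(list(v = NaN, u = 0), p, 0), "v")
})

test_that("MSNs are silent without stimulation; pallidal cells pace", {
  for (ct in c("D1_MSN", "D2_MSN")) {
    tr <- simulate_neuron(neuron_params(ct, param_tab),
                          stimulus_protocol(3000, 0, 0.5))
    expect_length(tr$spike_times, 0)
  }
  for (ct in c("GPe", "GPi")) {
    tr <- simulate_neuron(neuron_params(ct, param_tab),
                          stimulus_protocol(2000, 0, 0.5))
    expect_gt(length(tr$spike_times), 50) # sustained fast spiking at I = 0
    expect_lte(find_rheobase(neuron_params(ct, param_tab)), 0)
  }
})

test_that("simulate_neuron is deterministic", {
  p <- neuron_params("STN", param_tab)
  pr <- stimulus_protocol(c(300, 300), c(0, 120), 0.5)
  expect_identical(simulate_neuron(p, pr)$spike_times,
                   simulate_neuron(p, pr)$spike_times)
})

test_that("f-I curves: zero below rheobase, non-decreasing above", {
  grid <- seq(0, 400, by = 50)
  for (ct in c("CTX_RS", "CTX_FS", "GPe", "GPi", "D1_MSN")) {
    p <- neuron_params(ct, param_tab)
    fi <- f_i_curve(p, 0.5, grid, trial_duration = 1500)
    rheo <- find_rheobase(p, 0.5, tol = 2, trial_duration = 1500)
    expect_true(all(fi$rate_hz[fi$current_pA < rheo - 4] == 0))
    expect_true(all(diff(fi$rate_hz) > -1e-9))
  }
  expect_error(f_i_curve(neuron_params("STN", param_tab), 0.5,
                         numeric(0)), "empty")
})

test_that("halving dt changes f-I frequencies by < 5%", {
  p <- neuron_params("CTX_RS", param_tab)
  grid <- c(100, 200, 300)
  f1 <- f_i_curve(p, 0.5, grid, trial_duration = 1500, dt = 0.1)$rate_hz
  f2 <- f_i_curve(p, 0.5, grid, trial_duration = 1500, dt = 0.05)$rate_hz
  expect_true(all(abs(f1 - f2) / pmax(f2, 1) < 0.05))
})

test_that("rheobase bisection brackets the firing threshold", {
  p <- neuron_params("CTX_RS", param_tab)
  r <- find_rheobase(p, 0.5, tol = 1, trial_duration = 1500)
  below <- simulate_neuron(p, stimulus_protocol(1500, r - 2, 0.5))
  above <- simulate_neuron(p, stimulus_protocol(1500, r + 2, 0.5))
  expect_length(below$spike_times[below$spike_times > 750], 0)
  expect_gt(length(above$spike_times), 0)
  expect_error(find_rheobase(p, 0.5, upper = 10), "bound")
})

test_that("D1 latency exceeds later ISIs; DA raises slope, not rheobase", {
  p <- neuron_params("D1_MSN", param_tab)
  tr <- simulate_neuron(p, stimulus_protocol(2000, 150, 0.52))
  expect_gt(length(tr$spike_times), 3)
  expect_gt(tr$spike_times[1], max(diff(tr$spike_times)))
  # rheobase is unchanged by dopamine; suprathreshold slope increases
  r1 <- find_rheobase(p, 0.52, tol = 1)
  r2 <- find_rheobase(p, 0.98, tol = 1)
  expect_lte(abs(r1 - r2), 2)
  f52 <- f_i_curve(p, 0.52, c(150, 300), trial_duration = 1500)$rate_hz
  f98 <- f_i_curve(p, 0.98, c(150, 300), trial_duration = 1500)$rate_hz
  expect_gt(diff(f98), 0)
  expect_gt(f98[1], f52[1])
})

test_that("dopamine excites D1 and inhibits D2 at fixed current", {
  d1 <- neuron_params("D1_MSN", param_tab)
  d2 <- neuron_params("D2_MSN", param_tab)
  rate <- function(p, phi, I) {
    st <- simulate_neuron(p, stimulus_protocol(1500, I, phi))$spike_times
    length(st[st > 750])
  }
  expect_gt(rate(d1, 0.9, 200), rate(d1, 0.3, 200))
  expect_lt(rate(d2, 0.9, 320), rate(d2, 0.3, 320))
})

test_that("STN fires spontaneously and rebounds after hyperpolarisation", {
  p <- neuron_params("STN", param_tab)
  free <- simulate_neuron(p, stimulus_protocol(2000, 0, 0.5))$spike_times
  expect_gt(length(free[free > 1000]), 5) # low-frequency spontaneous mode
  tr <- simulate_neuron(p, stimulus_protocol(c(500, 500, 1000),
                                             c(0, -300, 0), 0.5))
  st <- tr$spike_times
  expect_length(st[st >= 500 & st < 1000], 0) # silenced during the hold
  expect_gte(sum(st >= 1000 & st < 1100), 2)  # rebound burst at release
  expect_gt(length(st[st > 1500]), 3)         # spontaneous firing resumes
})

test_that("TC cell: rebound burst, and burst-to-tonic transition", {
  p <- neuron_params("TC", param_tab)
  tr <- simulate_neuron(p, stimulus_protocol(c(500, 500, 1000),
                                             c(0, -900, 0), 0.5))
  expect_lt(min(tr$v_mV[tr$time_ms > 500 & tr$time_ms < 1000]), -80)
  burst <- tr$spike_times[tr$spike_times >= 1000 & tr$spike_times < 1200]
  expect_gte(length(burst), 3)
  # above rheobase: initial fast spikes, then slower regular firing
  tn <- simulate_neuron(p, stimulus_protocol(2000, 150, 0.5))$spike_times
  expect_gt(length(tn), 5)
  isi <- diff(tn)
  expect_lt(mean(head(isi, 3)), mean(tail(isi, 3)))
  # silent at rest
  expect_length(simulate_neuron(p,
                                stimulus_protocol(1000, 0, 0.5))$spike_times,
                0)
})

test_that("phase portrait equilibria match simulated behaviour", {
  p <- neuron_params("CTX_RS", param_tab)
  low <- phase_portrait(p, injected_current = 0)
  expect_true("stable" %in% low$equilibria$stability)
  high <- phase_portrait(p, injected_current = 500)
  expect_false("stable" %in% high$equilibria$stability)
  expect_named(low$nullclines, c("v", "u_vnull", "u_unull"))
})

test_that("bifurcation scan agrees with the rheobase bisection", {
  for (ct in c("CTX_RS", "D1_MSN")) {
    p <- neuron_params(ct, param_tab)
    rheo <- find_rheobase(p, 0.5, tol = 0.5, trial_duration = 2500)
    scan <- bifurcation_scan(p, seq(0, 400, by = 1), phi = 0.5)
    expect_false(is.na(scan$bifurcation_current))
    # the saddle-node point and the sustained-firing threshold agree
    expect_lt(abs(scan$bifurcation_current - rheo), 10)
  }
})
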
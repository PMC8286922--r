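# bgloop

A spiking-network simulator of the basal ganglia–thalamo-cortical loop
with dopamine as a control parameter, for studying how the circuit's
oscillatory state — and its gating of cortical information through the
thalamus — changes between healthy and Parkinsonian conditions.

## Who this is for, and what it does

Computational neuroscientists who want a compact, reproducible model of
the cortex → striatum → pallidum/STN → thalamus circuit that:

* builds the network from ~1,700 extended Izhikevich point neurons —
  seven cell classes (regular- and fast-spiking cortex, D1-/D2-type
  medium spiny neurons, GPe, GPi, STN, thalamocortical relay cells),
  wired as a random graph with conduction delays and signed weights;
* treats dopamine as a tonic + stimulus-locked phasic level
  φ(t) ∈ [0, 1] that excites D1 cells, inhibits D2 cells and rescales
  cortico-striatal efficacy, thereby switching dominance between the
  direct (gate-open) and indirect (gate-closed) pathways;
* evolves the cortical and cortico-striatal synapses with pair-based
  additive STDP, including structural (prune/re-form) plasticity;
* ships five ready-made protocol scenarios (healthy resting, gate open,
  gate closed, attenuated phasic dopamine, Parkinsonian resting with
  weakened GPi→thalamus weights);
* analyses the output with the field's standard pipeline: population
  firing rates (T = 50 ms windows, multi-run averages), Hann-windowed
  spectrograms and power histograms, dominant-frequency/band labels
  (theta 4–8, alpha 8–13, beta 13–30, gamma 30–150 Hz), pairwise
  spike-count synchrony, burst statistics, and VAR-based partial
  directed coherence.

The single-cell model is the quadratic threshold-firing form
`C v' = k (v − v_r)(v − v_t) − u − w + I`, `u' = a (b (v − v_r) − u)`,
with spike reset `v ← c, u ← u + d`; thalamic relay cells carry a second,
slower recovery variable `w` that powers their rebound bursts. All
parameters live in plain-text tables under `inst/extdata/`.

## Worked example: the Parkinsonian resting state

```r
library(bgloop)

# scenario 5: tonic dopamine depleted, GPi->thalamus weights reduced;
# scaled-down runs (10 s warm-up + the analysed 7 s), two repetitions
sc <- scenario_config(5, duration_ms = 17000, n_reps = 2)
recs <- lapply(1:2, function(k) run_scenario_rep(sc, master_seed = 1,
                                                 rep = k))
recs[[1]]
#> <spike_record> 517749 spikes over 17 s (seed 22937)

# subthalamic rhythm, from the repetition-averaged 2 ms rate series
stn <- average_rates(lapply(recs, firing_rate, population = "STN",
                            window_ms = 2, stride_ms = 2))
spectral_summary(stn)
#> <spectral_summary> STN: dominant 17 Hz (beta), band power fraction 0.12

# tremor-like thalamic rebound bursting
burst_stats(recs[[1]], "TC")[c("max_burst_len", "n_rebound_bursts")]
#> $max_burst_len
#> [1] 3
#> $n_rebound_bursts
#> [1] 11

# dopamine leaves the D1 rheobase untouched (it only steepens the f-I)
find_rheobase(neuron_params("D1_MSN"), 0.52)
#> [1] 110.6445
```

The STN (with GPe and the D2 population) sits in the beta band — the
Parkinsonian signature — and the thalamus fires rebound bursts of three
or more spikes; in the healthy resting scenario (`scenario_config(1)`)
the same network shows cortical theta, pallidal gamma and a silent
thalamus.

A thin command-line front end is included at `inst/scripts/bgloop`
(`bgloop run --scenario 5 --reps 20 --seed 1 --out DIR [--fast]`, plus
`analyze`, `validate-config` and `neuron` subcommands).

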
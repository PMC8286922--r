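---
title: "Methods: a spiking model of basal ganglia-thalamo-cortical gating under dopamine control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking model of basal ganglia-thalamo-cortical gating under dopamine control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The circuit and what the model is for

The basal ganglia (BG) sit between cortex and thalamus and act as a
dopamine-controlled gate on cortical information flow. Cortical input
reaches the striatum, whose two classes of medium spiny neurons (MSNs)
launch two competing routes to the BG output nucleus: the *direct*
pathway (D1-type MSNs inhibit the GPi, releasing the thalamus) and the
*indirect* pathway (D2-type MSNs inhibit the GPe, which disinhibits the
STN, which excites the GPi and clamps the thalamus shut). A *hyperdirect*
route (cortex to STN to GPi) provides an early brake. Dopamine tips the
balance: D1 cells are excited and D2 cells inhibited by it, and it also
rescales the efficacy of the cortico-striatal synapses. When dopamine is
depleted, the indirect pathway dominates and the BG network falls into
exaggerated beta-band (13-30 Hz) synchrony, the electrophysiological
signature of Parkinson's disease (PD); combined with weakened
pallido-thalamic coupling, the thalamus develops tremor-like rebound
bursting.

`bgloop` implements this circuit as a spiking network of ~1,700 extended
Izhikevich-type point neurons and reproduces five protocol scenarios —
three healthy (resting; stimulus with adequate phasic dopamine; stimulus
with no phasic dopamine) and two Parkinsonian (attenuated phasic
dopamine; depleted tonic dopamine at rest with weakened GPi-thalamus
coupling) — together with the firing-rate and spectral pipeline used to
read the network's frequency-band signatures.

# Single-cell model

Every neuron follows the quadratic threshold-firing form

$$C\,\dot v = k\,(v - v_r)(v - v_t) - u - w + I_{\text{bias}} + I(t),\qquad
  \dot u = a\,[\,b\,(v - v_r) - u\,],$$

with the auxiliary reset: when $v \ge v_{\text{peak}}$ a spike is
registered, $v \leftarrow c$ and $u \leftarrow u + d$. The second slow
variable $w$ (same linear form, slower rate $a_2$, sensitivity $b_2$,
post-spike jump $d_2$) exists only for thalamocortical (TC) relay cells,
where it stands in for the slow T-type calcium/potassium machinery that
produces rebound bursts; for all other cell types $w \equiv 0$. Voltages
are clamped below at $-100$ mV (an inhibitory-reversal floor that keeps
the quadratic term well behaved under strong synchronous inhibition).
Integration is explicit Euler — 0.1 ms in single-cell mode, 0.5 ms in
network mode — with a hard stability cap of 1 ms.

All parameter values live in one versioned table
(`inst/extdata/neuron_params.tsv`) and nowhere else. They were seeded
from canonical parameter regimes for each firing class (regular spiking
for excitatory cortex, fast spiking for cortical interneurons and the
pallidal segments, latency class for MSNs, rebound classes for STN and
TC) and then calibrated with `find_rheobase()`/`f_i_curve()` until the
qualitative single-cell repertoire holds:

* **MSNs** rest hyperpolarised at $-80$ mV and are silent without input;
  above rheobase the first spike arrives with a latency longer than any
  subsequent inter-spike interval (the latency class: small $a$,
  negative $b$).
* **GPe/GPi** are autonomous pacemakers. The model expresses this with a
  constant intrinsic bias current ($I_{\text{bias}}$), so both cells
  fire fast spikes at zero injected current and their rheobase is
  negative.
* **STN** fires spontaneously at low rate, has a slightly sigmoidal f-I
  curve, and rebounds with a short burst after release from
  hyperpolarisation (slow positive $b$).
* **TC** cells are silent at rest, fire an initial fast cluster that
  relaxes to tonic firing under depolarising current, and produce a
  multi-spike rebound burst after $\ge$ 500 ms below $-80$ mV. The TC
  cell combines a fast *amplifying* recovery variable (negative $b$,
  near-threshold reset $c$) that sustains bursts with the slow positive
  $b_2$ variable that charges during hyperpolarisation and powers the
  rebound.

## Dopamine at the membrane

The circuit dopamine level $\phi(t) \in [0,1]$ splits into identical
D1/D2 receptor levels (`split_receptor_levels()` is the seam for future
receptor-specific schedules). At the membrane it acts only on MSNs, with
opposite signs:

* **D1**: the after-spike increment shrinks,
  $d_{\text{eff}} = d\,(1 - L\,\phi)$ with $L = 0.8$. This raises the
  suprathreshold f-I slope while leaving the rheobase exactly unchanged —
  the two features the reference recordings pin down for D1 cells.
* **D2**: a hyperpolarising current $-\kappa\,\phi$ with
  $\kappa = 240$ pA. This lowers the D2 response monotonically in
  $\phi$ and hyperpolarises D2 cells during phasic release.

$\kappa$ is deliberately strong: it is the main lever by which the tonic
dopamine level switches the indirect pathway between its healthy
($\phi = 0.5$) and Parkinsonian ($\phi = 0$) operating points. A side
effect is that an isolated D2 cell at $\phi \approx 0.5$ needs more than
200 pA to fire, somewhat above the reference single-cell figure; the D2
unit tests therefore probe the dopamine sign property above that
rheobase.

In the network, dopamine additionally rescales cortico-striatal efficacy
(the second role of dopamine): inputs onto D1 are multiplied by
$1 + 0.6\,\phi$ and onto D2 by $1 - 0.6\,\phi$, applied at pulse-arrival
time.

## The dopamine schedule

$\phi(t) = \phi_{\text{tonic}} + \phi_{\text{phasic}}(t)$ with
$\phi_{\text{tonic}} + \phi_{\text{phasic}} \le 1$. The phasic component
jumps instantaneously to its peak while the cortex is stimulated and
decays exponentially afterwards with a 500 ms time constant (the
single-exponential decay is the minimal smooth choice consistent with
"decays with time"; both the constant and the form are configuration,
not code).

# Network construction

Populations: 800 regular-spiking and 200 fast-spiking cortical cells
(the 4:1 cortical ratio), 200 D1- and 200 D2-MSNs, and 100 cells each in
GPe, GPi, STN and the TC relay population. Wiring is an independent
random graph: each (pre, post) pair of a projection connects with the
projection's probability, without self-connections; weights are drawn
from a clipped normal distribution and signed by the source population
(inhibitory efferents stay non-positive, excitatory non-negative — a
Dale-like consistency that is enforced and tested). Each projection has
a conduction delay, rounded to whole integration steps. The projection
table (`inst/extdata/projections.tsv`) carries the probabilities, weight
scales, bounds and delays; the inhibitory couplings are generally
stronger than the excitatory ones.

Synapses are delta-current pulses: a presynaptic spike deposits its
weight into the target's input current exactly one conduction delay
later, for one integration step. Poisson background trains (per-neuron
rate and pulse weight in `inst/extdata/populations.tsv`) stand in for
the afferents outside the modelled circuit and set each population's
basal rate.

Two design choices deserve comment because the defaults were genuinely
open:

* **Pallido-subthalamic loop delays** (6 ms each way) place the
  STN-GPe loop resonance in the beta band when the loop is released by
  GPe suppression; at healthy GPe rates the loop is damped and the
  resonance is invisible.
* **GPi drive composition**: the GPi combines a pacemaker bias with a
  strong, convergent STN projection, so its rate inherits the
  subthalamic state — steady and high in the healthy resting state,
  elevated and beta-modulated in the dopamine-depleted state. This is
  what lets the same wiring produce "constant inhibitory influence" in
  scenario 1 and an increased, oscillating GPi in scenario 5.

## Plasticity

Three projections are plastic: the intra-cortical excitatory
connections, cortical excitatory-to-inhibitory connections, and the
cortico-striatal projection onto D1 MSNs. The rule is pair-based
additive STDP over all spike pairs: $\Delta w = A_+ e^{-\Delta t/\tau_+}$
for pre-before-post, $-A_- e^{\Delta t/\tau_-}$ for post-before-pre,
nothing at exact coincidence. The intra-cortical and cortico-striatal
profiles differ (the cortico-striatal window potentiates faster and
depresses more slowly). Weights are clipped to per-projection bounds —
the anti-instability clamp — and a weight clipped to zero marks the edge
prunable: with a small per-update probability it is re-formed between a
uniformly drawn unconnected pair at the minimum positive weight
(structural/wiring plasticity). Every prune/form event is logged with
its timestamp. Updates are applied in 1 s batches using the spikes since
the previous batch, which for the additive all-pairs rule is equivalent
to online updating up to clipping order; the batched update is verified
against a brute-force $O(n^2)$ pair-sum oracle in the tests.

# The five scenarios

| id | $\phi_{\text{tonic}}$ | $\phi_{\text{phasic}}$ | stimulus | GPi$\to$TC scale |
|----|------|------|----------|------|
| 1  | 0.5  | 0    | off      | 1    |
| 2  | 0.5  | 0.5  | on       | 1    |
| 3  | 0.5  | 0    | on       | 1    |
| 4  | 0.5  | 0.4  | on       | 1    |
| 5  | 0    | 0    | off      | 0.1  |

The stimulus is a 2 s constant-current step (default 250 pA) into both
cortical populations, placed at seconds 2-4 of the analysed window.
Twenty repetitions with independently wired networks are the reference
protocol; every repetition's seed derives deterministically from the
master seed, the scenario id and the repetition index.

The scenario-5 GPi-thalamus reduction factor is not stated in the
source description; it is a configuration value, swept by
`scripts/sweep_gpi_thalamus_scale.R`. In this implementation the
dopamine-depleted GPi fires roughly 1.5x faster than the healthy one,
which cancels mild weight reductions — tremor-like rebound bursting
emerges only below a factor of about 0.2, and the default is 0.1.

# Analysis pipeline

1. **Raster**: every spike is logged as (population, neuron, time).
2. **Firing rate**: spike counts in half-open sliding windows
   $[t, t+T)$, divided by $T$ and by the population size (per-neuron Hz;
   a flag reproduces the raw population-summed convention). The
   reporting grid uses $T = 50$ ms. Spectral analysis uses the same
   counting rule on a 2 ms grid, because a 50 ms grid caps the spectrum
   at 10 Hz and the claims of interest extend to 150 Hz; the Nyquist
   check is enforced. Rates are averaged pointwise across repetitions
   before any spectral step, as in the reference pipeline.
3. **Spectra**: Hann-windowed short-time Fourier transform, 1 s
   segments, 50% overlap, linear detrend per segment, scaled so the
   time-averaged one-sided power histogram sums to the variance of the
   detrended series (Parseval, verified to estimator tolerance). The
   dominant frequency is the argmax of the non-DC histogram; bands are
   half-open — theta [4, 8), alpha [8, 13), beta [13, 30),
   gamma [30, 150) — so 13 Hz is beta and 30 Hz is gamma. Scenario
   claims tied to "during stimulation" are evaluated on the 2 s stimulus
   window of the averaged rates; resting-state claims on the full
   analysed 7 s. For scenario 2 the gamma claim concerns the STN-GPe
   subnetwork; the acceptance output reports both populations and their
   pooled rate (the pooled signal is carried by the louder GPe).
4. **Synchrony**: mean pairwise Pearson correlation of binned spike
   counts, pooled over the listed populations, clipped to [0, 1] (the
   raw value and the active-neuron count ride along as attributes;
   silent populations give a flagged `NA`, never a silent 0). The
   healthy-vs-PD comparison bins at the reporting window $T = 50$ ms, at
   which the fast pallidal rhythm averages out within bins and beta-band
   comodulation remains.
5. **Directed coupling**: least-squares VAR fit on the multivariate rate
   series (order fixed or AIC-selected), and partial directed coherence
   plus its generalised variant from the frequency-domain coefficient
   matrix, column-normalised so each source column's squared magnitudes
   sum to one at every frequency.
6. **Bursts**: a burst is a run of inter-spike intervals at most 25 ms
   (matching the 40-55 Hz intra-burst rate of the TC rebound response);
   a rebound burst additionally requires at least 50 ms of preceding
   silence. Tremor-like activity is scored as rebound bursts of three or
   more spikes.

The spike-sorting (PCA) step of LFP-style pipelines is deliberately
absent: the simulator produces labelled spikes, so there is nothing to
sort.

# Scaled-down study conditions

The reference protocol simulates 10 minutes per repetition and analyses
the final 7 s. The packaged tests and the acceptance script run the
same analysed 7 s window after a 10 s warm-up (17 s total per
repetition), with 2 repetitions in the test suite and 5 in the
acceptance script, at the network step of 0.5 ms. Warm-up mainly serves
to decorrelate the initial conditions and let the plastic weights settle
near their stationary values; the initial weights are calibrated close
to those values, so the shorter warm-up changes the analysed statistics
little. What the scaled-down runs cannot show is slow structural-
plasticity phenomena that need minutes of simulated time to develop.

# What passes, and what the model does not reproduce

Under these conditions the package reproduces: cortical/D1 theta at
rest with a silent thalamus; the dopamine-gated thalamic relay
(scenario 2 relays the stimulus, scenario 3 blocks it, scenario 4 is
degraded); the scenario-3 GPi surge past 50 Hz with a slow, transient
thalamic response; the scenario-5 beta signature in D2/GPe/STN with
thalamic rebound bursts of three or more spikes; and higher
indirect-pathway synchrony in the PD resting state than in the healthy
one.

Three documented gaps remain, asserted red in the acceptance suite
rather than weakened:

* In scenario 2 the **STN's own dominant frequency** sits in high beta
  (~20 Hz) rather than gamma; the gamma claim holds for the GPe and for
  the pooled STN-GPe subnetwork rate.
* The **scenario-4 thalamic response** is weak (~5 spikes/s, below the
  8 Hz figure) but is patterned at ~17 Hz rather than confined to the
  theta band. The source description is itself ambiguous here — its
  figure caption assigns the scenario-4 thalamus to the beta band while
  the body text says theta.
* Of the **two-factor necessity** of thalamic tremor, only one arm
  reproduces: dopamine depletion alone (full GPi-thalamus weights)
  indeed produces no bursting, but weight reduction alone does, because
  the healthy-state GPi fires more slowly than the PD-state GPi and so
  the healthy thalamus ends up less inhibited at equal scaling. Breaking
  this symmetry presumably requires coupling details not available to
  this implementation.

# Numerical notes, degenerate inputs, limitations

* Determinism: every random element (wiring, Poisson background,
  rewiring draws, initial-potential stagger) flows from one integer
  seed; identical configuration and seed give bit-identical spike
  records, and the RNG state of the calling session is never disturbed.
* The integrator aborts with the step, population and neuron named if a
  membrane potential becomes non-finite.
* Spike times use the start-of-step convention; delays are at least one
  network step; synaptic causality (no effect before spike time plus
  delay) is property-tested.
* Empty stimulus windows, a zero phasic amplitude, zero-rate background
  and empty spike records are all well-defined and tested degenerate
  cases; overlapping stimulus windows are rejected as ill-defined.
* The model is a qualitative instrument: point neurons, delta synapses,
  one global dopamine signal, no striatal fast-spiking interneurons
  (their effect is folded into the MSN parameters and the dopamine
  couplings), no reticular thalamus, no closed thalamo-cortical loop,
  and no claim of quantitative LFP realism — the "LFP" here is a
  population firing rate.
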
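---
title: "A spiking basal ganglia model of subthalamic stimulation and impulsive choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking basal ganglia model of subthalamic stimulation and impulsive choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgstim)
```

## The model

`bgstim` simulates action selection in the cortico-basal-ganglia loop with
spiking neurons, and uses it to study how parkinsonian dopamine depletion,
dopaminergic medication, and subthalamic deep-brain stimulation (DBS) change
decision making on the Iowa Gambling Task (IGT).

Three nuclei - the subthalamic nucleus (STN), the external globus pallidus
(GPe) and the internal globus pallidus (GPi) - are each modelled as a
50 x 50 lattice of two-variable Izhikevich neurons,

$$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with a spike emitted and the state reset ($v \leftarrow c$,
$u \leftarrow u + d$) whenever $v$ reaches $+30$ mV.  Striatal D1 and D2
medium spiny neuron populations are not integrated explicitly; they are
Poisson spike sources whose rates encode learned deck values (below).  The
wiring follows the classic direct/indirect scheme, one-to-one between
corresponding lattice positions:

* striatal D1 inhibits GPi (direct, "Go"),
* striatal D2 inhibits GPe (indirect, "NoGo"),
* STN and GPe are reciprocally coupled (STN excitatory, GPe inhibitory),
* STN excites GPi,
* STN and GPe each carry a 4-neighbour lateral kernel
  (excitatory within STN, inhibitory within GPe).

The hyper-direct cortex-to-STN pathway and the GPe-to-GPi projection are
deliberately absent.  Synapses are current-based single-exponential filters;
each presynaptic spike adds a unit kick that decays with the projection's
time constant.

A thalamic *race model* performs selection: each deck quadrant drives one
leaky accumulator with a constant go signal minus the smoothed GPi firing
rate of that quadrant plus Gaussian noise; the first accumulator to reach
threshold selects its deck, and if none crosses within the trial the largest
accumulator wins (logged as a timeout).

### Deck topography

Every nucleus is partitioned into four equal quadrants carrying the signals
of decks A-D (`quadrant_map()`).  Deck A owns the low-row/low-column
quadrant (lattice point (13, 13)), deck D the high-row/high-column quadrant
(lattice point (38, 38)).  Electrode positions 1, 2 and 3 place the DBS
centre at (13, 13), (25, 25) and (38, 38) respectively, so position 3
selectively stimulates deck D's territory.

## Dopamine

Dopamine acts at two sites.

**Plasticity.** Each deck carries two cortico-striatal weights, $w^{D1}$
and $w^{D2}$, initialised uniformly on (0, 1).  After the network selects a
deck and the card's reward and penalty are drawn, the temporal-difference
error $\delta = Re + L - V$ (with $V$ the selected deck's $w^{D1}$) updates
the selected deck's weights in opposition:
$\Delta w^{D1} = +\eta\,\delta$, $\Delta w^{D2} = -\eta\,\delta$, with
$\eta = 0.1$.  Condition transforms:

* healthy (HC): $\delta$ unchanged;
* untreated PD (PD_OFF): $\delta \leftarrow \min(\delta, DA_{ceil})$ - loss
  of dopamine neurons caps positive reward prediction errors while dips
  pass;
* medicated PD (L-DOPA): $\delta \leftarrow \min(\delta, DA_{ceil}) +
  \delta_{med}$;
* dopamine agonist (DAA): the same medicated error, but applied to $w^{D2}$
  only ($w^{D1}$ frozen), reflecting D2-receptor-selective agonism.

**Network state.** Tonic dopamine scales the lateral coupling within STN
and GPe and the pallido-subthalamic projection as
$g_{eff} = g \cdot \max(0, 1 - k\,DA)$ (for GPe->STN with a
dopamine-independent floor of 10%), so the dopamine-depleted network has
strong lateral coupling and strong slow pallidal inhibition.  This is what
switches the STN-GPe loop from the healthy asynchronous tonic regime into
synchronous ~4 Hz rebound bursting.

## DBS current

The electrode injects, into STN only, a biphasic rectangular pulse train at
130 Hz whose spatial footprint is a Gaussian around the electrode centre:

$$I^{DBS}_{ij} = A_{DBS}\,\exp\!\big(-((i - i_c)^2 + (j - j_c)^2)/\sigma^2\big),$$

note the $\sigma^2$ (not $2\sigma^2$) denominator.  The waveform is +1 for
one phase width, -1 for the next, 0 until the next period; equal phase
widths keep it charge balanced.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| lattice | 50 x 50 per nucleus | module size |
| `dt` | 0.1 ms | explicit-Euler step |
| STN `a,b,c,d` | 0.005, 0.265, -65, 2 | slow recovery + rebound firing |
| GPe/GPi `a,b,c,d` | 0.1, 0.2, -65, 2 | fast tonic pallidal firing |
| `tau_inh` | 140 ms | slow pallidal (GABA-B-like) inhibition; sets the ~4 Hz burst period |
| `tau_exc`, `tau_str` | 5, 10 ms | glutamatergic / striatal GABA kinetics |
| `g_lat_stn`, `g_lat_gpe` | 17, 8.5 | lateral coupling before dopamine scaling |
| `da_coupling` k | 1 | dopamine scaling of lateral + pallido-subthalamic gain |
| striatal rates | affine on `[w_floor, w_max]` = [0.1, 2] to [2, 40] Hz | weight-to-rate code, clipped to the physiological band |
| `eta` | 0.1 | learning rate |
| `da_ceil` | 0.05 | PD clamp on positive TD errors (learning scale) |
| `delta_med` | 13 | medication term; exceeds the largest scaled penalty (12.5) |
| `outcome_scale` | 0.01 | card points to learning scale (100 points = 1) |
| electrode | 130 pA, sigma 35, 130 Hz, 0.4 ms/phase | whole-module desynchronising stimulation |

Several of these are calibration constants rather than literature values;
the choices and their rationale:

* **STN bias current.**  In isolation (`nucleus_params("STN")`, bias 3 pA)
  STN fires tonically at ~12 Hz with rebound.  Inside the network the
  default configuration raises the bias to 34 pA: it stands in for
  background excitatory drive omitted from the reduced circuit and balances
  the tonic component of the slow pallidal inhibition, keeping healthy STN
  tonically active at a few Hz.
* **Slow pallidal inhibition (140 ms).**  The burst period of the STN-GPe
  pacemaker is set by how long STN stays hyperpolarised after a synchronous
  GPe volley.  A GABA-B-like 140 ms time constant places the population
  rhythm at ~4 Hz, the tremor band, and yields a synchrony index near 0.67
  in the dopamine-depleted network.
* **DBS phase width (0.4 ms).**  With 0.1 ms explicit-Euler steps, a
  100 microsecond phase at clinical pA-scale amplitudes perturbs the
  membrane by a few mV that cancel between phases.  0.4 ms per phase makes
  the printed amplitude axis (70-300 pA) span the interesting operating
  range: moderate currents desynchronise the parkinsonian rhythm, large
  currents entrain STN at the stimulation frequency and raise its rate.
* **Medication term (13).**  Chosen to exceed the largest scaled penalty
  (deck B's 1250 points = 12.5), so that under medication *every* outcome -
  including net losses - produces a positive effective error.  This is the
  model's expression of medication-induced insensitivity to punishment:
  weights of picked decks inflate toward the clip, the striatal rate code
  saturates, and the model stops discriminating decks.
* **Rate-map floor (`w_floor` = 0.1).**  Weights at or below 0.1 all map to
  the 2 Hz floor.  In untreated PD, where the clamp keeps learned values
  near zero, deck signals collapse onto the floor and selection is driven
  by residual initial-value differences and noise.

## What the simulations show

With the default configuration:

* **Healthy network**: asynchronous tonic STN activity, synchrony index
  ~0.1-0.2, no prominent low-frequency peak.
* **Dopamine-depleted network**: synchronous rebound bursting, synchrony
  ~0.67, population spectral peak ~4 Hz.
* **Stimulation**: at the default 130 pA whole-module setting the synchrony
  index falls to ~0.42 and the 4 Hz peak is suppressed; below ~70 pA the
  effect fades; at 300 pA and above STN is entrained by the pulse train,
  firing rates rise several-fold and synchrony climbs again (an inverted-U
  in amplitude).
* **IGT**: healthy controls score positive (slow learning of C/D with a
  realistic attraction to deck B's frequent wins); L-DOPA scores negative
  with impaired early bins; the dopamine agonist is near chance with very
  high between-run variance (selection anchored on frozen random initial
  values); untreated PD retains punishment learning.

### A structural caveat on untreated PD

In this architecture the delta clamp can only *remove* components of
healthy learning: negative errors pass unchanged, so untreated PD keeps
punishment-driven avoidance of the disadvantageous decks while being spared
the healthy model's costly chasing of deck B's frequent large rewards.  Its
mean IGT score therefore comes out near or slightly above the healthy mean,
not below it.  Making the untreated-PD score strongly negative would
require a systematic preference for the disadvantageous decks, which cannot
arise from the published update equations together with a payoff schedule
in which the disadvantageous decks are exactly the heavily punished ones.
We implement the published equations and report this tension rather than
distorting the update rule.  The same holds for the stimulated untreated-PD
score.  The medication conditions do reproduce the qualitative clinical
picture (impaired learning, negative trend, high variance).

## The synthetic task environment

The IGT deck schedule is generated, not measured: each pick pays the deck's
fixed reward and, with the deck's loss probability, its penalty (canonical
structure: A 100/-250 at 50%, B 100/-1250 at 10%, C 50/-50 at 50%,
D 50/-250 at 10%; expected values -25, -25, +25, +25 per pick).  The
schedule lives in an editable CSV (`inst/extdata/deck_schedule.csv`).  The
probabilistic-loss form reproduces the canonical long-run payoff structure
but not the exact per-block loss positions of the clinical instrument, and
no claim is made about real-subject behaviour: passing tests show that the
model behaves as specified under this payoff law, not that it predicts
patient data.

## Numerical choices

* Explicit Euler at `dt = 0.1` ms with simultaneous update of $v$ and $u$;
  spike times are assigned to the step on which $v$ crosses +30 mV, no
  interpolation.  Non-finite state aborts with a diagnostic naming the
  nucleus and `dt`.
* The synchrony index is the Kuramoto order parameter over
  linearly-interpolated spike phases, time-averaged over the window where
  every included neuron has a defined phase; neurons with fewer than two
  spikes are excluded with a message.  The index depends mildly on the
  analysis window (phase coherence drifts over long traces); all calibrated
  values use a 3 s window, while spectra use longer traces for finer
  frequency resolution.
* Spectra are plain periodograms of the mean-subtracted 1-ms-binned
  population rate over the full trace, argmax restricted to a band
  (tremor band 2-8 Hz by default); a peak is "prominent" if it exceeds ten
  times the median spectral power.
* Race ties (several accumulators crossing on one step) are broken
  uniformly at random; a trial with no crossing selects the largest
  accumulator and flags a timeout.
* The C++ engine uses its own xoroshiro128+ stream seeded per trial from
  the R session RNG, so runs are reproducible end-to-end from one
  `set.seed()`/`seed =` argument and amplitude-0 stimulation is
  bit-identical to stimulation off.

## Problem sizes used in the test-suite and reproduction script

Population-activity calibration quantities (synchrony, spectra, stimulation
response) are computed on the full 50 x 50 module with 2-3 s of simulated
time and 5-10 seeds.  Behavioural experiments run 10 runs x 100 trials per
condition: on the full module in the reproduction script, and on a 30 x 30
module (with electrode coordinates scaled accordingly) in the
acceptance-tier tests.  Property and unit tests use 20 x 20 to 30 x 30
lattices.  The qualitative regimes (asynchronous healthy activity,
parkinsonian bursting, value-driven selection, stimulation-induced
de-selection) are preserved at these sizes, which are the package's
standard verification sizes.

## Known limitations

* Appendix-level constants of the original circuit (synaptic gains, module
  sizes, Izhikevich parameter tables, payoff schedule) were not available;
  all such values are package calibrations documented above, so agreement
  with printed population-level numbers is calibrated, not derived.
* The thalamic stage is a phenomenological race, not a spiking nucleus.
* No conduction delays, no plasticity inside the BG nuclei, no D3-receptor
  pharmacology, no volume-conductor electrode model.
* The untreated-PD behavioural scores sit near or above healthy scores (see
  the structural caveat above), unlike the printed negative means.
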
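---
title: "Cell-assembly formation and retrieval in a CA3 spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-assembly formation and retrieval in a CA3 spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca3assembly)
```

## The model

Hippocampal area CA3 is the classical substrate for auto-associative
memory: recurrent excitatory connections among pyramidal cells (PCs) store
activity patterns as *cell assemblies*, and partial cues retrieve the full
pattern (*pattern completion*). This package implements a multi-type
spiking model of the mouse CA3 circuit and the training/testing pipeline
around it.

**Neurons.** Every neuron follows the nine-parameter Izhikevich
dynamical-systems formulation

$$C\dot v = k(v - v_r)(v - v_t) - u + I,\qquad
  \dot u = a\,[\,b(v - v_r) - u\,],$$

with a hard reset ($v \le v_{peak} \Rightarrow v \leftarrow v_{min},\,
u \leftarrow u + d$). Eight CA3 neuron types are parameterized: pyramidal
cells plus seven interneuron classes (axo-axonic, basket, CCK+ basket,
bistratified, ivy, mossy-fiber-associated ORDEN, QuadD-LM). The per-type
parameter table ships in the package configurations.

**Synapses.** Each of the 51 directional type pairs carries
five-parameter Tsodyks–Markram short-term plasticity: at each presynaptic
spike arrival the utilization $u$ jumps by $U(1-u)$, the conductance
increments by $w\,g\,u^{+}x$, resources deplete by $u^{+}x$, and between
events $u$, $x$ and the conductance relax exponentially with $\tau_f$,
$\tau_r$, $\tau_d$. Conductances close onto currents through reversal
potentials ($E_{exc}=0$ mV, $E_{inh}=-70$ mV; configurable — the source
work does not state the simulator's closure, so the common
conductance-based convention is used). All conduction delays are 1 ms.

**Long-term plasticity.** Recurrent PC→PC synapses (only) learn under a
symmetric STDP rule, $\Delta w = A e^{-|\Delta t|/\tau}$ with
$\tau = 20$ ms, implemented online with one exponentially decaying trace
per neuron so that every ordered spike pair contributes exactly once
(all-pairs semantics; exact coincidences on the 0.2 ms grid are credited
once at whichever spike is processed second). The maximum weight scales
inversely with assembly size, $w^{*}_{max} = 6000/\mathrm{size}$ (anchored
at $w^{*}_{max}=20$ for size 300), and the amplitude
$A = (w^{*}_{max} - w^{*}_{init})/400$ lets a weight climb from
$w^{*}_{init} = 0.625$ to the cap over the 400 coincident spike pairs of a
100-presentation training run:

```{r}
reproduce_table4()[c(1, 9, 17), ]
```

The printed `g_max` column of the published table implies an unrounded
recurrent conductance of ≈0.5531 nS while the connection table prints
0.55 nS; `g_max` here is derived from the configured 0.55 and can differ
from the published column by up to ~0.4 in the first decimal at small
sizes. The `w_max` and `A` columns reproduce exactly.

**Protocol.** Training presents frozen spike patterns to disjoint (or 5%
pairwise-overlapping) subsets of PCs: each member receives 4 uniform-random
spike times inside a 20 ms gamma window, one pattern per 200 ms theta
cycle, round-robin, after a 1 s settling prefix. Pattern spikes are induced
by 2 ms current pulses of 5,000 pA — calibrated so one pulse produces one
spike at PC parameters (the source work states only "requisite injected
current"); a hard spike-forcing mode exists for unit tests. Between
training and testing every plastic weight is divided by the single factor
`mean(w)/w_init` (homeostatic divisive downscaling: the mean returns to
$w^{*}_{init}$ exactly, ratios are preserved). Testing presents degraded
cues — `round_half_up((1-d/100)·size)` members, sampled equally from
shared and unique members when assemblies overlap — simultaneously at
500 ms of a 1 s run, and reads out the first 20 ms gamma window after cue
offset (the retrieval half of the theta cycle).

**Metrics.** Auto-association is quantified by the SNR (mean
within-assembly plastic weight over mean other plastic weight) and the
fraction of within-assembly synapses at $w_{max}$ (tolerance
$10^{-6}w_{max}$). Retrieval is quantified by reconstruction accuracy
$100\,(PCC_{out} - PCC_{in})/(1 - PCC_{in})$, where the PCCs correlate
binary activity vectors over all PCs: commanded training input vs commanded
cue (input PCC) and observed training output vs observed test readout
(output PCC). The training output is taken from the stimulation gamma
window of the final presentation itself — during training the pattern is
commanded *inside* that window; the post-offset readout convention applies
to testing, where retrieval is expected after the cue. Binary indicators
are the default; spike-count vectorization is available
(`mode = "count"`).

## Design choices in the open points

* **Lognormal background parameterization.** The published per-type
  $(\mu, \sigma^2)$ of the lognormal background current are read as the
  location and variance parameters of $\ln I$ (so PCs at
  $\mu = 4.0,\ \sigma^2 = 1.5$ have median $e^4 \approx 55$ pA and a heavy
  right tail); the alternative reading ($\mu$ = mean in pA ≈ 4 pA) cannot
  produce the reported firing rates at all.
* **Background redraw interval.** One *constant* draw per neuron per phase
  leaves the tail of the lognormal pinned at the same few percent of PCs
  for the entire 19–70 s phase. Under symmetric STDP those tonically
  coactive pairs saturate: in a desk-scale experiment the whole plastic
  matrix reached $w_{max}$ (SNR → 1, PCs at ~108 Hz), erasing assembly
  structure. The protocols therefore redraw each neuron's current every
  100 ms by default (theta-timescale fluctuation of the upstream
  dentate/entorhinal drive); `bg_redraw_ms = Inf` restores the
  constant-per-phase mode, and `sample_network_background()` documents
  both.
* **Scaling rule.** `scale_network(config, f)` multiplies counts by `f`
  and probabilities by `1/f` (capped at 1, with a warning), preserving each
  connection type's expected in-degree — and multiplies the plasticity
  anchor by `f`: the maximum potentiated drive a member receives is
  (within-assembly in-degree) × $w_{max}$ × $g$, and since the in-degree
  grows by $1/f$ under probability rescaling, the anchor must shrink by
  $f$ to keep the trained network in the full-scale dynamical regime. With
  the unscaled anchor the desk-scale network is epileptic after a handful
  of presentations. The *shipped* desk configuration carries a further
  pilot-calibrated factor of 6 on its anchor (1440 rather than 240):
  probability capping at 25× compression makes feedforward inhibition
  relatively stronger than at full scale, and 6 is the smallest multiplier
  (of 2, 3, 4, 6, 8 piloted) that yields robust pattern completion while
  keeping non-assembly weights stable — the same pilot procedure the
  source model used to anchor its own maximum weight.
* **Assembly overlap structure.** Pairwise shared sets are mutually
  disjoint (no cell in three assemblies) and `round_half_up` is used for
  all member counts, consistent with the worked examples (50% of 275 →
  138 cue cells; size 300 at 5% overlap → 135 unique + 15 shared cued).
* **Autapses and multapses.** Excluded: potential connections are
  axo-dendritic overlaps between distinct cells, and the Tsodyks–Markram
  parameters describe the *unitary* (summed-contact) connection, so one
  Bernoulli trial per ordered pair.
* **Normalized SNR ceiling.** The ceiling ("all within-assembly synapses at
  the downscaled maximum, all others at the downscaled minimum") is
  infinite when the lower bound is 0 (non-negative excitatory weights);
  `autoassociation_snr()` implements the definition literally, reports 0
  in that degenerate case and 100 when the observed noise is itself 0, and
  accepts a `w_min_norm` floor for a finite ceiling.
* **Numerics.** Classical RK4 at a fixed 0.2 ms step with currents held
  constant within a step; exact exponential relaxation for all synaptic
  state (unconditionally stable); spike detection after the full step with
  the membrane clamped to $v_{peak}$ in voltage records; delivery exactly
  1 ms (5 steps) after emission. Weight updates are applied immediately at
  each spike with clipping to $[0, w_{max}]$, which makes the online scheme
  exactly equal to the brute-force all-pairs kernel sum when unclipped
  (verified to relative error $<10^{-10}$). Against a dt/20 reference,
  coarse-step spike counts agree within one spike for types firing below
  ~100 Hz; for intrinsically fast-spiking types (basket cells at several
  hundred Hz, tens of steps per inter-spike interval) counts agree within
  ~10%.

## The synthetic circuit configuration

The per-type population counts (except the published axo-axonic count of
1,482) and the 51 connection probabilities are published only in graphical
form, so the shipped configurations are labelled *synthetic*: the PC count
(74,366) makes the published sparseness bounds (assembly sizes 50–600 ↔
γ between 0.067% and 0.8%) exact, the remaining interneuron counts fill
the published 84,053 total, the recurrent PC probability is the CA3
literature value (0.01), and the interneuron pathway probabilities
(~0.06–0.10) are calibrated so the expected synapse count is ≈176 million
and the network sits in the published firing-rate regime (PCs well below
interneurons, sparse background activity) — the same rate-matching
constraint the source model applied to its inputs. Quantitative claims
that depend on the exact published wiring (the full-scale firing-rate
table, reconstruction accuracy at 97.5% degradation, capacity estimates)
are out of desk-scale reach and are not asserted by the test suite.

## What the tests do and do not show

The test suite verifies the machinery against independent oracles
(fine-step reference integration at dt/20, scalar Tsodyks–Markram
recursion, brute-force STDP sums, closed-form set algebra for assemblies
and cues) and runs one seeded end-to-end experiment at desk scale
(scale factor 0.04: 2,975 PCs + 387 interneurons, ~7.0 million synapses,
3 assemblies of 50, 30 presentations each, 50% cue degradation — sizes
chosen so the whole pipeline runs comfortably on one CPU). The end-to-end
checks are directional (SNR > 1 after training; reconstruction accuracy
strictly above its untrained baseline), not the published full-scale
percentages: the desk-scale circuit preserves expected in-degrees but not
the fluctuation statistics of 176 M synapses, its probabilities are partly
capped at 1, and its background regime is the package's own calibration.
Passing these tests shows the pipeline is implemented correctly, not that
the synthetic desk-scale network quantitatively reproduces mouse CA3.

## Known limitations

* No morphology, no distance-dependent delays, single-compartment neurons,
  one receptor class per synapse.
* No inhibitory long-term plasticity; the only homeostatic event is the
  single divisive downscaling between phases.
* The Treves–Rolls capacity expression is typographically ambiguous in the
  source; `treves_rolls_capacity()` ships one documented interpretation and
  carries no validation weight.
* Interneuron firing rates at desk scale run above the published in vivo
  table; they are reported by `firing_rate_summary()` but not calibrated.
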
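---
title: "Event-driven unsupervised STDP learning: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven unsupervised STDP learning: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpnet)
```

This vignette explains the model `stdpnet` simulates, the assumptions behind
it, the parameters that matter, and the design decisions taken where the
design was genuinely open. The README shows the worked example; here we
focus on *why* the pieces look the way they do.

## The model

### Event-driven dynamics

The simulator has no clock. The network state is a pure function of the
ordered sequence of input events: each event deposits its synaptic weight
into the accumulators of the neurons whose receptive field contains it,
threshold crossings are resolved immediately, and nothing at all happens
between events. Four classical ingredients are deliberately absent —
leak currents, refractory periods, per-stimulus state resets, and
homeostatic rate regulation — because each of them smuggles an absolute
timescale or dataset statistics into the dynamics. With them gone, the
network is *timescale invariant*: rescaling all event times by any positive
constant yields the same spike sequence (at rescaled times) and
bit-identical weights. The test suite asserts this property literally, and
it holds by construction: time is only ever compared, never subtracted.

### Dual accumulators

Winner-take-all competition is essential for feature diversity but starves
higher layers of spikes. Every neuron therefore carries two accumulators
fed by the same input:

* the **learning accumulator** (threshold `t_learn`) drives STDP and WTA.
  Its crossings are "pseudo-spikes": they trigger a weight update and
  inhibition — implemented as a *reset* of the inhibited neurons'
  accumulator, reference time, and active-input set — but propagate
  nothing;
* the **inference accumulator** (threshold `t_infer`) drives propagation.
  Its crossings emit spikes downstream and are subject only to a mild
  inter-map inhibition (radius `r_inh_infer`, default 0 = same position in
  other maps).

Because the learning side never consumes the inference side's charge, a
layer can compete fiercely for features while still emitting a rich spike
code. Disabling the inference inter-map inhibition entirely degrades the
toy-task readout noticeably (the spike code becomes redundant across maps),
which is why `r_inh_infer = 0` means "same position only" rather than
"off"; a negative radius disables it explicitly.

### The plasticity rule

At a pseudo-spike, synapses whose presynaptic neuron fired since the
neuron's last learning reset get `alpha_plus * exp(-beta_plus * w)`; all
others get `alpha_minus * exp(-beta_minus * (1 - w))`; the result is
clipped to `[0, 1]`. Defaults: `alpha_plus / alpha_minus = -8`,
`beta_plus = 3`, `beta_minus = 0` (flat depression). Two properties do the
work:

* the rule is *binary per synapse* — fired-in-window or not — so no STDP
  time constant exists, preserving timescale invariance. The active-input
  set is cleared on every learning reset, including resets received as
  inhibition;
* the damped potentiation crosses the flat depression at
  `w* = -(1/beta_plus) log(-alpha_minus/alpha_plus)` (`crossover_weight()`,
  ≈ 0.69 at the defaults). Above `w*` depression wins, so weights approach
  but do not saturate at 1, and a long balanced alternation of LTP and LTD
  settles near `w*` (a property test asserts within 0.05).

Only the LTP/LTD *ratio* shapes what is learned; the common magnitude sets
learning speed and is a per-layer setting, because deeper layers see far
fewer pseudo-spikes. A `simple = TRUE` toggle removes the exponential
(bare ±alpha increments, still clipped) for hardware-minded experiments.
The un-clipped variant with both dampings is retained through `beta_minus`;
the operative default is the clipped form with flat LTD.

## Parameters at a glance

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `t_learn`, `t_infer` | per layer | accumulator thresholds, in units of summed synaptic weight. Full-scale reference: 8/8 (conv-1), 30/30 (conv-2), 30/30 (fc) |
| `r_inh_learn` | 2 | inter-map learning inhibition radius (Chebyshev, grid positions); 2 covers all neurons whose 5x5 filters overlap the winner's |
| `r_inh_infer` | 0 | inter-map inference inhibition; 0 = same position only, negative = off |
| `alpha_plus` | 0.08 (full scale) | LTP rate; `alpha_minus = -alpha_plus/8` |
| `beta_plus`, `beta_minus` | 3, 0 | weight-dependence damping |
| `init_mean ± init_sd` | 0.8 ± 0.1 conv, 0.67 ± 0.1 fc | initial weights, normal then clipped to `[0,1]` |
| `base_period` | 0.12 | time per spike of a full-intensity pixel (arbitrary units — only ratios matter) |
| `rate_jitter_sd` | 0.1 | relative sd of the per-pixel rate Gaussian |
| `isi_jitter` | on | multiply each inter-spike interval by uniform `[0,1]` (doubles the mean rate) |
| `duration` | 1 (2 for the toy task) | presentation time per stimulus |

The encoder's Gaussian rate perturbation is under-determined by the method
(only "drawn from a Gaussian" is assumed, and results are insensitive to
the exact conversion); we use a relative 10% sd with negative draws clipped
to zero. `base_period = 0.12` is chosen so that a 28x28 digit-like image
with a typical intensity mass (~120 summed pixel values) emits about 2,000
events per presentation, inside the 1,400–3,500 band the standard protocol
assumes; an encoding test checks that band on synthetic 28x28 stimuli.

## Numerical and semantic choices

* **Simultaneous events.** The method itself never defines what happens
  when two events share a timestamp. We impose a total order: time, then
  source layer (input = 0), then map, then row-major position, then
  insertion order. This makes replays deterministic; it is a convention,
  not a claim about the underlying model.
* **Zero propagation delay.** A propagated spike carries the timestamp of
  the event that caused the crossing and is processed before any
  later-timed event. Same-time events at lower layers are drained first
  (see the ordering above).
* **Learning before inference.** When one event pushes both accumulators of
  a neuron over threshold, the learning side (STDP + inhibition) is
  resolved first, then propagation, for the whole layer. The two sides are
  independent, so the order only matters for reproducibility.
* **Crossing resolution.** After each delivered event, the layer is
  re-scanned in address order; each winner is processed and the scan
  restarts, so a neuron inhibited mid-resolution never fires. Since weights
  are ≤ 1 and thresholds ≥ 1, a single event cannot push a neuron two
  thresholds past zero.
* **Inference crossings do not clear the active-input set** — that set
  belongs to the learning side alone.
* **Degenerate inputs.** Empty streams are legal (no spikes, no updates);
  negative or non-finite event times, out-of-geometry addresses, and
  weights outside `[0,1]` are rejected with diagnostics; `beta_plus = 0`
  makes the crossover undefined and errors explicitly.
* **Checkpoints** are JSON (configuration plus full-precision weights) with
  a tidy per-weight CSV export via `tidy()`; both are plain text and
  round-trip losslessly.

## The reference simulator

`run_stream_reference()` is an independent R implementation that steps a
clock over the greatest-common-divisor grid of (integer) event times,
visiting every tick. It shares only the `stdp_update()` arithmetic with the
event kernel; queueing, delivery, and crossing resolution are written
separately. On networks of up to ~50 neurons the two produce identical
spike records and bit-identical weights — this cross-check runs in the test
suite and guards the compiled kernel's bookkeeping.

## The synthetic task: what it emulates, and what it does not

`generate_toy_set()` produces K classes of small grayscale patterns with
the statistical structure the method assumes: class-consistent spatial
features, intensities in `[0,1]` suitable for rate coding, per-instance
±1-pixel translations and clipped Gaussian pixel noise (sd 0.1), balanced
classes, shuffled order. The default task (K = 4, 12x12, 400 train / 100
test) uses hand-drawn digit-like glyphs (a J-hook, 1, 7, 4) chosen so that
any two prototypes share fewer than half of the smaller one's pixels *and*
remain distinguishable at the pooled spatial resolution of the small
network. Earlier drafts used a ring-shaped "0" and a centered "1"; both
were replaced — the ring's enclosed hole cannot be represented by the
pooled-scale feature composite, and a center stroke is indistinguishable
from the "4"'s vertical at that resolution. Alternative programmatic
families (`bars`, `crosses`, `corner-blobs`) support other class counts.

The desk-scale network (`toy_network_config()`) is the reference
architecture shrunk to a 12x12 input: 4 conv maps, 2x2 relay pooling, 20
fully connected neurons. Two adaptations were calibrated once on the
generator's conditions and then frozen. First, the convolution kernel is
3x3 rather than 5x5: a 5-pixel kernel on a 12-pixel image leaves a 4x4
pooled grid too coarse to separate four classes, and the kernel should
scale with the image. Second, thresholds and rates: conv 6/3 (the learning
threshold above the propagation threshold, so each weight update integrates
a receptive-field-sized window of evidence while the spike code stays
dense), fc 20/20, `alpha_plus` 0.03 (conv) and 0.06 (fc) at the fixed -8
ratio — the fully connected layer needs the larger magnitude because its
per-neuron weight columns receive far fewer updates in one pass than the
shared convolution kernels, which accumulate updates from every grid
position. The toy presentation time is 2 time units (~650 events
per stimulus), giving the single pass enough events to converge.

What passing on this task shows: the full pipeline — encoding, simultaneous
multi-layer STDP under the online constraints, spike-count labeling and
classification — recovers planted class structure in one pass at desk
scale, and the ablations (reset-per-example, layer-wise training,
randomized presentation times in `[0.1, 1.9]x`) leave that recovery
essentially unchanged. What it does not show: performance on real
handwritten digits (correlated stroke statistics, heavier class overlap,
10 classes), robustness at 16/32/256-map scale, or behavior over
60,000-stimulus streams. The full-scale protocol is available
(`full_network_config()`, the IDX readers and the command-line runner) but
requires hours of CPU and external data; its headline numbers are not part
of the test suite.

## Feature visualization

`preferred_feature()` composites what a unit prefers back into pixel
space. A first-stage map's preferred feature is its kernel. For deeper
units, each kernel (or fully connected grid) position selects the
lower-layer input channel with the maximum connection strength, scales that
channel's feature by the weight, and places it at *every* pre-pool position
the cell aggregates; overlapping placements are averaged. Placing at all
pooled offsets, rather than only the window's anchor, is the faithful
reading of relay pooling (a pooled cell receives all of them) and
reproduces the translation blur the features actually acquire. The
composite is a visualization, not an inverse: pooled resolution limits what
it can show (enclosed holes, sub-window phase).

## Readout conventions

Responses are spike counts of the top layer inside each stimulus window,
reconstructed from the presentation log that only the experimenter holds.
Labeling credits exactly one neuron per stimulus (ties to the lowest
index); silent stimuli credit nothing. Classification returns the preferred
label of the most active neuron, falling back to the most active *labeled*
neuron, and abstains on all-silent responses; abstentions count as errors.
Labeling and testing run with plasticity frozen — the online running-error
metric is the exception: it labels on the fly during the training pass,
predicting each stimulus before tallying it, and reports the error over a
trailing window (default 1,000 stimuli).

## Known limitations

* Pool layers are pure relays; max-pooling variants are deliberately out of
  scope (they would need an unlock time, breaking timescale invariance).
* The fully connected inference side has no lateral competition; whether it
  should is an open modeling question we resolve as "none" (matching the
  reference parameter set, which lists no fc radius).
* `run_stream()` starts each call with zeroed accumulators; continuing
  state across calls (a truly endless stream) would need the state threaded
  through, which the in-memory API does not currently expose.
* The dense reference simulator requires integer-scalable event times and
  is quadratic-ish in network size; it is a verification tool, not a
  production path.
* Accuracy at desk scale has run-to-run spread of a few points; the toy
  conditions above were chosen so that recovery is robust across seeds, but
  single runs remain stochastic simulations.
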
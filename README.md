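# stdpnet

Event-driven simulation of deep spiking convolutional networks that learn
hierarchical features with **unsupervised STDP in every layer
simultaneously**, from a continuous stream of spike events.

## The problem

Most spiking networks that learn with spike-timing dependent plasticity
(STDP) are still trained like frame-based deep networks: layers are trained
one after another, neuron state is reset between training images, and the
simulation clock, leak and refractory constants are tuned to the stimulus
presentation time. None of that is available to a system that must learn
online from an event-based sensor, where stimuli arrive continuously, at
unknown times, and at unknown timescales.

`stdpnet` implements a network designed for exactly that setting:

* **Dual-accumulator integrate-and-fire neurons.** Each neuron integrates
  every input twice: a *learning* accumulator with threshold
  `T_STDP` whose crossings ("pseudo-spikes") trigger the weight update and
  winner-take-all (WTA) inhibition but are never propagated, and an
  *inference* accumulator with threshold `T_prop` whose crossings propagate
  spikes downstream. Decoupling competition from propagation lets all layers
  train at the same time: inhibition keeps features diverse while the
  inference side still supplies enough spikes to the layers above.
* **WTA inhibition by reset.** A pseudo-spike in a convolutional map resets
  the learning accumulators (value, reference time and active-input set) of
  all other positions of that map, and of all positions within a Chebyshev
  radius `r_STDP` (default 2) in every other map. Propagated spikes reset
  only the inference accumulators at the same position of the other maps
  (`r_prop = 0`). In the fully connected layer the learning competition is
  all-to-all.
* **Bounded exponential STDP.** At each pseudo-spike at time `t_post`,
  every afferent synapse is updated by

      dw = alpha+ * exp(-beta+ * w)    if the presynapse spiked in (t_post,last, t_post]
      dw = alpha- * exp(-beta- * (1-w)) otherwise,

  clipped to `[0, 1]`, with `alpha+ > 0 > alpha-`, `alpha+/alpha- = -8`,
  `beta+ = 3`, `beta- = 0`. There is no STDP time window: a synapse is
  potentiated iff it fired since the neuron's last learning reset.
  Depression overtakes potentiation at the crossover weight
  `w* = -(1/beta+) ln(-alpha-/alpha+) = ln(8)/3 ≈ 0.69`, which keeps weights
  off the bounds and the neuron plastic.
* **Strict online constraints.** No leak, no refractory periods, no resets at
  stimulus boundaries, no homeostasis, no input normalization. Time enters
  the simulation only through event order, so the dynamics are **timescale
  invariant**: multiplying all input event times by any positive constant
  reproduces the identical spike sequence and bit-identical final weights.
* **Rate encoding and a spike-count readout.** Images become noisy periodic
  spike trains with rates proportional to pixel intensity. After training,
  neurons are labeled by the classes they respond to most ("the neuron with
  the highest spike count"), and a test stimulus is classified by the
  preferred label of its most active neuron — labels never touch the
  weights.

The architecture is conv → pool → conv → pool → fully connected; pooling
layers are pure relays over non-overlapping 2x2 windows. The event kernel is
compiled (Rcpp) and a dense time-stepped reference simulator written in
plain R serves as an independent cross-check.

## A worked example

A single unsupervised pass over a desk-scale synthetic task: four classes of
12x12 digit-like glyphs (translated and noisy), rate-encoded into one
continuous event stream, learned by a 4-map convolution + 20-neuron fully
connected network.

```r
library(stdpnet)

res <- run_toy_experiment(seed = 1)
res$fit
#> <stdp_fit> 400 stimuli, 259989 input events
#>   final running error: 0.043
res$eval
#> <stdp_eval> accuracy 100.0% on 100 stimuli (0 abstentions)
glance(res$eval)
#> # A tibble: 1 × 4
#>   accuracy n_test n_abstain n_labeled_neurons
#>      <dbl>  <int>     <int>             <int>
#> 1        1    100         0                15
```

The 400 training glyphs become ~260,000 input events. During the single
training pass the online running error (trailing-window accuracy with
neurons labeled on the fly) falls to 4.3%; the frozen two-pass evaluation —
label neurons on the training stimuli, classify the held-out test stimuli by
spike counts — gets all 100 test stimuli right, with 15 of 20 neurons having
acquired a class label. Per-layer event counts are in
`res$fit$record$counters`; `autoplot(res$fit)` draws the running-error
curve, and `plot_preferred_features(res$fit$network, 3)` shows that the
top-layer neurons have learned class prototypes.

Analytic anchors of the learning rule and architecture:

```r
crossover_weight(stdp_params())                            # 0.6931472
count_adjustable_synapses(full_network_config(16, 256, 1000))  # 4198800
```

The full-scale protocol — a single randomly ordered pass over all 60,000
MNIST digits with the 28x28 reference configuration
(`full_network_config()`), labeling with the training set and testing on the
10,000 test digits — is supported (`read_idx_images()` ingests the standard
IDX files; `inst/scripts/stdpnet` drives train/label/test/sweep/visualize
from the shell) but takes hours of CPU and an externally supplied dataset,
so it is documented rather than run here.

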
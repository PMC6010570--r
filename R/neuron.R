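#' Dual-accumulator integrate-and-fire neuron
#'
#' Each neuron integrates every input it receives into two independent
#' accumulators. The *learning* accumulator drives STDP and winner-take-all
#' competition: crossing its threshold is a "pseudo-spike" that triggers a
#' weight update and lateral inhibition but is never propagated. The
#' *inference* accumulator drives spike propagation and is (largely) exempt
#' from inhibition. There is no leak and no refractory period: between
#' events the state is unchanged regardless of elapsed time, and a neuron
#' may cross threshold on consecutive events.
#'
#' `active_inputs` records which presynaptic addresses fired at least once
#' since the last learning reset (the STDP rule is binary per synapse: a
#' presynapse either spiked inside the window or it did not). Learning
#' resets zero the learning accumulator, stamp the reference time and clear
#' `active_inputs`; inference resets touch only the inference side.
#'
#' These pure R functions document the per-neuron semantics and back the
#' reference simulator and tests; [run_stream()] runs the same dynamics in
#' compiled code.
#'
#' @param t Initial reference time.
#' @return `neuron_state()`: a `neuron_state` object with fields `v_learn`,
#'   `v_infer`, `t_ref_learn`, `t_ref_infer`, `active_inputs`.
#' @examples
#' st <- neuron_state()
#' out <- integrate_neuron(st, w = 0.8, pre = "px:3:4", t = 1,
#'                         thresholds = neuron_thresholds(8, 8))
#' out$state$v_learn
#' @export
neuron_state <- function(t = 0) {
  structure(list(v_learn = 0, v_infer = 0, t_ref_learn = t, t_ref_infer = t,
                 active_inputs = character()),
            class = "neuron_state")
}

#' @describeIn neuron_state Threshold pair for the two accumulators.
#' @param t_learn,t_infer Strictly positive thresholds for the learning and
#'   inference accumulators.
#' @export
neuron_thresholds <- function(t_learn, t_infer = t_learn) {
  if (t_learn <= 0 || t_infer <= 0) abort("thresholds must be strictly positive")
  structure(list(t_learn = t_learn, t_infer = t_infer),
            class = "neuron_thresholds")
}

#' @describeIn neuron_state Integrate one presynaptic spike of weight `w`
#'   into both accumulators. Crossing flags are set when an accumulator
#'   reaches its threshold, but the accumulators are *not* reset here: the
#'   caller orchestrates STDP, inhibition and propagation first.
#' @param state A `neuron_state`.
#' @param w Synaptic weight in `[0, 1]`.
#' @param pre Presynaptic address (any value with a unique string form).
#' @param thresholds A [neuron_thresholds()] object.
#' @export
integrate_neuron <- function(state, w, pre, t, thresholds) {
  stopifnot(inherits(state, "neuron_state"),
            inherits(thresholds, "neuron_thresholds"))
  if (w < 0 || w > 1) abort("synaptic weight must lie in [0, 1]")
  if (t < max(state$t_ref_learn, state$t_ref_infer))
    abort("event time precedes the neuron's reference time")
  state$v_learn <- state$v_learn + w
  state$v_infer <- state$v_infer + w
  state$active_inputs <- union(state$active_inputs, as.character(pre))
  list(state = state,
       learn_crossed = state$v_learn >= thresholds$t_learn,
       infer_crossed = state$v_infer >= thresholds$t_infer)
}

#' @describeIn neuron_state Learning-side reset (own pseudo-spike or WTA
#'   inhibition): zero `v_learn`, stamp `t_ref_learn`, clear
#'   `active_inputs`. Idempotent at the same `t`.
#' @export
reset_learning <- function(state, t) {
  stopifnot(inherits(state, "neuron_state"))
  if (t < state$t_ref_learn) abort("reset time precedes the reference time")
  state$v_learn <- 0
  state$t_ref_learn <- t
  state$active_inputs <- character()
  state
}

#' @describeIn neuron_state Inference-side reset (own propagated spike or
#'   inter-map inference inhibition): zero `v_infer`, stamp `t_ref_infer`.
#'   Leaves the learning accumulator and `active_inputs` untouched.
#' @export
reset_inference <- function(state, t) {
  stopifnot(inherits(state, "neuron_state"))
  if (t < state$t_ref_infer) abort("reset time precedes the reference time")
  state$v_infer <- 0
  state$t_ref_infer <- t
  state
}
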
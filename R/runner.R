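#' Train a network on a continuous event stream
#'
#' The online protocol: a single pass over the stream with all layers
#' plastic simultaneously. The kernel applies no leak, no refractory
#' period, no homeostasis, and no resets at stimulus boundaries — the
#' network never learns where one stimulus ends and the next begins. Two
#' ablations are available: `reset_per_example` wipes all accumulators at
#' every stimulus onset, and `layerwise` trains the layers successively
#' (each trainable layer gets its own full pass over the stream, lower
#' layers frozen after their turn) instead of simultaneously.
#'
#' @param stream A `spike_stream` from [make_stream()].
#' @param network An untrained [build_network()] network.
#' @param reset_per_example Ablation: reset neuron state at stimulus
#'   onsets.
#' @param layerwise Ablation: successive layer-by-layer training.
#' @param window Trailing window (in stimuli) for the online running-error
#'   metric.
#' @return An `stdp_fit`: list with the trained `network`, the training
#'   pass `record`, online `metrics` (see [online_running_error()]),
#'   `counters` and `settings`.
#' @export
train_once <- function(stream, network, reset_per_example = FALSE,
                       layerwise = FALSE, window = 1000) {
  stopifnot(inherits(stream, "spike_stream"), inherits(network, "stdp_network"))
  nl <- length(network$layers)
  trainable <- which(vapply(network$layers, `[[`, "", "kind") != "pool")
  if (layerwise) {
    rec <- NULL
    for (li in trainable) {
      lp <- rep(FALSE, nl)
      lp[li] <- TRUE
      rec <- run_stream(stream, network, layer_plastic = lp,
                        reset_per_example = reset_per_example)
      network <- rec$network
    }
  } else {
    rec <- run_stream(stream, network, plastic = TRUE,
                      reset_per_example = reset_per_example)
    network <- rec$network
  }
  metrics <- NULL
  if (!all(is.na(stream$log$label))) {
    resp <- response_matrix(rec, stream$log)
    metrics <- online_running_error(resp, stream$log$label, window = window)
  }
  structure(
    list(network = network, record = rec, log = stream$log,
         metrics = metrics, counters = rec$counters,
         settings = list(reset_per_example = reset_per_example,
                         layerwise = layerwise, window = window)),
    class = "stdp_fit")
}

#' @export
print.stdp_fit <- function(x, ...) {
  cat(sprintf("<stdp_fit> %d stimuli, %d input events\n",
              nrow(x$log), x$record$n_input_events))
  if (!is.null(x$metrics)) {
    fin <- tail(x$metrics$running_error, 1)
    cat(sprintf("  final running error: %.3f\n", fin))
  }
  invisible(x)
}

#' @rdname train_once
#' @param x An `stdp_fit`.
#' @param ... Unused.
#' @export
tidy.stdp_fit <- function(x, ...) x$metrics

#' @rdname train_once
#' @export
glance.stdp_fit <- function(x, ...) {
  tibble(
    n_stimuli = nrow(x$log),
    n_input_events = x$record$n_input_events,
    n_propagated = nrow(x$record$spikes),
    n_pseudo_spikes = sum(x$counters$pseudo_spikes),
    final_running_error = if (is.null(x$metrics)) NA_real_
                          else tail(x$metrics$running_error, 1),
    layerwise = x$settings$layerwise,
    reset_per_example = x$settings$reset_per_example)
}

#' Evaluate a trained network with the spike-count classifier
#'
#' Two frozen passes (weights untouched): the labeling stimuli assign each
#' top-layer neuron its preferred class by strongest response, then the
#' test stimuli are classified by the preferred label of the neuron that
#' fired the most. Abstentions (no top-layer spike) count as errors.
#'
#' @param object An `stdp_fit` or trained `stdp_network`.
#' @param label_stream A `spike_stream` of labeled stimuli for the
#'   labeling pass.
#' @param test_stream A `spike_stream` for the test pass.
#' @return An `stdp_eval`: list with `accuracy`, per-stimulus
#'   `predictions`, a `confusion` tibble, the label `tally` and the two
#'   response matrices.
#' @export
evaluate_network <- function(object, label_stream, test_stream) {
  network <- if (inherits(object, "stdp_fit")) object$network else object
  stopifnot(inherits(network, "stdp_network"))
  lab_rec <- run_stream(label_stream, network, plastic = FALSE)
  lab_resp <- response_matrix(lab_rec, label_stream$log)
  tally <- tally_labeling_pass(lab_resp, label_stream$log$label)
  test_rec <- run_stream(test_stream, network, plastic = FALSE)
  test_resp <- response_matrix(test_rec, test_stream$log)
  predicted <- classify_responses(test_resp, tally)
  labels <- test_stream$log$label
  predictions <- tibble(stimulus = seq_along(labels), label = labels,
                        predicted = predicted,
                        correct = !is.na(predicted) & predicted == labels)
  confusion <- dplyr::count(predictions, .data$label, .data$predicted,
                            name = "n")
  structure(
    list(accuracy = mean(predictions$correct), predictions = predictions,
         confusion = confusion, tally = tally,
         label_responses = lab_resp, test_responses = test_resp),
    class = "stdp_eval")
}

#' @export
print.stdp_eval <- function(x, ...) {
  cat(sprintf("<stdp_eval> accuracy %.1f%% on %d stimuli (%d abstentions)\n",
              100 * x$accuracy, nrow(x$predictions),
              sum(is.na(x$predictions$predicted))))
  invisible(x)
}

#' @rdname evaluate_network
#' @param x An `stdp_eval`.
#' @param ... Unused.
#' @export
tidy.stdp_eval <- function(x, ...) x$predictions

#' @rdname evaluate_network
#' @export
glance.stdp_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         n_test = nrow(x$predictions),
         n_abstain = sum(is.na(x$predictions$predicted)),
         n_labeled_neurons = sum(!is.na(x$tally$preferred)))
}

#' Run the full toy-task protocol
#'
#' Convenience wrapper over the standard experiment at desk scale:
#' generate the synthetic pattern set, encode it as one continuous stream,
#' train in a single simultaneous pass, then run the frozen labeling and
#' test passes. The training set doubles as the labeling set, mirroring
#' the two-pass evaluation protocol.
#'
#' @param seed Integer seed driving the toy set, weight init and encoding.
#' @param spec A [toy_task_spec()].
#' @param config A [network_config()]; defaults to [toy_network_config()].
#' @param encoder An [encoder_params()].
#' @param reset_per_example,layerwise Ablation flags (see [train_once()]).
#' @param duration_factors Per-stimulus training-duration factors, e.g.
#'   `runif(n, 0.1, 1.9)` drawn internally when
#'   `randomize_durations = TRUE`.
#' @param randomize_durations Draw per-stimulus duration factors uniformly
#'   from `[0.1, 1.9]` for the training stream.
#' @return A list with `fit` (`stdp_fit`), `eval` (`stdp_eval`) and `toy`
#'   (the generated set).
#' @export
run_toy_experiment <- function(seed = 1, spec = toy_task_spec(),
                               config = toy_network_config(),
                               encoder = toy_encoder_params(),
                               reset_per_example = FALSE, layerwise = FALSE,
                               randomize_durations = FALSE,
                               duration_factors = 1) {
  set.seed(seed)
  toy <- generate_toy_set(spec)
  net <- build_network(config)
  if (randomize_durations)
    duration_factors <- runif(nrow(toy$train), 0.1, 1.9)
  train_stream <- make_stream(toy$train, encoder,
                              duration_factors = duration_factors)
  fit <- train_once(train_stream, net, reset_per_example = reset_per_example,
                    layerwise = layerwise)
  label_stream <- make_stream(toy$train, encoder)
  test_stream <- make_stream(toy$test, encoder)
  ev <- evaluate_network(fit, label_stream, test_stream)
  list(fit = fit, eval = ev, toy = toy)
}

#' Sweep the stimulus presentation time
#'
#' Retrains the network for each duration factor and evaluates in two
#' modes: `matched` (labeling and testing at the same factor as training)
#' and `fixed` (labeling and testing at factor 1 regardless of training).
#' Comparing the modes separates feature-learning failures from classifier
#' failures at short presentation times.
#'
#' @param factors Positive multiplicative factors on the presentation time.
#' @param seed Integer seed (re-seeded per factor for comparability).
#' @param modes Subset of `c("matched", "fixed")`.
#' @inheritParams run_toy_experiment
#' @return A tibble with `factor`, `mode`, `accuracy`.
#' @export
presentation_time_sweep <- function(factors, seed = 1, spec = toy_task_spec(),
                                    config = toy_network_config(),
                                    encoder = toy_encoder_params(),
                                    modes = c("matched", "fixed")) {
  stopifnot(all(factors > 0))
  out <- list()
  for (f in factors) {
    set.seed(seed)
    toy <- generate_toy_set(spec)
    net <- build_network(config)
    train_stream <- make_stream(toy$train, encoder, duration_factors = f)
    fit <- train_once(train_stream, net)
    for (mode in modes) {
      ef <- if (mode == "matched") f else 1
      ev <- evaluate_network(
        fit,
        make_stream(toy$train, encoder, duration_factors = ef),
        make_stream(toy$test, encoder, duration_factors = ef))
      out[[length(out) + 1]] <- tibble(factor = f, mode = mode,
                                       accuracy = ev$accuracy)
    }
  }
  bind_rows(out)
}

#' Sweep the learning-rate magnitude
#'
#' Scales the LTP and LTD rates of every layer by a common multiplier
#' (the LTP/LTD ratio is untouched) and reports the online accuracy over
#' the final trailing window of the training pass together with the frozen
#' test accuracy.
#'
#' @param multipliers Positive learning-rate multipliers.
#' @inheritParams presentation_time_sweep
#' @return A tibble with `multiplier`, `online_accuracy`,
#'   `test_accuracy`.
#' @export
learning_rate_sweep <- function(multipliers, seed = 1,
                                spec = toy_task_spec(),
                                config = toy_network_config(),
                                encoder = toy_encoder_params()) {
  stopifnot(all(multipliers > 0))
  out <- list()
  for (m in multipliers) {
    cfg <- config
    cfg$layers <- lapply(cfg$layers, function(ls) {
      if (ls$kind != "pool") {
        ls$stdp$alpha_plus <- ls$stdp$alpha_plus * m
        ls$stdp$alpha_minus <- ls$stdp$alpha_minus * m
      }
      ls
    })
    res <- run_toy_experiment(seed = seed, spec = spec, config = cfg,
                              encoder = encoder)
    mt <- res$fit$metrics
    w <- min(res$fit$settings$window, nrow(mt))
    online_acc <- mean(mt$correct[(nrow(mt) - w + 1):nrow(mt)])
    out[[length(out) + 1]] <- tibble(multiplier = m,
                                     online_accuracy = online_acc,
                                     test_accuracy = res$eval$accuracy)
  }
  bind_rows(out)
}
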
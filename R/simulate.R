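#' Run an event stream through the network
#'
#' The event-driven simulation kernel: input events are integrated in
#' timestamp order (ties broken by layer, then map, then row-major position,
#' then insertion order), threshold crossings are resolved immediately —
#' learning/WTA side first, then propagation — and propagated spikes are
#' inserted with zero delay at the causing event's timestamp, so they are
#' processed before any later-timed event. No state changes occur between
#' events (no leak), nothing resets at stimulus boundaries (unless the
#' reset-per-example ablation is requested), and there is no refractory
#' mechanism. Consequently the dynamics are timescale invariant: multiplying
#' all input times by a positive constant rescales spike times and changes
#' nothing else.
#'
#' @param events A tibble of input events ([spike_events()]) or a
#'   `spike_stream` from [make_stream()] (its presentation log is carried
#'   into the result; the network itself never sees stimulus boundaries).
#' @param network An [build_network()] object.
#' @param plastic Logical: apply STDP updates? `FALSE` freezes all weights
#'   (labeling/testing passes).
#' @param layer_plastic Optional logical vector, one entry per layer, for
#'   layer-wise training protocols. Overrides `plastic`.
#' @param reset_per_example Ablation flag: reset all accumulators at every
#'   stimulus onset (requires a presentation log or `boundaries`).
#' @param boundaries Stimulus onset times for `reset_per_example` when
#'   `events` carries no log.
#' @return A `spike_record`: list with `spikes` (tibble of all propagated
#'   spikes: `time`, `layer`, `map`, `row`, `col`, `kind`), `network` (the
#'   updated network), `counters` (per-layer integration/spike counts),
#'   `state` (final accumulator values), and `log` (if supplied).
#' @examples
#' net <- build_network(toy_network_config(), seed = 1)
#' ev <- spike_events(time = seq(0, 1, by = 0.1), row = 6, col = 6)
#' rec <- run_stream(ev, net)
#' @export
run_stream <- function(events, network, plastic = TRUE, layer_plastic = NULL,
                       reset_per_example = FALSE, boundaries = NULL) {
  log <- NULL
  if (inherits(events, "spike_stream")) {
    log <- events$log
    events <- events$events
  }
  stopifnot(inherits(network, "stdp_network"))
  validate_events(events)
  if (nrow(events) > 0 && any(events$layer != 0))
    abort("input streams must consist of input events (layer 0)")
  if (nrow(events) > 0 &&
      (any(events$row > network$input_side) || any(events$col > network$input_side)))
    abort("input event addresses exceed the network's input geometry")
  events <- events[order(events$time, method = "radix"), ]

  nl <- length(network$layers)
  if (is.null(layer_plastic)) layer_plastic <- rep(isTRUE(plastic), nl)
  stopifnot(length(layer_plastic) == nl)

  if (reset_per_example && is.null(boundaries)) {
    if (is.null(log)) abort("`reset_per_example` needs a presentation log or `boundaries`")
    boundaries <- sort(log$t_start)[-1]
  }
  if (!reset_per_example) boundaries <- numeric(0)

  res <- cpp_run_stream(
    lapply(network$layers, unclass), network$input_side,
    events$time, events$map - 1L, events$row - 1L, events$col - 1L,
    layer_plastic, as.double(boundaries))

  for (i in seq_len(nl)) {
    ls <- network$layers[[i]]
    if (ls$kind == "pool") next
    w <- res$weights[[i]]
    dim(w) <- dim(ls$w)
    network$layers[[i]]$w <- w
  }

  spikes <- tibble(
    time = res$spike_t, layer = res$spike_layer, map = res$spike_map + 1L,
    row = res$spike_row + 1L, col = res$spike_col + 1L, kind = "propagated")

  counters <- tibble(
    layer = seq_len(nl),
    kind = vapply(network$layers, `[[`, "", "kind"),
    integrations = res$integrations,
    pseudo_spikes = res$pseudo_spikes,
    propagated_spikes = res$propagated_spikes)

  structure(
    list(spikes = spikes, network = network, counters = counters,
         state = res$state, log = log, n_input_events = nrow(events),
         boundary_resets = res$boundary_resets),
    class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d input events -> %d propagated spikes\n",
              x$n_input_events, nrow(x$spikes)))
  print(x$counters)
  invisible(x)
}

#' @rdname run_stream
#' @param x A `spike_record`.
#' @param ... Unused.
#' @export
tidy.spike_record <- function(x, ...) x$spikes

#' @rdname run_stream
#' @export
glance.spike_record <- function(x, ...) {
  tibble(
    n_input_events = x$n_input_events,
    n_propagated = nrow(x$spikes),
    n_pseudo_spikes = sum(x$counters$pseudo_spikes),
    n_integrations = sum(x$counters$integrations),
    boundary_resets = x$boundary_resets)
}
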
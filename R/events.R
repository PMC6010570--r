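#' Construct a table of spike events
#'
#' Events are the sole carriers of time in the simulator: a timestamped
#' address, either an input pixel (`layer = 0`) or a neuron in a network
#' layer. The network has no clock; nothing happens between events.
#'
#' @param time Non-negative, finite event times (arbitrary units).
#' @param layer Source layer index: 0 for input pixels, `i` for the i-th
#'   network layer.
#' @param map Map (input channel / neural map / fc neuron) index, 1-based.
#' @param row,col Grid position, 1-based.
#' @param kind `"input"` or `"propagated"`.
#' @return A tibble with columns `time`, `layer`, `map`, `row`, `col`,
#'   `kind`.
#' @examples
#' spike_events(time = c(0, 0.5), row = c(1, 2), col = c(1, 1))
#' @export
spike_events <- function(time, layer = 0L, map = 1L, row, col,
                         kind = "input") {
  ev <- tibble(time = as.double(time), layer = as.integer(layer),
               map = as.integer(map), row = as.integer(row),
               col = as.integer(col), kind = as.character(kind))
  validate_events(ev)
  ev
}

validate_events <- function(events) {
  req <- c("time", "layer", "map", "row", "col")
  if (!all(req %in% names(events)))
    abort(paste("events need columns:", paste(req, collapse = ", ")))
  if (nrow(events) == 0) return(invisible(events))
  if (any(!is.finite(events$time)) || any(events$time < 0))
    abort("event times must be finite and non-negative")
  if (any(events$map < 1) || any(events$row < 1) || any(events$col < 1))
    abort("event addresses must be positive (1-based)")
  invisible(events)
}

#' A deterministic total-order event queue
#'
#' Pending events pop in non-decreasing time order; ties are broken by
#' (layer ascending, map, row-major position, insertion order), so replaying
#' a stream is fully deterministic. This R-level queue backs the reference
#' simulator and replay tooling; [run_stream()] uses an equivalent compiled
#' queue internally.
#'
#' @return An empty `event_queue`.
#' @examples
#' q <- event_queue()
#' q <- push_event(q, spike_events(time = 2, row = 1, col = 1))
#' q <- push_event(q, spike_events(time = 1, row = 3, col = 1))
#' pop_event(q)$event$time  # 1
#' @export
event_queue <- function() {
  q <- tibble(time = double(), layer = integer(), map = integer(),
              row = integer(), col = integer(), kind = character(),
              .seq = integer())
  structure(q, class = c("event_queue", class(q)), next_seq = 1L)
}

#' @describeIn event_queue Insert events (validated; a negative time or
#'   non-positive address is rejected with a diagnostic).
#' @param queue An `event_queue`.
#' @param events A tibble of events as produced by [spike_events()].
#' @export
push_event <- function(queue, events) {
  stopifnot(inherits(queue, "event_queue"))
  validate_events(events)
  s0 <- attr(queue, "next_seq")
  events$.seq <- seq.int(s0, length.out = nrow(events))
  out <- bind_rows(as_tibble(queue), events[names(queue)])
  structure(out, class = class(queue),
            next_seq = s0 + nrow(events))
}

#' @describeIn event_queue Remove and return the next event. Returns
#'   `list(event = <tibble row or NULL>, queue = <remaining queue>)`.
#' @export
pop_event <- function(queue) {
  stopifnot(inherits(queue, "event_queue"))
  if (nrow(queue) == 0) return(list(event = NULL, queue = queue))
  ord <- order(queue$time, queue$layer, queue$map, queue$row, queue$col,
               queue$.seq, method = "radix")
  i <- ord[1]
  ev <- as_tibble(queue)[i, setdiff(names(queue), ".seq")]
  rest <- structure(as_tibble(queue)[-i, ], class = class(queue),
                    next_seq = attr(queue, "next_seq"))
  list(event = ev, queue = rest)
}

#' Read or write an event stream as CSV
#'
#' The address-event CSV has header `time,layer,map,row,col,kind` and stores
#' times with full double precision, so a written stream replays losslessly.
#'
#' @param events A tibble of events.
#' @param path File path.
#' @return `read_events_csv()` returns the event tibble;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events)
  df <- as.data.frame(events[, c("time", "layer", "map", "row", "col", "kind")])
  df$time <- sprintf("%.17g", df$time)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, colClasses = c(time = "numeric", layer = "integer",
                                      map = "integer", row = "integer",
                                      col = "integer", kind = "character"))
  validate_events(as_tibble(df))
}
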
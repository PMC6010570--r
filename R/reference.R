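# Dense time-stepped reference simulator.
#
# Independent oracle for the event-driven kernel: instead of jumping from
# event to event, it advances a clock over a regular grid whose step is the
# greatest common divisor of the (integer) event times, visiting every grid
# tick whether or not anything happens there. Written in plain R with naive
# scans; intended for networks of up to a few dozen neurons.

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)

.ref_layer_init <- function(ls) {
  st <- list()
  if (ls$kind == "conv") {
    S <- ls$out_side
    st$VL <- array(0, dim = c(S, S, ls$maps))
    st$VI <- array(0, dim = c(S, S, ls$maps))
    st$ACT <- array(FALSE, dim = c(ls$kernel, ls$kernel, ls$in_maps, S, S, ls$maps))
  } else if (ls$kind == "fc") {
    nin <- ls$in_side^2 * ls$in_maps
    st$VL <- numeric(ls$maps)
    st$VI <- numeric(ls$maps)
    st$ACT <- matrix(FALSE, nrow = nin, ncol = ls$maps)
  }
  st
}

#' Dense time-stepped reference simulation
#'
#' Reference implementation of [run_stream()] for cross-checking: a clocked
#' simulator stepping at the greatest common divisor of the event times.
#' Event times must be non-negative integers (after division by `unit`).
#' Only the default protocol is supported (all layers plastic or frozen, no
#' per-example resets). Slow by design; use on small networks.
#'
#' @inheritParams run_stream
#' @param unit Optional time unit; times divided by `unit` must be integers.
#' @return A list with `spikes` (tibble, same format and order as
#'   [run_stream()]) and `network` (updated weights).
#' @export
run_stream_reference <- function(events, network, plastic = TRUE, unit = 1) {
  if (inherits(events, "spike_stream")) events <- events$events
  validate_events(events)
  it <- events$time / unit
  if (any(abs(it - round(it)) > 1e-9))
    abort("the reference simulator needs integer event times (after `unit`)")
  it <- as.integer(round(it))

  layers <- network$layers
  nl <- length(layers)
  states <- lapply(layers, .ref_layer_init)
  rec <- list()

  # grid step: gcd of all positive event times
  pos <- unique(it[it > 0])
  dt <- if (length(pos) == 0) 1L else Reduce(.gcd2, pos)
  tmax <- if (nrow(events) == 0) -1L else max(it)

  ev <- events[order(it, method = "radix"), ]
  ev_it <- sort(it)

  emit <- function(t, layer, map, row, col) {
    rec[[length(rec) + 1]] <<- c(t, layer, map, row, col)
  }

  # deliver one item into layer `li`; returns nothing, mutates states
  deliver_ref <- function(li, im, ix, iy) {
    ls <- layers[[li]]
    st <- states[[li]]
    if (ls$kind == "conv") {
      k <- ls$kernel; s <- ls$stride; S <- ls$out_side
      for (orow in seq_len(S)) {
        kx <- ix - (orow - 1) * s
        if (kx < 1 || kx > k) next
        for (ocol in seq_len(S)) {
          ky <- iy - (ocol - 1) * s
          if (ky < 1 || ky > k) next
          wv <- ls$w[kx, ky, im, ]
          st$VL[orow, ocol, ] <- st$VL[orow, ocol, ] + wv
          st$VI[orow, ocol, ] <- st$VI[orow, ocol, ] + wv
          st$ACT[kx, ky, im, orow, ocol, ] <- TRUE
        }
      }
    } else {
      flat <- ((im - 1) * ls$in_side + (ix - 1)) * ls$in_side + iy
      st$VL <- st$VL + ls$w[flat, ]
      st$VI <- st$VI + ls$w[flat, ]
      st$ACT[flat, ] <- TRUE
    }
    states[[li]] <<- st
  }

  # find the first learning/inference crossing in scan order, or NULL
  first_crossing <- function(li, side) {
    ls <- layers[[li]]
    st <- states[[li]]
    v <- if (side == "learn") st$VL else st$VI
    thr <- if (side == "learn") ls$t_learn else ls$t_infer
    if (ls$kind == "fc") {
      idx <- which(v >= thr)
      if (length(idx) == 0) return(NULL)
      return(list(map = min(idx), row = 1L, col = 1L))
    }
    S <- ls$out_side
    for (m in seq_len(ls$maps))
      for (r in seq_len(S))
        for (cl in seq_len(S))
          if (v[r, cl, m] >= thr) return(list(map = m, row = r, col = cl))
    NULL
  }

  resolve_ref <- function(li, t) {
    ls <- layers[[li]]
    emitted <- list()
    repeat {  # learning side
      win <- first_crossing(li, "learn")
      if (is.null(win)) break
      st <- states[[li]]
      if (ls$kind == "conv") {
        m <- win$map
        if (plastic) {
          layers[[li]]$w[, , , m] <<-
            stdp_update(as.vector(ls$w[, , , m]),
                        as.vector(st$ACT[, , , win$row, win$col, m]),
                        ls$stdp)
          ls <- layers[[li]]
        }
        st$VL[, , m] <- 0
        st$ACT[, , , , , m] <- FALSE
        S <- ls$out_side
        r <- ls$r_inh_learn
        rows <- max(1, win$row - r):min(S, win$row + r)
        cols <- max(1, win$col - r):min(S, win$col + r)
        for (m2 in setdiff(seq_len(ls$maps), m)) {
          st$VL[rows, cols, m2] <- 0
          st$ACT[, , , rows, cols, m2] <- FALSE
        }
      } else {
        if (plastic) {
          layers[[li]]$w[, win$map] <<-
            stdp_update(ls$w[, win$map], st$ACT[, win$map], ls$stdp)
          ls <- layers[[li]]
        }
        st$VL[] <- 0
        st$ACT[] <- FALSE
      }
      states[[li]] <<- st
    }
    repeat {  # inference side
      win <- first_crossing(li, "infer")
      if (is.null(win)) break
      st <- states[[li]]
      emit(t, li, win$map, win$row, win$col)
      emitted[[length(emitted) + 1]] <- win
      if (ls$kind == "conv") {
        st$VI[win$row, win$col, win$map] <- 0
        ri <- ls$r_inh_infer
        if (!is.null(ri) && ri >= 0) {
          S <- ls$out_side
          rows <- max(1, win$row - ri):min(S, win$row + ri)
          cols <- max(1, win$col - ri):min(S, win$col + ri)
          for (m2 in setdiff(seq_len(ls$maps), win$map))
            st$VI[rows, cols, m2] <- 0
        }
      } else {
        st$VI[win$map] <- 0
      }
      states[[li]] <<- st
    }
    emitted
  }

  ei <- 1L
  for (step in 0:max(0, tmax %/% dt)) {
    t_int <- step * dt
    if (t_int > tmax) break
    # same-time agenda: (layer, map, row, col, seq) ascending; input events
    # (layer 0) come first among equal times because their layer is lowest
    agenda <- list()
    while (ei <= nrow(ev) && ev_it[ei] == t_int) {
      agenda[[length(agenda) + 1]] <-
        list(layer = 0L, map = ev$map[ei], row = ev$row[ei], col = ev$col[ei],
             seq = ei)
      ei <- ei + 1L
    }
    nseq <- nrow(ev) + 1L
    while (length(agenda) > 0) {
      keys <- vapply(agenda, function(a)
        c(a$layer, a$map, a$row, a$col, a$seq), numeric(5))
      pick <- do.call(order, as.data.frame(t(keys)))[1]
      a <- agenda[[pick]]
      agenda[[pick]] <- NULL
      tl <- a$layer + 1L
      if (tl > nl) next
      ls <- layers[[tl]]
      tt <- t_int * unit
      if (ls$kind == "pool") {
        pr <- pool_route(a$row, a$col, ls$window)
        emit(tt, tl, a$map, pr[1], pr[2])
        agenda[[length(agenda) + 1]] <-
          list(layer = tl, map = a$map, row = pr[1], col = pr[2], seq = nseq)
        nseq <- nseq + 1L
      } else {
        deliver_ref(tl, a$map, a$row, a$col)
        for (w in resolve_ref(tl, tt)) {
          agenda[[length(agenda) + 1]] <-
            list(layer = tl, map = w$map, row = w$row, col = w$col, seq = nseq)
          nseq <- nseq + 1L
        }
      }
    }
  }

  spikes <- if (length(rec) == 0) {
    tibble(time = double(), layer = integer(), map = integer(),
           row = integer(), col = integer(), kind = character())
  } else {
    m <- do.call(rbind, rec)
    tibble(time = m[, 1], layer = as.integer(m[, 2]), map = as.integer(m[, 3]),
           row = as.integer(m[, 4]), col = as.integer(m[, 5]),
           kind = "propagated")
  }
  network$layers <- layers
  list(spikes = spikes, network = network)
}
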
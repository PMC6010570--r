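#' Per-stimulus spike-count responses
#'
#' Counts, for every stimulus window in the presentation log, the spikes
#' each neuron of a layer propagated. The "response" of a neuron to a
#' stimulus is its inference spike count inside the stimulus window,
#' reconstructed after the fact from the log — the network itself never
#' receives stimulus boundaries.
#'
#' @param record A `spike_record` from [run_stream()] (must carry a log, or
#'   pass one via `log`).
#' @param log A presentation log tibble (`stimulus`, `label`, `t_start`,
#'   `duration`).
#' @param layer Layer index to read out; defaults to the last layer.
#' @return A matrix of spike counts, stimuli in rows, neurons in columns,
#'   with the stimulus labels as a `"labels"` attribute.
#' @export
response_matrix <- function(record, log = NULL, layer = NULL) {
  stopifnot(inherits(record, "spike_record"))
  if (is.null(log)) log <- record$log
  if (is.null(log)) abort("no presentation log available")
  if (is.null(layer)) layer <- length(record$network$layers)
  ls <- record$network$layers[[layer]]
  n_neuron <- if (ls$kind == "fc") ls$maps else ls$maps * ls$out_side^2
  sp <- record$spikes[record$spikes$layer == layer, ]
  n_stim <- nrow(log)
  out <- matrix(0L, nrow = n_stim, ncol = n_neuron)
  if (nrow(sp) > 0) {
    brk <- c(log$t_start, log$t_start[n_stim] + log$duration[n_stim])
    stim <- findInterval(sp$time, brk, rightmost.closed = FALSE)
    keep <- stim >= 1 & stim <= n_stim & sp$time < brk[n_stim + 1]
    neuron <- if (ls$kind == "fc") sp$map
              else ((sp$map - 1) * ls$out_side + (sp$row - 1)) * ls$out_side + sp$col
    tab <- table(factor(stim[keep], levels = seq_len(n_stim)),
                 factor(neuron[keep], levels = seq_len(n_neuron)))
    out <- matrix(as.integer(tab), nrow = n_stim, ncol = n_neuron)
  }
  attr(out, "labels") <- log$label
  out
}

#' @rdname response_matrix
#' @return `stimulus_responses()`: the same counts as a long tibble
#'   (`stimulus`, `label`, `neuron`, `spikes`).
#' @export
stimulus_responses <- function(record, log = NULL, layer = NULL) {
  m <- response_matrix(record, log, layer)
  labs <- attr(m, "labels")
  tibble(stimulus = rep(seq_len(nrow(m)), ncol(m)),
         label = rep(labs, ncol(m)),
         neuron = rep(seq_len(ncol(m)), each = nrow(m)),
         spikes = as.integer(m))
}

#' Label neurons by their strongest responses
#'
#' One labeling pass over a labeled stimulus set: for every stimulus,
#' exactly the neuron with the highest response (ties broken by the lowest
#' neuron index) is credited with the stimulus label. A stimulus to which
#' no neuron responded contributes nothing. A neuron's preferred label is
#' the class it was credited most often (ties to the lowest class index);
#' neurons never credited stay unlabeled. Labels influence only this
#' interpretation of the neurons — never the learned weights.
#'
#' @param responses A stimuli-by-neurons count matrix
#'   ([response_matrix()]).
#' @param labels Per-stimulus class labels (defaults to the matrix's
#'   `"labels"` attribute).
#' @return A `label_tally`: list with `counts` (neurons x classes),
#'   `preferred` (per-neuron class or `NA`), `classes`, and `n_silent`
#'   (stimuli with all-zero response).
#' @export
tally_labeling_pass <- function(responses, labels = NULL) {
  if (is.null(labels)) labels <- attr(responses, "labels")
  stopifnot(nrow(responses) == length(labels))
  classes <- sort(unique(labels))
  counts <- matrix(0L, nrow = ncol(responses), ncol = length(classes),
                   dimnames = list(NULL, as.character(classes)))
  n_silent <- 0L
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    if (all(r == 0)) { n_silent <- n_silent + 1L; next }
    win <- which.max(r)  # lowest index on ties
    k <- match(labels[i], classes)
    counts[win, k] <- counts[win, k] + 1L
  }
  preferred <- apply(counts, 1, function(x)
    if (sum(x) == 0) NA_integer_ else which.max(x))
  structure(list(counts = counts,
                 preferred = classes[preferred],
                 classes = classes, n_silent = n_silent),
            class = "label_tally")
}

#' @export
print.label_tally <- function(x, ...) {
  cat(sprintf("<label_tally> %d neurons, %d classes, %d labeled, %d silent stimuli\n",
              nrow(x$counts), length(x$classes),
              sum(!is.na(x$preferred)), x$n_silent))
  invisible(x)
}

#' Spike-count classification
#'
#' Predicts the preferred label of the neuron that fired the most (ties to
#' the lowest index). If that neuron is unlabeled, falls back to the
#' labeled neuron with the highest response. An all-zero response abstains
#' (`NA`), which downstream accuracy counts as incorrect.
#'
#' @param responses A stimuli-by-neurons count matrix (or a single response
#'   vector).
#' @param tally A [tally_labeling_pass()] result with at least one labeled
#'   neuron.
#' @return Predicted class per stimulus (`NA` = abstain).
#' @export
classify_responses <- function(responses, tally) {
  stopifnot(inherits(tally, "label_tally"))
  if (all(is.na(tally$preferred))) abort("the tally has no labeled neuron")
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  labeled <- which(!is.na(tally$preferred))
  apply(responses, 1, function(r) {
    if (all(r == 0)) return(tally$classes[NA_integer_])
    win <- which.max(r)
    if (!is.na(tally$preferred[win])) return(tally$preferred[win])
    lw <- labeled[which.max(r[labeled])]
    tally$preferred[lw]
  })
}

#' Classification accuracy with abstentions counted as errors
#'
#' @param predicted Predictions from [classify_responses()].
#' @param labels True labels.
#' @return Fraction correct.
#' @export
classification_accuracy <- function(predicted, labels) {
  mean(!is.na(predicted) & predicted == labels)
}

#' Test accuracy as a function of the labeled fraction
#'
#' Rebuilds the label tally from random subsets of the labeling stimuli and
#' evaluates the spike-count classifier on a fixed held-out set — the
#' label-efficiency curve of the unsupervised readout. Fraction 1
#' reproduces the full-tally accuracy.
#'
#' @param label_responses,label_labels Responses and labels of the labeling
#'   pass.
#' @param test_responses,test_labels Held-out responses and labels.
#' @param fractions Label fractions in (0, 1].
#' @param seed Optional seed for the subset draws.
#' @return A tibble with `fraction`, `n_labels`, `accuracy`.
#' @export
label_efficiency_curve <- function(label_responses, label_labels,
                                   test_responses, test_labels,
                                   fractions = c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                                   seed = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    abort("fractions must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(fractions, function(f) {
    n <- nrow(label_responses)
    idx <- if (f >= 1) seq_len(n) else sort(sample.int(n, max(1, round(f * n))))
    tally <- tally_labeling_pass(label_responses[idx, , drop = FALSE],
                                 label_labels[idx])
    acc <- if (all(is.na(tally$preferred))) 0 else
      classification_accuracy(classify_responses(test_responses, tally),
                              test_labels)
    tibble(fraction = f, n_labels = length(idx), accuracy = acc)
  })
}

#' Online running error during a training pass
#'
#' Labels neurons on the fly: each stimulus is first classified with the
#' tally accumulated so far (errors include abstentions and the cold start
#' before any neuron is labeled), then its true label is tallied. The
#' running error is the error fraction over the trailing `window` stimuli.
#'
#' @param responses Stimuli-by-neurons counts of a training pass, in
#'   presentation order.
#' @param labels True labels in presentation order.
#' @param window Trailing window length.
#' @return A tibble with `stimulus`, `label`, `predicted`, `correct`,
#'   `running_error`.
#' @export
online_running_error <- function(responses, labels = NULL, window = 1000) {
  if (is.null(labels)) labels <- attr(responses, "labels")
  n <- nrow(responses)
  classes <- sort(unique(labels))
  counts <- matrix(0L, nrow = ncol(responses), ncol = length(classes))
  predicted <- rep(classes[NA_integer_], n)
  correct <- logical(n)
  preferred <- rep(NA_integer_, ncol(responses))
  for (i in seq_len(n)) {
    r <- responses[i, ]
    labeled <- which(!is.na(preferred))
    if (any(r > 0) && length(labeled) > 0) {
      win <- which.max(r)
      p <- if (!is.na(preferred[win])) preferred[win]
           else preferred[labeled[which.max(r[labeled])]]
      predicted[i] <- classes[p]
    }
    correct[i] <- !is.na(predicted[i]) && predicted[i] == labels[i]
    if (any(r > 0)) {
      win <- which.max(r)
      k <- match(labels[i], classes)
      counts[win, k] <- counts[win, k] + 1L
      preferred[win] <- which.max(counts[win, ])
    }
  }
  err <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - window + 1)
    mean(!correct[lo:i])
  }, numeric(1))
  tibble(stimulus = seq_len(n), label = labels, predicted = predicted,
         correct = correct, running_error = err)
}

#' Preferred input-space feature of a neuron or map
#'
#' Visualizes what a unit has learned, composited back into image
#' coordinates. A first-stage convolutional map's preferred feature is its
#' own kernel. For deeper units, each kernel position recursively
#' substitutes the lower-layer feature with the maximum connection
#' strength, placed at its receptive-field location and scaled by that
#' connection weight; overlapping placements are averaged.
#'
#' @param network A trained `stdp_network`.
#' @param layer Layer index (conv or fc; pooling layers delegate to the
#'   layer below).
#' @param unit Map index (conv) or neuron index (fc).
#' @return A matrix in input-pixel coordinates.
#' @export
preferred_feature <- function(network, layer, unit) {
  stopifnot(inherits(network, "stdp_network"))
  geo <- .layer_geometry(network)
  .pf(network, layer, unit, geo)
}

# receptive-field arithmetic per layer: the step of the *input* grid in
# input pixels, and the step between adjacent output positions
.layer_geometry <- function(network) {
  step <- 1   # input grid of layer 1 = raw pixels
  geo <- vector("list", length(network$layers))
  for (i in seq_along(network$layers)) {
    ls <- network$layers[[i]]
    geo[[i]] <- list(in_step = step)
    if (ls$kind == "conv") {
      step <- step * ls$stride
    } else if (ls$kind == "pool") {
      step <- step * ls$window
    }
    geo[[i]]$out_step <- step
  }
  geo
}

.pf <- function(network, layer, unit, geo) {
  ls <- network$layers[[layer]]
  if (ls$kind == "pool") {
    below <- .prev_featured(network, layer)
    return(.pf(network, below, unit, geo))
  }
  if (ls$kind == "conv" && layer == 1)
    return(ls$w[, , 1, unit])
  below <- .prev_featured(network, layer)
  # pooling factor between the featured layer below and this one: one input
  # cell here aggregates pw x pw output positions of the layer below
  pw <- 1L
  js <- seq_len(layer - 1)
  for (j in js[js > below])
    if (network$layers[[j]]$kind == "pool") pw <- pw * network$layers[[j]]$window
  ob <- geo[[below]]$out_step   # pixel step between the below layer's units

  weight_at <- function(x, y, im) {
    if (ls$kind == "conv") ls$w[x, y, im, unit]
    else ls$w[((im - 1) * ls$in_side + (x - 1)) * ls$in_side + y, unit]
  }
  ncell <- if (ls$kind == "conv") ls$kernel else ls$in_side
  child0 <- .pf(network, below, 1, geo)
  side <- ((ncell * pw - 1L)) * ob + nrow(child0)
  canvas <- matrix(0, side, side)
  count <- matrix(0, side, side)
  children <- lapply(seq_len(ls$in_maps), function(im)
    .pf(network, below, im, geo))
  for (x in seq_len(ncell)) {
    for (y in seq_len(ncell)) {
      ww <- vapply(seq_len(ls$in_maps), function(im) weight_at(x, y, im),
                   numeric(1))
      im <- which.max(ww)
      child <- children[[im]] * ww[im]
      # composite at every pre-pool position this input cell aggregates
      for (jx in seq_len(pw)) {
        for (jy in seq_len(pw)) {
          r0 <- ((x - 1L) * pw + jx - 1L) * ob
          c0 <- ((y - 1L) * pw + jy - 1L) * ob
          rows <- r0 + seq_len(nrow(child))
          cols <- c0 + seq_len(ncol(child))
          rows <- rows[rows <= side]
          cols <- cols[cols <= side]
          canvas[rows, cols] <- canvas[rows, cols] +
            child[seq_along(rows), seq_along(cols)]
          count[rows, cols] <- count[rows, cols] + 1
        }
      }
    }
  }
  canvas / pmax(count, 1)
}

.prev_featured <- function(network, layer) {
  i <- layer - 1
  while (i >= 1 && network$layers[[i]]$kind == "pool") i <- i - 1
  if (i < 1) abort("no featured layer below")
  i
}
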
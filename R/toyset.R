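# Synthetic multi-class pattern tasks: desk-scale stand-ins for MNIST with
# the statistical structure the method assumes — K classes of small
# grayscale patterns, rate-codable, with class-consistent features.

.glyph <- function(rows) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(r) as.numeric(r == "#")))
  m
}

# 8x8 binary digit-like glyphs (J, 1, 7, 4) — drawn so that any two glyphs
# share fewer than half of the smaller glyph's pixels, and so that every
# glyph keeps a distinct coarse (pooled-scale) footprint
.mini_digits <- function() {
  list(
    .glyph(c("....###.",
             "......#.",
             "......#.",
             "......#.",
             "......#.",
             "......#.",
             ".#....#.",
             "..####..")),
    .glyph(c("#.......",
             "##......",
             "#.......",
             "#.......",
             "#.......",
             "#.......",
             "#.......",
             "##......")),
    .glyph(c(".######.",
             "......#.",
             ".....#..",
             "....#...",
             "...#....",
             "...#....",
             "..#.....",
             "..#.....")),
    .glyph(c("....#...",
             "...##...",
             "..#.#...",
             ".#..#...",
             ".######.",
             "....#...",
             "....#...",
             "....#..."))
  )
}

#' Class prototype patterns for the synthetic tasks
#'
#' Four pattern families are available: hand-drawn binary `mini-digits`
#' (digit-like glyphs, up to 4 classes), `bars` (thick bars of alternating
#' orientation at spread positions), `crosses` (plus shapes at distinct
#' positions) and `corner-blobs` (square blobs in distinct corners/centers).
#' Prototypes are validated to be pairwise distinct: the pixel overlap of
#' any two prototypes (relative to the smaller one) must stay below 50%.
#'
#' @param family Pattern family.
#' @param classes Number of classes K (>= 2).
#' @param side Image side length n (>= 8).
#' @return A list of `side` x `side` matrices with values in `[0, 1]`.
#' @examples
#' protos <- toy_prototypes("mini-digits", classes = 4, side = 12)
#' @export
toy_prototypes <- function(family = c("mini-digits", "bars", "crosses",
                                      "corner-blobs"),
                           classes = 4, side = 12) {
  family <- match.arg(family)
  if (classes < 2) abort("at least 2 classes are required")
  if (side < 8) abort("side length must be at least 8")
  place <- function(glyph, side) {
    scale <- max(1L, (side - 4L) %/% 8L)
    g <- kronecker(glyph, matrix(1, scale, scale))
    out <- matrix(0, side, side)
    off <- (side - nrow(g)) %/% 2
    out[off + seq_len(nrow(g)), off + seq_len(ncol(g))] <- g
    out
  }
  protos <- switch(family,
    "mini-digits" = {
      if (classes > 4) abort("the mini-digit family provides at most 4 classes")
      lapply(.mini_digits()[seq_len(classes)], place, side = side)
    },
    "bars" = lapply(seq_len(classes), function(i) {
      m <- matrix(0, side, side)
      th <- max(2L, side %/% 6L)
      pos <- 2 + round((i - 1) / max(1, classes - 1) * (side - th - 3))
      if (i %% 2 == 1) m[pos:(pos + th - 1), 2:(side - 1)] <- 1
      else m[2:(side - 1), pos:(pos + th - 1)] <- 1
      m
    }),
    "crosses" = lapply(seq_len(classes), function(i) {
      m <- matrix(0, side, side)
      th <- max(1L, side %/% 8L)
      arm <- side %/% 4L
      cx <- if (i %% 2 == 1) arm + 2 else side - arm - 1
      cy <- if (i <= 2) arm + 2 else side - arm - 1
      m[max(1, cx - arm):min(side, cx + arm),
        max(1, cy - th + 1):min(side, cy + th - 1)] <- 1
      m[max(1, cx - th + 1):min(side, cx + th - 1),
        max(1, cy - arm):min(side, cy + arm)] <- 1
      m
    }),
    "corner-blobs" = lapply(seq_len(classes), function(i) {
      m <- matrix(0, side, side)
      b <- max(3L, side %/% 3L)
      corners <- list(c(2, 2), c(2, side - b), c(side - b, 2),
                      c(side - b, side - b), c((side - b) %/% 2, (side - b) %/% 2))
      if (i > length(corners)) abort("too many classes for corner blobs")
      cc <- corners[[i]]
      m[cc[1]:(cc[1] + b - 1), cc[2]:(cc[2] + b - 1)] <- 1
      m
    })
  )
  .check_proto_overlap(protos)
  protos
}

.check_proto_overlap <- function(protos) {
  for (i in seq_along(protos)) {
    for (j in seq_along(protos)) {
      if (j <= i) next
      a <- protos[[i]] > 0.5
      b <- protos[[j]] > 0.5
      ov <- sum(a & b) / min(sum(a), sum(b))
      if (ov >= 0.5)
        abort(sprintf("prototypes %d and %d overlap by %.0f%% (>= 50%%)",
                      i, j, 100 * ov))
    }
  }
  invisible(TRUE)
}

#' Specify a synthetic pattern-recognition task
#'
#' @param classes Number of classes K.
#' @param side Image side length.
#' @param family Pattern family (see [toy_prototypes()]).
#' @param noise_sd Per-pixel additive Gaussian noise (clipped to `[0, 1]`).
#' @param jitter Maximum per-instance translation in pixels (each instance
#'   is shifted by integers drawn uniformly from `-jitter..jitter` on both
#'   axes).
#' @param n_train,n_test Training/test set sizes (balanced classes).
#' @return A `toy_task_spec` object.
#' @export
toy_task_spec <- function(classes = 4, side = 12, family = "mini-digits",
                          noise_sd = 0.1, jitter = 1,
                          n_train = 400, n_test = 100) {
  if (classes < 2) abort("K must be >= 2")
  if (side < 8) abort("side must be >= 8")
  structure(list(classes = classes, side = side, family = family,
                 noise_sd = noise_sd, jitter = jitter,
                 n_train = n_train, n_test = n_test),
            class = "toy_task_spec")
}

#' Generate a labeled synthetic image set
#'
#' Each instance is its class prototype, translated by a small random
#' integer shift and perturbed by clipped Gaussian pixel noise. Classes are
#' balanced and presentation order is shuffled. Reproducible under a fixed
#' seed.
#'
#' @param spec A [toy_task_spec()].
#' @param seed Optional integer seed.
#' @return A list with tibbles `train` and `test`, each with list-column
#'   `image` and integer column `label` (1..K), plus `prototypes`.
#' @examples
#' toy <- generate_toy_set(toy_task_spec(n_train = 8, n_test = 4), seed = 1)
#' @export
generate_toy_set <- function(spec = toy_task_spec(), seed = NULL) {
  stopifnot(inherits(spec, "toy_task_spec"))
  if (!is.null(seed)) set.seed(seed)
  protos <- toy_prototypes(spec$family, spec$classes, spec$side)
  draw <- function(n) {
    labels <- sample(rep_len(seq_len(spec$classes), n))
    images <- lapply(labels, function(k) {
      img <- protos[[k]]
      if (spec$jitter > 0) {
        sh <- sample(seq(-spec$jitter, spec$jitter), 2, replace = TRUE)
        img <- .shift_matrix(img, sh[1], sh[2])
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                            nrow(img), ncol(img))
      img[] <- pmin(1, pmax(0, img))
      img
    })
    tibble(image = images, label = as.integer(labels))
  }
  list(train = draw(spec$n_train), test = draw(spec$n_test),
       prototypes = protos, spec = spec)
}

.shift_matrix <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Default desk-scale network and encoder for the toy task
#'
#' A 4-map 3x3/stride-1 convolution stage (learning inhibition radius 2,
#' inference inhibition radius 0), 2x2 relay pooling, and a 20-neuron fully
#' connected layer — the reference architecture scaled down to a 12x12
#' input, with the kernel shrunk in proportion to the image so the pooled
#' grid (5x5) retains enough spatial resolution to separate the pattern
#' classes. Thresholds and learning-rate magnitudes are calibrated to this
#' scale (the LTP/LTD ratio stays -8 everywhere): the convolutional
#' learning threshold (6) is set higher than its propagation threshold (3)
#' so each STDP update integrates a receptive-field-sized window of
#' evidence while spike counts stay high, and the small fully connected
#' layer uses a threshold of 20 with a larger rate magnitude than the
#' convolution: its per-neuron weight columns receive far fewer updates in
#' a single pass than the shared convolution kernels, which accumulate
#' updates from every grid position.
#'
#' @param maps Convolutional maps.
#' @param fc_neurons Fully connected neurons.
#' @param input_side Image side length.
#' @param kernel Convolution kernel side length.
#' @param conv_rate,fc_rate LTP rate magnitudes (alpha+) per layer;
#'   alpha- = -alpha+ / 8.
#' @param t_conv_learn,t_conv_infer Convolutional thresholds.
#' @param t_fc Fully connected thresholds.
#' @return A [network_config()].
#' @export
toy_network_config <- function(maps = 4, fc_neurons = 20, input_side = 12,
                               kernel = 3, conv_rate = 0.03, fc_rate = 0.06,
                               t_conv_learn = 6, t_conv_infer = 3,
                               t_fc = 20) {
  network_config(input_side, list(
    layer_spec("conv", maps = maps, kernel = kernel, t_learn = t_conv_learn,
               t_infer = t_conv_infer,
               stdp = stdp_params(conv_rate, -conv_rate / 8)),
    layer_spec("pool"),
    layer_spec("fc", maps = fc_neurons, t_learn = t_fc, t_infer = t_fc,
               stdp = stdp_params(fc_rate, -fc_rate / 8))
  ))
}

#' @rdname toy_network_config
#' @export
toy_encoder_params <- function() encoder_params(duration = 2)
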
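#' Specify one network layer
#'
#' A network is a stack of convolutional, pooling and fully connected layers.
#' Convolutional layers share one weight kernel per neural map across all
#' spatial positions; pooling layers are pure relays (no weights, no
#' thresholds) that forward every spike with coordinates floor-divided by the
#' window; the fully connected layer merges all maps and positions into
#' global, position-independent class representations.
#'
#' Each non-pool neuron holds two thresholds: `t_learn` for the learning
#' accumulator (pseudo-spikes that trigger STDP and winner-take-all
#' inhibition, never propagated) and `t_infer` for the inference accumulator
#' (propagated spikes). Learning inhibition in a convolutional layer resets
#' all other positions of the winning map plus a Chebyshev neighborhood of
#' radius `r_inh_learn` in every other map; inference inhibition is
#' inter-map only, with radius `r_inh_infer` (`0` = the same position in
#' every other map, negative = disabled). In a fully connected layer,
#' learning competition is all-to-all and inference spikes are uninhibited.
#'
#' Defaults follow the reference parameterization: convolution kernel 5,
#' stride 1, thresholds 8 (first conv stage) or 30 (deeper stages, set
#' explicitly), `r_inh_learn = 2`, `r_inh_infer = 0`, initial weights drawn
#' from a normal distribution 0.8 +- 0.1 for conv and 0.67 +- 0.1 for fc,
#' clipped to `[0, 1]`.
#'
#' @param kind One of `"conv"`, `"pool"`, `"fc"`.
#' @param maps Number of neural maps (conv) or neurons (fc). Ignored for
#'   pool layers, which relay every incoming map.
#' @param kernel,stride Convolution kernel side length and stride.
#' @param window Pooling window (non-overlapping).
#' @param t_learn,t_infer Thresholds of the learning and inference
#'   accumulators.
#' @param r_inh_learn,r_inh_infer Inter-map inhibition radii (Chebyshev, in
#'   grid positions) for the learning and inference accumulators.
#' @param init_mean,init_sd Initial weight distribution.
#' @param stdp An [stdp_params()] object for this layer.
#' @return A `layer_spec` object.
#' @examples
#' layer_spec("conv", maps = 16, t_learn = 8, t_infer = 8)
#' layer_spec("pool")
#' layer_spec("fc", maps = 1000, t_learn = 30, t_infer = 30)
#' @export
layer_spec <- function(kind = c("conv", "pool", "fc"), maps = NULL,
                       kernel = 5, stride = 1, window = 2,
                       t_learn = NULL, t_infer = NULL,
                       r_inh_learn = 2, r_inh_infer = 0,
                       init_mean = NULL, init_sd = 0.1,
                       stdp = stdp_params()) {
  kind <- match.arg(kind)
  if (kind != "pool") {
    if (is.null(maps) || maps < 1) abort("`maps` must be a positive integer")
    if (is.null(t_learn)) t_learn <- if (kind == "conv") 8 else 30
    if (is.null(t_infer)) t_infer <- t_learn
    if (t_learn <= 0 || t_infer <= 0) abort("thresholds must be positive")
    if (is.null(init_mean)) init_mean <- if (kind == "conv") 0.8 else 0.67
  }
  structure(
    list(kind = kind, maps = maps, kernel = kernel, stride = stride,
         window = window, t_learn = t_learn, t_infer = t_infer,
         r_inh_learn = r_inh_learn, r_inh_infer = r_inh_infer,
         init_mean = init_mean, init_sd = init_sd, stdp = stdp),
    class = "layer_spec"
  )
}

#' Output grid side length of a layer
#'
#' Valid convolution: `(n - k) / s + 1`. Non-overlapping pooling: `n / s`
#' (errors if `n` is not divisible).
#'
#' @param n Input side length.
#' @param k Kernel side (conv) or window (pool).
#' @param s Stride.
#' @param kind `"conv"` or `"pool"`.
#' @return Integer side length.
#' @examples
#' output_side(28, 5, 1)            # 24
#' output_side(24, 2, 2, "pool")    # 12
#' @export
output_side <- function(n, k, s = 1, kind = c("conv", "pool")) {
  kind <- match.arg(kind)
  if (kind == "conv") {
    if (n < k) abort("input side is smaller than the kernel")
    if ((n - k) %% s != 0)
      abort("convolution arithmetic does not chain: (n - k) not divisible by stride")
    as.integer((n - k) / s + 1)
  } else {
    if (n %% k != 0)
      abort("pooling side must divide the input side (non-overlapping windows)")
    as.integer(n / k)
  }
}

#' Assemble and validate a network configuration
#'
#' Chains the layer geometry from the input side through all layers,
#' erroring if shapes do not compose, and resolves per-layer input/output
#' sides and map counts. The final layer must be fully connected.
#'
#' @param input_side Side length of the (square, single-channel) input.
#' @param layers A list of [layer_spec()] objects.
#' @return A `network_config` object whose `$layers` carry resolved
#'   `in_side`, `in_maps` and `out_side` fields.
#' @examples
#' cfg <- network_config(12, list(
#'   layer_spec("conv", maps = 4, t_learn = 8),
#'   layer_spec("pool"),
#'   layer_spec("fc", maps = 20, t_learn = 30)
#' ))
#' @export
network_config <- function(input_side, layers) {
  if (length(layers) == 0) abort("at least one layer is required")
  side <- as.integer(input_side)
  maps <- 1L
  resolved <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ls <- layers[[i]]
    stopifnot(inherits(ls, "layer_spec"))
    ls$in_side <- side
    ls$in_maps <- maps
    if (ls$kind == "conv") {
      side <- output_side(side, ls$kernel, ls$stride, "conv")
      maps <- as.integer(ls$maps)
    } else if (ls$kind == "pool") {
      side <- output_side(side, ls$window, ls$window, "pool")
      ls$maps <- maps
    } else {
      if (i != length(layers)) abort("a fully connected layer must be last")
      side <- 1L
      maps <- as.integer(ls$maps)
    }
    ls$out_side <- side
    resolved[[i]] <- ls
  }
  if (resolved[[length(resolved)]]$kind != "fc")
    abort("the final layer must be fully connected")
  structure(list(input_side = as.integer(input_side), layers = resolved),
            class = "network_config")
}

#' Reference full-scale network configuration
#'
#' Two 5x5/stride-1 convolution stages with 2x2 relay pooling and a fully
#' connected top layer: 28x28 input -> conv (24x24) -> pool (12x12) -> conv
#' (8x8) -> pool (4x4) -> fc. Thresholds 8/8, 30/30 and 30/30; learning
#' inhibition radius 2, inference inhibition radius 0.
#'
#' @param conv1_maps,conv2_maps,fc_neurons Layer sizes (defaults 16, 32,
#'   1000; the large variant uses 256 second-stage maps).
#' @param input_side Input image side length.
#' @return A [network_config()] object.
#' @examples
#' count_adjustable_synapses(full_network_config())
#' @export
full_network_config <- function(conv1_maps = 16, conv2_maps = 32,
                                fc_neurons = 1000, input_side = 28) {
  network_config(input_side, list(
    layer_spec("conv", maps = conv1_maps, t_learn = 8, t_infer = 8),
    layer_spec("pool"),
    layer_spec("conv", maps = conv2_maps, t_learn = 30, t_infer = 30),
    layer_spec("pool"),
    layer_spec("fc", maps = fc_neurons, t_learn = 30, t_infer = 30)
  ))
}

#' Count adjustable synapses in a configuration
#'
#' Shared convolution kernels contribute `kernel^2 * in_maps * maps` weights
#' per conv layer; the fully connected layer contributes its full fan-in
#' times its neuron count. Pooling layers carry no weights.
#'
#' @param config A [network_config()] object.
#' @return Total number of adjustable synaptic weights.
#' @examples
#' count_adjustable_synapses(full_network_config(16, 32, 1000))
#' @export
count_adjustable_synapses <- function(config) {
  stopifnot(inherits(config, "network_config"))
  total <- 0
  for (ls in config$layers) {
    if (ls$kind == "conv") {
      total <- total + ls$kernel^2 * ls$in_maps * ls$maps
    } else if (ls$kind == "fc") {
      total <- total + ls$in_side^2 * ls$in_maps * ls$maps
    }
  }
  total
}

#' Build a network with randomly initialized weights
#'
#' Weights are drawn from a normal distribution with the per-layer
#' `init_mean` and `init_sd`, then clipped to `[0, 1]`. All accumulators
#' start at zero. Deterministic under a fixed seed.
#'
#' @param config A [network_config()] object.
#' @param seed Optional integer seed.
#' @return An object of class `stdp_network`.
#' @examples
#' net <- build_network(toy_network_config(), seed = 1)
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(config$layers, function(ls) {
    if (ls$kind == "conv") {
      nw <- ls$kernel^2 * ls$in_maps * ls$maps
      ls$w <- array(pmin(1, pmax(0, rnorm(nw, ls$init_mean, ls$init_sd))),
                    dim = c(ls$kernel, ls$kernel, ls$in_maps, ls$maps))
    } else if (ls$kind == "fc") {
      nin <- ls$in_side^2 * ls$in_maps
      ls$w <- matrix(pmin(1, pmax(0, rnorm(nin * ls$maps, ls$init_mean, ls$init_sd))),
                     nrow = nin, ncol = ls$maps)
    }
    ls
  })
  structure(list(input_side = config$input_side, layers = layers,
                 config = config),
            class = "stdp_network")
}

#' Learning-side winner-take-all inhibition targets
#'
#' For a convolutional layer the learning reset of a pseudo-spiking winner
#' reaches (a) every other position of the winner's own map and (b) all
#' positions within Chebyshev distance `r_inh_learn` of the winner in every
#' other map. For a fully connected layer it reaches every other neuron.
#'
#' @param network An `stdp_network` (or `network_config`).
#' @param layer Layer index (1-based; must not be a pooling layer).
#' @param map,row,col Winner address (1-based; `row`/`col` ignored for fc).
#' @return A tibble with columns `map`, `row`, `col` of inhibited neurons
#'   (the winner itself is excluded).
#' @examples
#' net <- build_network(toy_network_config(), seed = 1)
#' nrow(inhibition_targets_learning(net, 1, map = 1, row = 5, col = 5))
#' @export
inhibition_targets_learning <- function(network, layer, map, row = 1, col = 1) {
  ls <- .get_layer(network, layer)
  if (ls$kind == "fc") {
    others <- setdiff(seq_len(ls$maps), map)
    return(tibble(map = others, row = 1L, col = 1L))
  }
  S <- ls$out_side
  .check_addr(ls, map, row, col)
  grid <- expand.grid(row = seq_len(S), col = seq_len(S))
  intra <- tibble(map = as.integer(map), row = as.integer(grid$row),
                  col = as.integer(grid$col))
  intra <- dplyr::filter(intra, !(.data$row == !!row & .data$col == !!col))
  r <- ls$r_inh_learn
  if (is.null(r) || r < 0) {
    inter <- tibble(map = integer(), row = integer(), col = integer())
  } else {
    rows <- max(1, row - r):min(S, row + r)
    cols <- max(1, col - r):min(S, col + r)
    inter <- tidyr::expand_grid(map = setdiff(seq_len(ls$maps), map),
                                row = as.integer(rows), col = as.integer(cols))
  }
  dplyr::arrange(bind_rows(intra, inter), .data$map, .data$row, .data$col)
}

#' Inference-side inhibition targets
#'
#' Inference inhibition is inter-map only: a propagated spike resets the
#' inference accumulators within Chebyshev distance `r_inh_infer` of the
#' winner's position in every *other* map. Radius 0 means the same position
#' only; a negative radius disables it. Fully connected inference spikes are
#' uninhibited (empty set).
#'
#' @inheritParams inhibition_targets_learning
#' @return A tibble with columns `map`, `row`, `col`.
#' @export
inhibition_targets_inference <- function(network, layer, map, row = 1, col = 1) {
  ls <- .get_layer(network, layer)
  empty <- tibble(map = integer(), row = integer(), col = integer())
  if (ls$kind == "fc") return(empty)
  r <- ls$r_inh_infer
  if (is.null(r) || r < 0) return(empty)
  S <- ls$out_side
  .check_addr(ls, map, row, col)
  rows <- max(1, row - r):min(S, row + r)
  cols <- max(1, col - r):min(S, col + r)
  out <- tidyr::expand_grid(map = setdiff(seq_len(ls$maps), map),
                            row = as.integer(rows), col = as.integer(cols))
  dplyr::arrange(out, .data$map, .data$row, .data$col)
}

#' Route a convolution-grid position through a pooling layer
#'
#' Non-overlapping pooling relays every spike, floor-dividing the
#' coordinates by the window.
#'
#' @param row,col 1-based position in the convolutional output grid.
#' @param window Pooling window side.
#' @return Integer vector `c(row, col)` in the pooled grid (1-based).
#' @examples
#' pool_route(6, 5)  # c(3, 3)
#' @export
pool_route <- function(row, col, window = 2) {
  as.integer(c((row - 1) %/% window, (col - 1) %/% window) + 1L)
}

.get_layer <- function(network, layer) {
  layers <- if (inherits(network, "stdp_network")) network$layers
            else if (inherits(network, "network_config")) network$layers
            else abort("expected an `stdp_network` or `network_config`")
  if (layer < 1 || layer > length(layers)) abort("invalid layer index")
  ls <- layers[[layer]]
  if (ls$kind == "pool") abort("pooling layers have no neurons to inhibit")
  ls
}

.check_addr <- function(ls, map, row, col) {
  S <- ls$out_side
  if (map < 1 || map > ls$maps || row < 1 || row > S || col < 1 || col > S)
    abort("address out of range for this layer")
  invisible(TRUE)
}

#' @export
print.stdp_network <- function(x, ...) {
  cat(sprintf("<stdp_network> input %dx%d\n", x$input_side, x$input_side))
  for (i in seq_along(x$layers)) {
    ls <- x$layers[[i]]
    if (ls$kind == "pool") {
      cat(sprintf("  [%d] pool %dx%d -> %dx%d (%d maps, relay)\n",
                  i, ls$in_side, ls$in_side, ls$out_side, ls$out_side, ls$maps))
    } else if (ls$kind == "conv") {
      cat(sprintf(
        "  [%d] conv %d maps, kernel %d/stride %d, %dx%d -> %dx%d, T = %g/%g\n",
        i, ls$maps, ls$kernel, ls$stride, ls$in_side, ls$in_side,
        ls$out_side, ls$out_side, ls$t_learn, ls$t_infer))
    } else {
      cat(sprintf("  [%d] fc %d neurons over %dx%dx%d, T = %g/%g\n",
                  i, ls$maps, ls$in_side, ls$in_side, ls$in_maps,
                  ls$t_learn, ls$t_infer))
    }
  }
  invisible(x)
}

#' Tidy the weights of a network
#'
#' @param x An `stdp_network`.
#' @param ... Unused.
#' @return A tibble with one row per adjustable weight: `layer`, `map`
#'   (output map or fc neuron), `in_map`, `kx`, `ky` (kernel offsets, or the
#'   input grid position for fc layers) and `weight`.
#' @export
tidy.stdp_network <- function(x, ...) {
  out <- list()
  for (i in seq_along(x$layers)) {
    ls <- x$layers[[i]]
    if (ls$kind == "pool") next
    if (ls$kind == "conv") {
      d <- expand.grid(kx = seq_len(ls$kernel), ky = seq_len(ls$kernel),
                       in_map = seq_len(ls$in_maps), map = seq_len(ls$maps))
      out[[length(out) + 1]] <- tibble(
        layer = i, map = as.integer(d$map), in_map = as.integer(d$in_map),
        kx = as.integer(d$kx), ky = as.integer(d$ky),
        weight = as.vector(ls$w))
    } else {
      d <- expand.grid(kx = seq_len(ls$in_side), ky = seq_len(ls$in_side),
                       in_map = seq_len(ls$in_maps), map = seq_len(ls$maps))
      # fc weight rows are laid out (in_map, kx, ky) row-major over the grid
      flat <- ((d$in_map - 1) * ls$in_side + (d$kx - 1)) * ls$in_side + d$ky
      out[[length(out) + 1]] <- tibble(
        layer = i, map = as.integer(d$map), in_map = as.integer(d$in_map),
        kx = as.integer(d$kx), ky = as.integer(d$ky),
        weight = ls$w[cbind(flat, d$map)])
    }
  }
  bind_rows(out)
}
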
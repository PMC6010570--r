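#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a spike raster for `spike_record`, the online running-error curve for
#' `stdp_fit`, and the confusion matrix for `stdp_eval`.
#' [plot_preferred_features()] draws the learned-feature mosaic of a layer.
#'
#' @param object The object to plot.
#' @param max_points Subsample cap for large spike rasters.
#' @param ... Unused.
#' @return A ggplot object.
#' @name stdpnet-plots
NULL

#' @rdname stdpnet-plots
#' @export
autoplot.spike_record <- function(object, max_points = 20000, ...) {
  sp <- object$spikes
  if (nrow(sp) > max_points)
    sp <- sp[sort(sample.int(nrow(sp), max_points)), ]
  ls <- object$network$layers
  sp <- mutate(sp, neuron = purrr::pmap_dbl(
    list(.data$layer, .data$map, .data$row, .data$col),
    function(l, m, r, cc) {
      S <- ls[[l]]$out_side
      ((m - 1) * S + (r - 1)) * S + cc
    }))
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$layer), scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (input units)", y = "neuron (flat index)",
                  title = "Propagated spikes by layer")
}

#' @rdname stdpnet-plots
#' @export
autoplot.stdp_fit <- function(object, ...) {
  if (is.null(object$metrics)) abort("this fit carries no online metrics")
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$stimulus, y = .data$running_error)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "training stimulus", y = "running error",
                  title = "Online running error (trailing window)")
}

#' @rdname stdpnet-plots
#' @export
autoplot.stdp_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = factor(.data$predicted),
                               y = factor(.data$label), fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted", y = "true class", fill = "count",
                  title = sprintf("Confusion (accuracy %.1f%%)",
                                  100 * object$accuracy))
}

#' @rdname stdpnet-plots
#' @param network A trained `stdp_network`.
#' @param layer Layer index to visualize.
#' @param units Unit (map/neuron) indices; defaults to all.
#' @export
plot_preferred_features <- function(network, layer, units = NULL) {
  ls <- network$layers[[layer]]
  if (is.null(units))
    units <- seq_len(if (ls$kind == "fc") ls$maps else ls$maps)
  df <- purrr::map_dfr(units, function(u) {
    m <- preferred_feature(network, layer, u)
    tibble(unit = u, row = rep(seq_len(nrow(m)), ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)),
           weight = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "strength",
                  title = sprintf("Preferred features, layer %d", layer))
}
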
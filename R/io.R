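#' Save and restore a network checkpoint
#'
#' Checkpoints are plain JSON: the resolved layer configuration plus the
#' flat weight vectors, restored losslessly (`digits = NA`). For quick
#' inspection in other tools, [tidy.stdp_network()] plus
#' [utils::write.csv()] gives a flat per-weight CSV.
#'
#' @param network An `stdp_network`.
#' @param path File path (`.json`).
#' @return `read_network()` returns the restored `stdp_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "stdp_network"))
  payload <- list(
    input_side = network$input_side,
    layers = lapply(network$layers, function(ls) {
      out <- ls[setdiff(names(ls), c("w", "stdp"))]
      out$stdp <- unclass(ls[["stdp"]])
      if (!is.null(ls[["w"]])) {
        out$w <- as.vector(ls[["w"]])
        out$w_dim <- dim(ls[["w"]])
      }
      out
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  scalar <- function(x) if (is.null(x)) NULL else x[[1]]
  layers <- lapply(payload$layers, function(ls) {
    out <- lapply(ls[setdiff(names(ls), c("stdp", "w", "w_dim"))],
                  function(x) if (length(x) == 1) x[[1]] else unlist(x))
    if (!is.null(ls[["stdp"]])) {
      sp <- lapply(ls[["stdp"]], scalar)
      out$stdp <- stdp_params(sp$alpha_plus, sp$alpha_minus, sp$beta_plus,
                              sp$beta_minus, isTRUE(sp$simple))
    }
    if (!is.null(ls[["w"]])) {
      w <- vapply(ls[["w"]], as.numeric, numeric(1))
      dim(w) <- vapply(ls[["w_dim"]], as.integer, integer(1))
      out$w <- w
    }
    out
  })
  structure(list(input_side = as.integer(payload$input_side),
                 layers = layers, config = NULL),
            class = "stdp_network")
}

#' Read a run configuration from YAML
#'
#' A run configuration mirrors [network_config()] plus [encoder_params()]:
#' top-level keys `input_side`, `layers` (list of maps with `kind` and any
#' [layer_spec()] argument; `stdp` sub-maps become [stdp_params()]) and
#' `encoder` (any [encoder_params()] argument). Used by the command-line
#' runner; see `system.file("scripts", "stdpnet", package = "stdpnet")`.
#'
#' @param path YAML file path.
#' @return A list with `config` (a `network_config`) and `encoder`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("reading YAML run configs requires the yaml package")
  y <- yaml::read_yaml(path)
  layers <- lapply(y$layers, function(ls) {
    args <- ls
    if (!is.null(ls$stdp)) args$stdp <- do.call(stdp_params, ls$stdp)
    do.call(layer_spec, args)
  })
  cfg <- network_config(y$input_side, layers)
  enc <- do.call(encoder_params, if (is.null(y$encoder)) list() else y$encoder)
  list(config = cfg, encoder = enc)
}
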
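#' STDP parameters for the bounded exponential learning rule
#'
#' At every learning-accumulator threshold crossing ("pseudo-spike") the
#' winning neuron updates its afferent weights: synapses whose presynaptic
#' neuron fired since the neuron's last learning reset are potentiated by
#' `alpha_plus * exp(-beta_plus * w)`, all other synapses are depressed by
#' `alpha_minus * exp(-beta_minus * (1 - w))`, and the result is clipped to
#' `[0, 1]`. With the default damping (`beta_plus = 3`, `beta_minus = 0`) the
#' depression term is a flat `alpha_minus` and potentiation is strongly damped
#' at high weights, so weights stop short of saturating: beyond the crossover
#' weight (see [crossover_weight()]) depression outweighs potentiation.
#'
#' Only the ratio `alpha_plus / alpha_minus` shapes the learned features; the
#' common magnitude sets the learning speed and is typically rescaled per
#' layer. The defaults fix the ratio at -8.
#'
#' @param alpha_plus Positive LTP rate.
#' @param alpha_minus Negative LTD rate.
#' @param beta_plus Non-negative LTP damping factor.
#' @param beta_minus Non-negative LTD damping factor.
#' @param simple If `TRUE`, drop the exponential weight dependence and apply
#'   the bare `alpha_plus` / `alpha_minus` increments (still clipped).
#' @return An object of class `stdp_params`.
#' @examples
#' p <- stdp_params()
#' crossover_weight(p)
#' @export
stdp_params <- function(alpha_plus = 0.08, alpha_minus = -0.01,
                        beta_plus = 3, beta_minus = 0, simple = FALSE) {
  if (!is.numeric(alpha_plus) || alpha_plus <= 0)
    abort("`alpha_plus` must be a positive number")
  if (!is.numeric(alpha_minus) || alpha_minus >= 0)
    abort("`alpha_minus` must be a negative number")
  if (beta_plus < 0 || beta_minus < 0)
    abort("damping factors must be non-negative")
  structure(
    list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
         beta_plus = beta_plus, beta_minus = beta_minus,
         simple = isTRUE(simple)),
    class = "stdp_params"
  )
}

#' Apply one STDP update to a weight kernel
#'
#' @param weights Numeric vector, matrix or array of weights in `[0, 1]`.
#' @param active Logical vector/array of the same length (or an integer index
#'   vector) marking synapses whose presynaptic neuron fired inside the
#'   learning window, i.e. since the postsynaptic neuron's last learning
#'   reset.
#' @param params An [stdp_params()] object.
#' @return The updated weights, clipped to `[0, 1]`, with dimensions
#'   preserved.
#' @examples
#' stdp_update(c(0, 0.5, 0.9), active = c(TRUE, TRUE, FALSE), stdp_params())
#' @export
stdp_update <- function(weights, active, params = stdp_params()) {
  stopifnot(inherits(params, "stdp_params"))
  if (any(weights < 0 | weights > 1))
    abort("`weights` must lie in [0, 1]")
  if (is.numeric(active)) {
    idx <- active
    active <- rep(FALSE, length(weights))
    active[idx] <- TRUE
  }
  if (length(active) != length(weights))
    abort("`active` must match `weights` in length")
  dw <- ifelse(
    active,
    if (params$simple) params$alpha_plus
    else params$alpha_plus * exp(-params$beta_plus * weights),
    if (params$simple) params$alpha_minus
    else params$alpha_minus * exp(-params$beta_minus * (1 - weights))
  )
  out <- pmin(1, pmax(0, weights + dw))
  dim(out) <- dim(weights)
  out
}

#' Weight at which potentiation and depression balance
#'
#' Solves `alpha_plus * exp(-beta_plus * w) = -alpha_minus` for `w`:
#' `w = -(1 / beta_plus) * log(-alpha_minus / alpha_plus)`. Above this weight
#' depression is stronger than potentiation, which keeps learned weights away
#' from the upper bound. With the defaults (ratio -8, damping 3) the
#' crossover sits at `log(8) / 3`, about 0.69.
#'
#' @param params An [stdp_params()] object with `beta_plus > 0`.
#' @return The crossover weight (not clipped to `[0, 1]`).
#' @examples
#' crossover_weight(stdp_params(alpha_plus = 0.08, alpha_minus = -0.01))
#' @export
crossover_weight <- function(params = stdp_params()) {
  stopifnot(inherits(params, "stdp_params"))
  if (params$beta_plus == 0)
    abort("crossover weight is undefined for `beta_plus` = 0 (LTP is undamped)")
  -(1 / params$beta_plus) * log(-params$alpha_minus / params$alpha_plus)
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf(
    "<stdp_params> alpha+ = %g, alpha- = %g, beta+ = %g, beta- = %g%s\n",
    x$alpha_plus, x$alpha_minus, x$beta_plus, x$beta_minus,
    if (x$simple) " (simple rule, no exponential)" else ""))
  invisible(x)
}
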
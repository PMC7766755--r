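#' Activation functions and their natural output ranges
#'
#' The three activations supported throughout the package, each with the
#' interval its outputs naturally occupy: sigmoid maps to (0,1), tanh to
#' (-1,1), and relu to \[0, Inf). Because maximum-entropy interventions and
#' activation binning both need a bounded interval, the relu range is
#' truncated by convention to \[0,1\]; with inputs drawn uniformly from
#' \[0,1\] this is exactly the interval a unit-weight relu edge fills, which
#' is what makes the relu identity edge a bin-for-bin bijection.
#'
#' @param name One of `"sigmoid"`, `"tanh"`, `"relu"`.
#' @return An object of class `ei_activation`: a list with elements `name`,
#'   `fn` (the function), `grad` (derivative expressed through the
#'   activation output where possible), and `range` (the bounded binning /
#'   perturbation interval).
#' @examples
#' act <- activation_kind("sigmoid")
#' act$fn(0) # 0.5
#' @export
activation_kind <- function(name = c("sigmoid", "tanh", "relu")) {
  if (length(name) != 1 || !name %in% c("sigmoid", "tanh", "relu")) {
    stop("unknown activation '", paste(name, collapse = ","),
         "' (expected one of: sigmoid, tanh, relu)", call. = FALSE)
  }
  out <- switch(name,
    sigmoid = list(
      name = "sigmoid",
      fn = function(z) stats::plogis(z),
      # derivative wrt pre-activation, from output a and pre-activation z
      grad = function(a, z) a * (1 - a),
      range = c(0, 1)
    ),
    tanh = list(
      name = "tanh",
      fn = function(z) tanh(z),
      grad = function(a, z) 1 - a^2,
      range = c(-1, 1)
    ),
    relu = list(
      name = "relu",
      fn = function(z) pmax(z, 0),
      grad = function(a, z) as.numeric(z > 0),
      range = c(0, 1)
    )
  )
  structure(out, class = "ei_activation")
}

as_activation <- function(x) {
  if (inherits(x, "ei_activation")) x else activation_kind(x)
}
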
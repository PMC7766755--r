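#' Construct a feedforward layer
#'
#' A layer is the causal mechanism under study: a dense weight matrix `W`
#' (entry `W[i, j]` is the weight of the edge from input node `i` to output
#' node `j`), an activation applied at each output node, and the bounded
#' intervals over which input nodes are perturbed (`input_range`) and output
#' activations are binned (`output_range`).
#'
#' Range conventions: by default the output range is the activation's
#' natural (truncated for relu) range, and the input range is the same
#' interval — the inputs are assumed to be activations of upstream nodes of
#' the same kind. For a network's first layer, which receives raw features
#' rather than upstream activations, `init_network()` sets the input range
#' to \[0,1\].
#'
#' @param weights Numeric matrix, `n_in` x `n_out`, all entries finite.
#' @param activation An activation name or [activation_kind()] object.
#' @param bias Optional numeric vector of length `n_out`; default absent.
#' @param input_range,output_range Either a length-2 vector `(lo, hi)`
#'   applied to every node, or a 2 x n matrix with one `(lo, hi)` column per
#'   node. Widths must be strictly positive.
#' @return An object of class `ei_layer`.
#' @examples
#' ly <- feedforward_layer(matrix(2.5), "sigmoid")
#' layer_forward(ly, 0.4)
#' @export
feedforward_layer <- function(weights, activation, bias = NULL,
                              input_range = NULL, output_range = NULL) {
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) < 1 || ncol(weights) < 1)
    stop("weights must be a numeric matrix with n_in >= 1 and n_out >= 1", call. = FALSE)
  if (!all(is.finite(weights)))
    stop("all weights must be finite", call. = FALSE)
  act <- as_activation(activation)
  n_in <- nrow(weights); n_out <- ncol(weights)
  if (!is.null(bias)) {
    bias <- as.numeric(bias)
    if (length(bias) != n_out || !all(is.finite(bias)))
      stop("bias must be a finite numeric vector of length n_out", call. = FALSE)
  }
  input_range <- expand_range(if (is.null(input_range)) act$range else input_range,
                              n_in, "input_range")
  output_range <- expand_range(if (is.null(output_range)) act$range else output_range,
                               n_out, "output_range")
  structure(list(weights = weights, activation = act, bias = bias,
                 input_range = input_range, output_range = output_range),
            class = "ei_layer")
}

# normalize a range spec to a 2 x n matrix and validate positive widths
expand_range <- function(r, n, what) {
  if (is.null(dim(r))) {
    if (length(r) != 2) stop(what, " must be (lo, hi) or a 2 x n matrix", call. = FALSE)
    r <- matrix(r, nrow = 2, ncol = n)
  }
  r <- as.matrix(r)
  if (nrow(r) != 2 || ncol(r) != n)
    stop(what, " must have one (lo, hi) column per node", call. = FALSE)
  if (any(!is.finite(r)) || any(r[2, ] - r[1, ] <= 0))
    stop(what, " must have strictly positive, finite width per node", call. = FALSE)
  unname(r)
}

#' Forward pass through one layer
#'
#' Computes `activation(x %*% W + bias)` row-wise. Deterministic; the only
#' entry point through which interventions reach downstream nodes.
#'
#' @param layer An [feedforward_layer()] object.
#' @param inputs Numeric vector of length `n_in`, or a matrix with `n_in`
#'   columns (one sample per row).
#' @return A matrix with `n_out` columns (a 1-row matrix for vector input).
#' @export
layer_forward <- function(layer, inputs) {
  stopifnot(inherits(layer, "ei_layer"))
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != nrow(layer$weights))
    stop("dimension mismatch: layer expects ", nrow(layer$weights),
         " inputs, got ", ncol(inputs), call. = FALSE)
  if (!all(is.finite(inputs)))
    stop("inputs must be finite", call. = FALSE)
  z <- inputs %*% layer$weights
  if (!is.null(layer$bias)) z <- sweep(z, 2, layer$bias, "+")
  layer$activation$fn(z)
}

n_in <- function(layer) nrow(layer$weights)
n_out <- function(layer) ncol(layer$weights)

#' @export
print.ei_layer <- function(x, ...) {
  cat(sprintf("<ei_layer> %d -> %d, activation %s%s\n",
              n_in(x), n_out(x), x$activation$name,
              if (is.null(x$bias)) ", no bias" else ", with bias"))
  invisible(x)
}

# convenience used throughout tests and curves: an isolated single edge
single_edge_layer <- function(activation, w, input_range = NULL, output_range = NULL) {
  feedforward_layer(matrix(w, 1, 1), activation,
                    input_range = input_range, output_range = output_range)
}
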
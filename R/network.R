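#' Assemble layers into a network
#'
#' Validates that consecutive layer dimensions chain (`n_out` of layer k
#' equals `n_in` of layer k+1) and attaches metadata (task name, training
#' step of a checkpoint, ...).
#'
#' @param layers List of [feedforward_layer()] objects.
#' @param meta Named list of metadata.
#' @return An object of class `ei_network`.
#' @export
network_spec <- function(layers, meta = list()) {
  if (!is.list(layers) || length(layers) < 1 ||
      !all(vapply(layers, inherits, TRUE, "ei_layer")))
    stop("layers must be a non-empty list of ei_layer objects", call. = FALSE)
  widths <- c(n_in(layers[[1]]), vapply(layers, n_out, 1L))
  for (k in seq_along(layers)[-1]) {
    if (n_in(layers[[k]]) != n_out(layers[[k - 1]]))
      stop("layer dimension chain violated between layers ", k - 1, " and ", k,
           ": ", n_out(layers[[k - 1]]), " outputs feed ", n_in(layers[[k]]),
           " inputs", call. = FALSE)
  }
  structure(list(layers = layers, architecture = as.integer(widths), meta = meta),
            class = "ei_network")
}

#' Initialize a network with uniform fan-in weights
#'
#' Weights of each layer are drawn i.i.d. from
#' `U(-1/sqrt(fanin), +1/sqrt(fanin))` where `fanin` is the layer's input
#' width; biases are absent by default. The first layer's perturbation range
#' is \[0,1\] (raw feature convention); every later layer inherits the
#' activation range of its upstream nodes.
#'
#' @param architecture Integer vector of layer widths, e.g. `c(4, 5, 5, 3)`.
#' @param activation Activation name shared by all layers.
#' @param seed Integer seed; the same seed reproduces the same weights.
#' @param bias If `TRUE`, zero-initialized biases are attached (off by
#'   default).
#' @param meta Metadata list stored on the network.
#' @return An `ei_network`.
#' @examples
#' net <- init_network(c(4, 5, 5, 3), "sigmoid", seed = 1)
#' net$architecture
#' @export
init_network <- function(architecture, activation = "sigmoid", seed,
                         bias = FALSE, meta = list()) {
  architecture <- as.integer(architecture)
  if (length(architecture) < 2)
    stop("architecture needs at least an input and an output width", call. = FALSE)
  if (any(architecture < 1))
    stop("layer widths must be positive", call. = FALSE)
  act <- as_activation(activation)
  layers <- with_seed(derive_seed(seed, "init"), {
    lapply(seq_len(length(architecture) - 1), function(k) {
      fanin <- architecture[k]
      bound <- 1 / sqrt(fanin)
      w <- matrix(stats::runif(fanin * architecture[k + 1], -bound, bound),
                  fanin, architecture[k + 1])
      feedforward_layer(
        w, act,
        bias = if (bias) rep(0, architecture[k + 1]) else NULL,
        input_range = if (k == 1) c(0, 1) else act$range
      )
    })
  })
  meta$activation <- act$name
  meta$seed <- seed
  network_spec(layers, meta)
}

#' Forward pass through a whole network
#'
#' @param net An `ei_network`.
#' @param inputs Feature matrix (samples in rows) or a single vector.
#' @return Output activation matrix.
#' @export
network_forward <- function(net, inputs) {
  stopifnot(inherits(net, "ei_network"))
  a <- if (is.null(dim(inputs))) matrix(inputs, nrow = 1) else inputs
  for (ly in net$layers) a <- layer_forward(ly, a)
  a
}

#' Save / load a network as JSON
#'
#' The file holds the architecture, the shared activation name, each layer's
#' weight matrix (row-major, one row per input node) and optional bias, and
#' the metadata. Weights are written with 17 significant digits so the
#' round-trip `load_network(save_network(x))` is bit-exact.
#'
#' @param net An `ei_network`.
#' @param path File path; the directory must exist.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the reconstructed `ei_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "ei_network"))
  payload <- list(
    architecture = net$architecture,
    activation = net$layers[[1]]$activation$name,
    layers = lapply(net$layers, function(ly) {
      list(weights = apply(ly$weights, 1, function(r) as.list(r), simplify = FALSE),
           bias = if (is.null(ly$bias)) NULL else as.list(ly$bias),
           input_range = apply(ly$input_range, 2, function(c2) as.list(c2), simplify = FALSE),
           output_range = apply(ly$output_range, 2, function(c2) as.list(c2), simplify = FALSE))
    }),
    meta = net$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such network file: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("malformed network file: ",
                                               conditionMessage(e), call. = FALSE))
  need <- c("architecture", "activation", "layers")
  if (!all(need %in% names(payload)))
    stop("malformed network file: missing fields ",
         paste(setdiff(need, names(payload)), collapse = ", "), call. = FALSE)
  act <- activation_kind(payload$activation) # distinct unknown-activation error
  layers <- lapply(payload$layers, function(ls) {
    w <- do.call(rbind, lapply(ls$weights, function(r) as.numeric(unlist(r))))
    feedforward_layer(
      w, act,
      bias = if (is.null(ls$bias)) NULL else as.numeric(unlist(ls$bias)),
      input_range = if (is.null(ls$input_range)) NULL
                    else vapply(ls$input_range, function(c2) as.numeric(unlist(c2)), numeric(2)),
      output_range = if (is.null(ls$output_range)) NULL
                     else vapply(ls$output_range, function(c2) as.numeric(unlist(c2)), numeric(2))
    )
  })
  net <- network_spec(layers, meta = payload$meta %||% list()) # chain check here
  arch <- as.integer(unlist(payload$architecture))
  if (!identical(net$architecture, arch))
    stop("malformed network file: stored architecture does not match layers",
         call. = FALSE)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ei_network <- function(x, ...) {
  cat(sprintf("<ei_network> %s, activation %s\n",
              paste(x$architecture, collapse = " -> "),
              x$layers[[1]]$activation$name))
  if (!is.null(x$meta$step)) cat("  checkpoint step:", x$meta$step, "\n")
  invisible(x)
}
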
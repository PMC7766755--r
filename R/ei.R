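#' Effective information of a layer
#'
#' The mutual information between the joint (binned) states of the input
#' nodes and the joint (binned) states of the output nodes when every input
#' node is independently forced to maximum entropy over its perturbation
#' range:
#' \deqn{EI = I(L_1, L_2) \mid do(L_1 = H_{max})}
#' Estimated with the plug-in histogram estimator on `cfg$n_samples`
#' intervention samples, streamed in batches. All mutual bits are caused by
#' the injected noise, so EI measures the strength of the layer's causal
#' relationships, in bits; it is bounded by
#' `min(n_in, n_out) * log2(n_bins)`.
#'
#' @param layer An [feedforward_layer()].
#' @param cfg An [intervention_config()].
#' @param n_bins Bins per node for both input and output discretization
#'   (default 16).
#' @return An `mi_estimate` with the EI in `value_bits`.
#' @examples
#' ly <- feedforward_layer(matrix(2), "sigmoid")
#' effective_information(ly, intervention_config(2e4, seed = 1))
#' @export
effective_information <- function(layer, cfg, n_bins = 16) {
  st <- perturb_stream_counts(layer, cfg, n_bins)
  ei_from_stream(st, cfg)
}

ei_from_stream <- function(st, cfg) {
  v <- if (length(st$in_counts) == 1 || length(st$out_counts) == 1) 0 else {
    max(entropy_from_counts(st$in_counts) + entropy_from_counts(st$out_counts) -
          entropy_from_counts(st$joint_counts), 0)
  }
  mi_estimate(v, st$n, length(st$joint_counts), st$n_bins,
              extra = list(seed = cfg$seed))
}

#' EI with a doubling convergence trace
#'
#' Runs the plug-in EI estimator on a growing prefix of one intervention
#' stream, doubling the cumulative sample count, until two successive
#' estimates differ by less than `tol` bits or `max_samples` is reached.
#' Non-convergence is flagged on the returned estimate, never raised as an
#' error, so long measurements can degrade gracefully.
#'
#' @param layer An [feedforward_layer()].
#' @param tol Convergence tolerance in bits (> 0).
#' @param max_samples Sample budget ceiling.
#' @param seed Seed of the intervention stream.
#' @param n_bins Bins per node.
#' @param start_samples First (smallest) sample count of the schedule.
#' @param batch_size Streaming batch size.
#' @return An `mi_estimate` with extra fields `converged` (logical) and
#'   `trace` (matrix with columns `n`, `ei_bits`, one row per doubling).
#' @examples
#' ly <- feedforward_layer(matrix(1.5), "sigmoid")
#' r <- converge_ei(ly, tol = 0.02, max_samples = 1e5, seed = 3)
#' r$converged
#' @export
converge_ei <- function(layer, tol = 0.01, max_samples = 1e7, seed = 1,
                        n_bins = 16, start_samples = 1e4, batch_size = 1e6) {
  stopifnot(tol > 0)
  schedule <- start_samples * 2^(0:max(0, floor(log2(max_samples / start_samples))))
  schedule <- unique(pmin(schedule, max_samples))
  trace <- matrix(NA_real_, nrow = length(schedule), ncol = 2,
                  dimnames = list(NULL, c("n", "ei_bits")))
  est <- NULL; converged <- FALSE; prev <- NA_real_
  for (k in seq_along(schedule)) {
    cfg <- intervention_config(schedule[k], seed = seed, batch_size = batch_size)
    est <- effective_information(layer, cfg, n_bins)
    trace[k, ] <- c(schedule[k], est$value_bits)
    if (!is.na(prev) && abs(est$value_bits - prev) < tol) {
      converged <- TRUE
      trace <- trace[seq_len(k), , drop = FALSE]
      break
    }
    prev <- est$value_bits
  }
  est$converged <- converged
  est$trace <- trace
  est
}

#' Deterministic quadrature EI (oracle)
#'
#' Computes the same binned EI as [effective_information()] but by exact
#' numerical quadrature instead of Monte-Carlo sampling: the input box is
#' tiled with a tensor grid of equal-mass cells, each cell midpoint is
#' pushed through the layer, and the exact bin-to-bin transition mass is
#' accumulated into a joint table. Independent of the sampling path, it
#' serves as the reference against which the Monte-Carlo estimator is
#' validated; practical for layers with one or two input nodes.
#'
#' @param layer An [feedforward_layer()] with a small number of inputs.
#' @param n_bins Bins per node.
#' @param total_cells Approximate total number of quadrature cells; split
#'   evenly across input dimensions (default 1e5 in 1-D, ~2e6 in 2-D).
#' @return An `mi_estimate` (with `n_samples` set to the cell count).
#' @export
quadrature_ei <- function(layer, n_bins = 16, total_cells = NULL) {
  d <- n_in(layer)
  if (d > 3) stop("quadrature oracle supports at most 3 input nodes", call. = FALSE)
  if (is.null(total_cells)) total_cells <- c(1e5, 2.1e6, 3.4e6)[d]
  m <- max(2L, as.integer(floor(total_cells^(1 / d))))
  B <- as.integer(n_bins)
  axes <- lapply(seq_len(d), function(i) {
    lo <- layer$input_range[1, i]; hi <- layer$input_range[2, i]
    lo + (seq_len(m) - 0.5) / m * (hi - lo)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  outputs <- layer_forward(layer, grid)
  bi <- discretize(grid, binning_scheme(B, layer$input_range))
  bo <- discretize(outputs, binning_scheme(B, layer$output_range))
  li <- joint_labels(bi, B); lo <- joint_labels(bo, B)
  ui <- unique(li); uo <- unique(lo)
  if (length(ui) == 1 || length(uo) == 1)
    return(mi_estimate(0, nrow(grid), length(ui) * length(uo), B))
  j <- (match(li, ui) - 1) * length(uo) + match(lo, uo)
  cj <- tabulate_sparse(j)
  v <- entropy_from_counts(tabulate_sparse(match(li, ui))) +
       entropy_from_counts(tabulate_sparse(match(lo, uo))) -
       entropy_from_counts(cj)
  mi_estimate(max(v, 0), nrow(grid), length(cj), B)
}
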
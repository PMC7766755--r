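#' Sensitivity of a layer
#'
#' Sum over all edges of the information each edge transmits in isolation:
#' \deqn{Sensitivity = \sum_{i \in L_1, j \in L_2} I(t_i, t_j) \mid do(i = H_{max})}
#' For each edge `(i, j)` the source node `i` alone is perturbed at maximum
#' entropy over its input range and the target is driven through that edge
#' only (`activation(w_ij * t_i)`, all other incoming edges removed — not
#' held at a baseline). Under this removal semantics a layer in which every
#' output node receives a single unique input has sensitivity equal to its
#' EI. Edges with exactly zero weight transmit a constant and contribute
#' exactly 0 bits; they are skipped.
#'
#' Each edge uses an independent sub-stream derived from `cfg$seed`, so
#' edge contributions are statistically independent of the joint injection
#' used for EI.
#'
#' @param layer An [feedforward_layer()].
#' @param cfg An [intervention_config()].
#' @param n_bins Bins per node.
#' @return List of class `ei_sensitivity`: `value_bits` (the sum) and
#'   `per_edge` (n_in x n_out matrix of edge contributions in bits).
#' @export
sensitivity <- function(layer, cfg, n_bins = 16) {
  B <- as.integer(n_bins)
  per_edge <- matrix(0, n_in(layer), n_out(layer))
  for (i in seq_len(n_in(layer))) {
    for (j in seq_len(n_out(layer))) {
      w <- layer$weights[i, j]
      if (w == 0) next
      per_edge[i, j] <- edge_ei(
        w, layer$activation,
        in_range = layer$input_range[, i],
        out_range = layer$output_range[, j],
        n_samples = cfg$n_samples, B = B,
        seed = derive_seed(cfg$seed, "edge", i, j),
        batch_size = cfg$batch_size
      )
    }
  }
  structure(list(value_bits = sum(per_edge), per_edge = per_edge,
                 n_samples = cfg$n_samples, n_bins = B, seed = cfg$seed),
            class = "ei_sensitivity")
}

# EI of one isolated edge: dense B x B joint table, streamed
edge_ei <- function(w, act, in_range, out_range, n_samples, B, seed,
                    batch_size = 1e6) {
  J <- matrix(0, B, B)
  with_seed(seed, {
    remaining <- n_samples
    while (remaining > 0) {
      nb <- min(remaining, batch_size)
      ti <- stats::runif(nb, in_range[1], in_range[2])
      tj <- act$fn(w * ti)
      bi <- bin_column(ti, in_range, B)
      bj <- bin_column(tj, out_range, B)
      J <- J + matrix(tabulate(bi * B + bj + 1L, B * B), B, B, byrow = TRUE)
      remaining <- remaining - nb
    }
  })
  mi_from_joint_counts(J)
}

bin_column <- function(v, r, B) {
  idx <- floor((v - r[1]) / (r[2] - r[1]) * B)
  idx[idx < 0] <- 0
  idx[idx > B - 1] <- B - 1
  as.integer(idx)
}

#' Degeneracy of a layer
#'
#' Information lost to overlapping connectivity, computed algebraically as
#' `sensitivity - EI` with a shared measurement configuration. Positive
#' degeneracy means upstream perturbation sources cannot be fully
#' reconstructed from the outputs. Small negative values can occur through
#' Monte-Carlo noise and are reported as-is, not clamped.
#'
#' @inheritParams sensitivity
#' @return Degeneracy in bits (scalar).
#' @export
degeneracy <- function(layer, cfg, n_bins = 16) {
  measure_layer(layer, cfg, n_bins)$degeneracy_bits
}

#' EI_parts: pairwise transmitted information under the joint injection
#'
#' The whole input layer is perturbed jointly at maximum entropy exactly as
#' for EI, but instead of the joint mutual information the sum of all
#' pairwise node-to-node mutual informations is taken:
#' \deqn{EI_{parts} = \sum_{i \in L_1, j \in L_2} I(t_i, t_j) \mid do(L_1 = H_{max})}
#' It differs from sensitivity in that all other nodes are perturbed too
#' (joint, not per-edge, injection), so interaction effects suppress or
#' inflate the pairwise terms. Pairs whose connecting weight is exactly
#' zero contribute exactly 0 bits and are skipped.
#'
#' @inheritParams sensitivity
#' @return List of class `ei_parts`: `value_bits` and `per_pair` matrix.
#' @export
ei_parts <- function(layer, cfg, n_bins = 16) {
  st <- perturb_stream_counts(layer, cfg, n_bins, pairwise = TRUE)
  parts_from_stream(st, layer)
}

parts_from_stream <- function(st, layer) {
  B <- st$n_bins
  per_pair <- matrix(0, n_in(layer), n_out(layer))
  for (i in seq_len(n_in(layer))) for (j in seq_len(n_out(layer))) {
    if (layer$weights[i, j] == 0) next
    per_pair[i, j] <- mi_from_joint_counts(st$pair_counts[, , i, j])
  }
  structure(list(value_bits = sum(per_pair), per_pair = per_pair,
                 n_samples = st$n, n_bins = B),
            class = "ei_parts")
}

#' Feedforward integrated information
#'
#' `phi = EI - EI_parts`, both computed on the same intervention samples
#' (common random numbers), measuring the irreducible joint effects of one
#' layer on the next. Not bounded below by zero: positive phi means the
#' joint effects are mostly informative, negative phi mostly noisy.
#'
#' @inheritParams sensitivity
#' @return Phi in bits (scalar).
#' @export
phi_feedforward <- function(layer, cfg, n_bins = 16) {
  st <- perturb_stream_counts(layer, cfg, n_bins, pairwise = TRUE)
  ei_from_stream(st, cfg)$value_bits - parts_from_stream(st, layer)$value_bits
}

#' Full causal-structure measurement of one layer
#'
#' One measurement point: EI and EI_parts are estimated from a single shared
#' joint injection (so their difference, phi, benefits from common random
#' numbers), sensitivity from independent per-edge injections, and
#' degeneracy and phi follow by their algebraic identities
#' `degeneracy = sensitivity - EI` and `phi = EI - EI_parts`, which
#' therefore hold exactly by construction on every result.
#'
#' @inheritParams sensitivity
#' @param layer_id Optional identifier stored on the result.
#' @param step Optional checkpoint/step index stored on the result.
#' @return An object of class `ei_result` with fields `ei_bits`,
#'   `sensitivity_bits`, `degeneracy_bits`, `ei_parts_bits`,
#'   `phi_feedforward_bits`, estimation metadata, and the per-edge
#'   sensitivity and per-pair EI_parts matrices.
#' @examples
#' ly <- feedforward_layer(matrix(c(2, 2), 2, 1), "sigmoid")
#' measure_layer(ly, intervention_config(2e4, seed = 5))
#' @export
measure_layer <- function(layer, cfg, n_bins = 16, layer_id = NA, step = NA) {
  st <- perturb_stream_counts(layer, cfg, n_bins, pairwise = TRUE)
  ei <- ei_from_stream(st, cfg)
  parts <- parts_from_stream(st, layer)
  sens <- sensitivity(layer, cfg, n_bins)
  structure(list(
    ei_bits = ei$value_bits,
    sensitivity_bits = sens$value_bits,
    degeneracy_bits = sens$value_bits - ei$value_bits,
    ei_parts_bits = parts$value_bits,
    phi_feedforward_bits = ei$value_bits - parts$value_bits,
    n_samples = cfg$n_samples, n_bins = as.integer(n_bins), seed = cfg$seed,
    n_distinct_joint = ei$n_distinct_joint,
    per_edge_sensitivity = sens$per_edge, per_pair_mi = parts$per_pair,
    layer_id = layer_id, step = step
  ), class = "ei_result")
}

#' @export
print.ei_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<ei_result>%s%s\n",
    "  EI          %8.4f bits\n",
    "  sensitivity %8.4f bits\n",
    "  degeneracy  %8.4f bits\n",
    "  EI_parts    %8.4f bits\n",
    "  phi         %8.4f bits\n",
    "  (n = %s, bins = %d, seed = %d)\n"),
    if (is.na(x$layer_id)) "" else paste0(" layer ", x$layer_id),
    if (is.na(x$step)) "" else paste0(" @ step ", x$step),
    x$ei_bits, x$sensitivity_bits, x$degeneracy_bits, x$ei_parts_bits,
    x$phi_feedforward_bits,
    format(x$n_samples, big.mark = ","), x$n_bins, x$seed))
  invisible(x)
}

#' Project a measurement onto the causal plane
#'
#' The causal plane has degeneracy on the x-axis and sensitivity on the
#' y-axis; since `EI = sensitivity - degeneracy`, displacement along the 45
#' degree line `y = x` (the EI "nullcline") leaves EI unchanged, movement
#' toward the sensitivity axis raises EI and movement toward the degeneracy
#' axis lowers it.
#'
#' @param result An `ei_result`.
#' @return A one-row data.frame with columns `degeneracy`, `sensitivity`,
#'   `step`, `layer_id`.
#' @export
causal_plane_point <- function(result) {
  stopifnot(inherits(result, "ei_result"))
  data.frame(degeneracy = result$degeneracy_bits,
             sensitivity = result$sensitivity_bits,
             step = result$step, layer_id = result$layer_id)
}
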
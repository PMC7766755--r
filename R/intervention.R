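#' Configuration of a maximum-entropy intervention
#'
#' Describes one noise injection: how many intervention samples to draw,
#' the seed of the sample stream, and the batch size used for streaming so
#' that memory scales with the batch, not with the total sample count. The
#' default sample count of 1e7 is the fixed injection length used for the
#' reference training experiments; desk-scale helpers (curves, trajectory
#' tracking) pass smaller explicit budgets.
#'
#' The sample stream is fully reproducible given `(seed, batch_size)`;
#' changing the batch size reorders which raw draws land in which matrix
#' cell, so it is part of the stream definition.
#'
#' @param n_samples Positive integer number of intervention samples.
#' @param seed Integer master seed for the injection.
#' @param batch_size Samples generated per streaming batch.
#' @return An object of class `ei_intervention`.
#' @export
intervention_config <- function(n_samples = 1e7, seed = 1, batch_size = 1e6) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1)
    stop("n_samples must be a positive integer", call. = FALSE)
  structure(list(n_samples = floor(n_samples), seed = as.integer(seed),
                 batch_size = max(1, floor(batch_size))),
            class = "ei_intervention")
}

#' Draw a maximum-entropy perturbation sample
#'
#' Realizes the intervention distribution `do(L1 = Hmax)`: every input node
#' is forced, independently and simultaneously, into states drawn uniformly
#' over its own `input_range`; the effect distribution is obtained by
#' pushing each sampled input row through the layer's forward pass.
#'
#' This materializes the full `n_samples x n_in` and `n_samples x n_out`
#' matrices; for injections larger than memory allows, the measurement
#' functions ([effective_information()], [measure_layer()], ...) stream the
#' same samples in batches instead of calling this directly.
#'
#' @param layer An [feedforward_layer()].
#' @param cfg An [intervention_config()].
#' @return An object of class `perturbation_sample`: list with `inputs`
#'   (the intervention states) and `outputs` (`layer_forward` of each row).
#' @examples
#' ly <- feedforward_layer(matrix(1), "sigmoid")
#' ps <- sample_intervention(ly, intervention_config(1000, seed = 7))
#' range(ps$inputs)
#' @export
sample_intervention <- function(layer, cfg) {
  stopifnot(inherits(layer, "ei_layer"), inherits(cfg, "ei_intervention"))
  inputs <- with_seed(derive_seed(cfg$seed, "joint"),
                      draw_uniform_inputs(layer, cfg$n_samples))
  structure(list(inputs = inputs, outputs = layer_forward(layer, inputs)),
            class = "perturbation_sample")
}

# uniform draws over each input node's range; columns independent
draw_uniform_inputs <- function(layer, n) {
  d <- n_in(layer)
  u <- matrix(stats::runif(n * d), n, d)
  lo <- layer$input_range[1, ]; hi <- layer$input_range[2, ]
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

# --- streaming accumulation -------------------------------------------------
#
# One pass over the intervention stream, accumulating
#   * sparse counts of joint input states, joint output states, and
#     (input, output) joint-joint states -> the EI estimate, and
#   * optionally dense B x B per-(i, j) pair counts on the same samples
#     -> the EI_parts estimate (common random numbers with EI).
# Memory is O(batch + distinct observed states + n_pairs * B^2).
perturb_stream_counts <- function(layer, cfg, n_bins, pairwise = FALSE,
                                  stream_seed = derive_seed(cfg$seed, "joint")) {
  B <- as.integer(n_bins)
  sc_in <- binning_scheme(B, layer$input_range)
  sc_out <- binning_scheme(B, layer$output_range)
  din <- n_in(layer); dout <- n_out(layer)
  acc_in <- list(); acc_out <- list(); acc_j <- list()
  cnt_in <- list(); cnt_out <- list(); cnt_j <- list()
  pair_counts <- if (pairwise) {
    array(0, dim = c(B, B, din, dout))
  } else NULL
  with_seed(stream_seed, {
    remaining <- cfg$n_samples
    k <- 0L
    while (remaining > 0) {
      nb <- min(remaining, cfg$batch_size)
      inputs <- draw_uniform_inputs(layer, nb)
      outputs <- layer_forward(layer, inputs)
      bin_i <- discretize(inputs, sc_in)
      bin_o <- discretize(outputs, sc_out)
      li <- joint_labels(bin_i, B)
      lo <- joint_labels(bin_o, B)
      lj <- if (din + dout <= floor(50 / log2(max(B, 2)))) {
        joint_labels(cbind(bin_i, bin_o), B)
      } else paste(li, lo, sep = "|")
      k <- k + 1L
      acc_in[[k]] <- unique(li); cnt_in[[k]] <- tabulate_sparse(li)
      acc_out[[k]] <- unique(lo); cnt_out[[k]] <- tabulate_sparse(lo)
      acc_j[[k]] <- unique(lj); cnt_j[[k]] <- tabulate_sparse(lj)
      if (pairwise) {
        for (i in seq_len(din)) for (j in seq_len(dout)) {
          if (layer$weights[i, j] == 0) next
          idx <- bin_i[, i] * B + bin_o[, j] + 1L
          pair_counts[, , i, j] <- pair_counts[, , i, j] +
            matrix(tabulate(idx, B * B), B, B, byrow = TRUE)
        }
      }
      remaining <- remaining - nb
    }
  })
  list(
    in_counts = merge_sparse(acc_in, cnt_in),
    out_counts = merge_sparse(acc_out, cnt_out),
    joint_counts = merge_sparse(acc_j, cnt_j),
    pair_counts = pair_counts,
    n = cfg$n_samples, n_bins = B
  )
}

merge_sparse <- function(label_batches, count_batches) {
  labs <- unlist(label_batches, use.names = FALSE)
  cnts <- unlist(count_batches, use.names = FALSE)
  u <- unique(labs)
  as.numeric(rowsum(cnts, match(labs, u), reorder = FALSE))
}
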
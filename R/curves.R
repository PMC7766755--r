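#' Single-edge EI curve over a weight grid
#'
#' EI of an isolated edge A -> B as a function of the connection weight:
#' the characteristic rise-and-decay curve of each activation. The same
#' input sample is reused across all grid weights (common random numbers),
#' so the estimated curve is a smooth function of the weight and the grid
#' argmax is not jittered by resampling noise.
#'
#' The perturbation and binning ranges follow the activation convention:
#' sigmoid (0,1), tanh (-1,1), relu \[0,1\].
#'
#' @param activation Activation name or [activation_kind()].
#' @param weights Numeric weight grid (default `seq(0, 6, by = 0.01)`).
#' @param n_bins Bins per node.
#' @param n_samples Intervention samples shared across the grid.
#' @param seed Sample stream seed.
#' @return A data.frame with columns `weight`, `ei_bits`, `n_samples`,
#'   `n_bins`, `seed`, carrying attributes `argmax` (grid weight of the
#'   maximum) and `grid_step`.
#' @examples
#' cv <- ei_curve_single_edge("relu", seq(0.5, 1.5, 0.05), n_samples = 2e4, seed = 1)
#' attr(cv, "argmax")
#' @export
ei_curve_single_edge <- function(activation, weights = seq(0, 6, by = 0.01),
                                 n_bins = 16, n_samples = 1e6, seed = 1) {
  act <- as_activation(activation)
  if (length(weights) == 0) stop("empty weight grid", call. = FALSE)
  B <- as.integer(n_bins)
  r <- act$range
  x <- with_seed(derive_seed(seed, "curve"),
                 stats::runif(n_samples, r[1], r[2]))
  bi <- bin_column(x, r, B)
  ei <- vapply(weights, function(w) {
    bj <- bin_column(act$fn(w * x), r, B)
    mi_from_joint_counts(matrix(tabulate(bi * B + bj + 1L, B * B), B, B, byrow = TRUE))
  }, numeric(1))
  out <- data.frame(weight = weights, ei_bits = ei,
                    n_samples = n_samples, n_bins = B, seed = seed)
  attr(out, "argmax") <- weights[which.max(ei)]
  attr(out, "grid_step") <- if (length(weights) > 1) stats::median(diff(weights)) else NA_real_
  out
}

#' EI, sensitivity and degeneracy manifolds for a two-input layer
#'
#' For a layer of two input nodes A, B with single connections to one
#' output node C, tabulates EI(wA, wB), sensitivity(wA, wB) and
#' degeneracy(wA, wB) over a weight grid. The identity
#' `EI = sensitivity - degeneracy` holds exactly at every grid point by
#' construction. Joint input samples are shared across the grid; per-edge
#' sensitivity injections use independent sub-streams.
#'
#' @param activation Activation name or [activation_kind()].
#' @param grid_wA,grid_wB Weight grids for the two edges.
#' @param n_bins Bins per node.
#' @param n_samples Intervention samples per grid point.
#' @param seed Master seed.
#' @return A long data.frame: `wA`, `wB`, `ei_bits`, `sensitivity_bits`,
#'   `degeneracy_bits`, `n_samples`, `n_bins`, `seed`.
#' @export
ei_manifold_two_inputs <- function(activation, grid_wA, grid_wB,
                                   n_bins = 16, n_samples = 1e5, seed = 1) {
  act <- as_activation(activation)
  if (length(grid_wA) == 0 || length(grid_wB) == 0)
    stop("empty weight grid", call. = FALSE)
  B <- as.integer(n_bins)
  r <- act$range
  xs <- with_seed(derive_seed(seed, "manifold"),
                  matrix(stats::runif(2 * n_samples, r[1], r[2]), ncol = 2))
  lab_in <- bin_column(xs[, 1], r, B) * B + bin_column(xs[, 2], r, B)
  # single-edge EI reused for the two sensitivity terms (removal semantics)
  sens_curve <- function(ws, which_edge) {
    vapply(ws, function(w) {
      if (w == 0) return(0)
      edge_ei(w, act, r, r, n_samples, B,
              seed = derive_seed(seed, "edge", which_edge, w))
    }, numeric(1))
  }
  sA <- sens_curve(grid_wA, 1L)
  sB <- sens_curve(grid_wB, 2L)
  grid <- expand.grid(wA = grid_wA, wB = grid_wB, KEEP.OUT.ATTRS = FALSE)
  ei <- mapply(function(wA, wB) {
    if (wA == 0 && wB == 0) return(0)
    y <- act$fn(xs[, 1] * wA + xs[, 2] * wB)
    lab_j <- lab_in * B + bin_column(y, r, B)
    cj <- tabulate_sparse(lab_j)
    max(entropy_from_counts(tabulate_sparse(lab_in)) +
          entropy_from_counts(tabulate(bin_column(y, r, B) + 1L, B)) -
          entropy_from_counts(cj), 0)
  }, grid$wA, grid$wB)
  sens <- sA[match(grid$wA, grid_wA)] + sB[match(grid$wB, grid_wB)]
  data.frame(wA = grid$wA, wB = grid$wB, ei_bits = ei,
             sensitivity_bits = sens, degeneracy_bits = sens - ei,
             n_samples = n_samples, n_bins = B, seed = seed)
}
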
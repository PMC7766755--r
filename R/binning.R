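#' Uniform per-node binning scheme
#'
#' Discretization that defines the state space on which mutual information
#' is computed: each node's interval is split into `n_bins` equal-width
#' bins, half-open `[lo, hi)` except the top bin, which is closed so the
#' upper endpoint belongs to bin `n_bins - 1`. Values outside the interval
#' are clipped into the boundary bins (required for relu, whose activations
#' can exceed the truncated \[0,1\] binning range).
#'
#' @param n_bins Positive integer number of bins per node.
#' @param ranges Length-2 vector or 2 x n matrix of per-node `(lo, hi)`.
#' @return An object of class `ei_binning`.
#' @examples
#' sc <- binning_scheme(8, c(0, 1))
#' discretize(c(0, 0.999, 1, 1.7), sc) # 0 7 7 7
#' @export
binning_scheme <- function(n_bins, ranges) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1) stop("n_bins must be a positive integer", call. = FALSE)
  if (is.null(dim(ranges))) ranges <- matrix(ranges, nrow = 2)
  if (nrow(ranges) != 2 || any(!is.finite(ranges)))
    stop("ranges must be a finite (lo, hi) pair per node", call. = FALSE)
  if (any(ranges[2, ] - ranges[1, ] <= 0))
    stop("zero-width binning range", call. = FALSE)
  structure(list(n_bins = n_bins, ranges = unname(as.matrix(ranges))),
            class = "ei_binning")
}

#' Discretize activations into bin indices
#'
#' @param values Numeric vector (single node) or matrix with one column per
#'   node of the scheme.
#' @param scheme An [binning_scheme()]. If its `ranges` has one column it is
#'   recycled across the matrix columns.
#' @return Integer matrix of bin indices in `0 .. n_bins - 1`, same shape
#'   as `values` (vectors come back as 1-column matrices).
#' @export
discretize <- function(values, scheme) {
  stopifnot(inherits(scheme, "ei_binning"))
  v <- if (is.null(dim(values))) matrix(values, ncol = 1) else as.matrix(values)
  r <- scheme$ranges
  if (ncol(r) == 1 && ncol(v) > 1) r <- r[, rep(1, ncol(v)), drop = FALSE]
  if (ncol(r) != ncol(v))
    stop("scheme has ", ncol(r), " node ranges but values have ", ncol(v),
         " columns", call. = FALSE)
  B <- scheme$n_bins
  lo <- rep(r[1, ], each = nrow(v))
  wd <- rep(r[2, ] - r[1, ], each = nrow(v))
  idx <- floor((as.numeric(v) - lo) / wd * B)
  idx[idx < 0] <- 0
  idx[idx > B - 1] <- B - 1 # clips out-of-range values and closes the top bin
  matrix(as.integer(idx), nrow = nrow(v))
}

# Map rows of a bin-index matrix to one joint-state label per row.
# Labels are canonical (depend only on the bin tuple, not on the sample):
# columns are packed into base-B doubles in chunks that stay below 2^50,
# and multi-chunk labels are joined into strings. Suitable as hash keys
# across streaming batches.
joint_labels <- function(bins, n_bins) {
  d <- ncol(bins)
  if (d == 1) return(as.numeric(bins[, 1]))
  bits <- log2(n_bins)
  chunk <- max(1L, as.integer(floor(50 / bits)))
  starts <- seq(1L, d, by = chunk)
  codes <- lapply(starts, function(s) {
    cols <- s:min(s + chunk - 1L, d)
    as.numeric(bins[, cols, drop = FALSE] %*% n_bins^(seq_along(cols) - 1))
  })
  if (length(codes) == 1) return(codes[[1]])
  do.call(paste, c(codes, sep = ":"))
}
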
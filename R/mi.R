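#' Shannon entropy of a count vector, in bits
#'
#' Plug-in (maximum-likelihood) estimate from raw counts; zero counts are
#' ignored.
#'
#' @param counts Non-negative numeric vector of state counts.
#' @return Entropy in bits.
#' @export
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("empty count vector", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Plug-in mutual information between two label sequences
#'
#' Maximum-likelihood histogram estimator in log base 2:
#' `MI = H(X) + H(Y) - H(X, Y)` with empirical frequencies. Joint states are
#' counted sparsely (only observed combinations are stored), so memory is
#' proportional to the number of distinct observed joint states, not to the
#' size of the full product state space. The estimator is non-negative by
#' construction; if either sequence is constant the result is exactly 0.
#' No small-sample bias correction is applied — at small `n` the estimate is
#' biased upward by roughly `(K - 1) / (2 n ln 2)` bits, with `K` the number
#' of occupied joint states; use [converge_ei()] to see the estimate
#' stabilize with growing `n` instead.
#'
#' @param x,y Equal-length label vectors (numeric or character joint-state
#'   labels, e.g. from [joint_labels()] / [discretize()]).
#' @return An object of class `mi_estimate`: list with `value_bits`,
#'   `n_samples`, `n_distinct_joint`.
#' @examples
#' x <- rep(0:7, each = 10)
#' mutual_information(x, x)$value_bits # exactly 3 bits
#' @export
mutual_information <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty input", call. = FALSE)
  if (length(x) != length(y)) stop("label sequences differ in length", call. = FALSE)
  ux <- unique(x); uy <- unique(y)
  if (length(ux) == 1 || length(uy) == 1) {
    return(mi_estimate(0, length(x), length(ux) * length(uy)))
  }
  ix <- match(x, ux); iy <- match(y, uy)
  j <- (ix - 1) * length(uy) + iy
  cj <- tabulate_sparse(j)
  v <- entropy_from_counts(tabulate(ix, length(ux))) +
       entropy_from_counts(tabulate(iy, length(uy))) -
       entropy_from_counts(cj)
  mi_estimate(max(v, 0), length(x), length(cj))
}

# counts of a numeric label vector without materializing the full range
tabulate_sparse <- function(lab) {
  u <- unique(lab)
  tabulate(match(lab, u), length(u))
}

mi_estimate <- function(value_bits, n_samples, n_distinct_joint,
                        n_bins = NA_integer_, extra = list()) {
  structure(c(list(value_bits = value_bits, n_samples = n_samples,
                   n_distinct_joint = n_distinct_joint, n_bins = n_bins),
              extra),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.4f bits  (n = %s, distinct joint states = %d%s)\n",
              x$value_bits, format(x$n_samples, big.mark = ","),
              x$n_distinct_joint,
              if (is.na(x$n_bins)) "" else paste0(", bins = ", x$n_bins)))
  if (!is.null(x$converged) && !x$converged)
    cat("  warning: estimate flagged as NOT converged\n")
  invisible(x)
}

# MI in bits from a dense joint count matrix (inputs in rows)
mi_from_joint_counts <- function(J) {
  n <- sum(J)
  pin <- rowSums(J); pout <- colSums(J)
  if (sum(pin > 0) == 1 || sum(pout > 0) == 1) return(0)
  max(entropy_from_counts(pin) + entropy_from_counts(pout) -
        entropy_from_counts(as.numeric(J)), 0)
}
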
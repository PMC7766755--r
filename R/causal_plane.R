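#' Causal-plane path length of a trajectory
#'
#' Total Euclidean distance travelled in the (degeneracy, sensitivity)
#' plane across consecutive measurement steps — how much a layer's causal
#' structure differentiates during training.
#'
#' @param degeneracy,sensitivity Numeric vectors ordered by step.
#' @return Scalar path length in bits.
#' @export
causal_path_length <- function(degeneracy, sensitivity) {
  stopifnot(length(degeneracy) == length(sensitivity))
  if (length(degeneracy) < 2) return(0)
  sum(sqrt(diff(degeneracy)^2 + diff(sensitivity)^2))
}

#' Distance from the EI nullcline
#'
#' Perpendicular distance of causal-plane points from the 45-degree line
#' `sensitivity = degeneracy`, on which movement leaves EI unchanged.
#' Layers that sit close to the nullcline contribute little net EI.
#'
#' @param degeneracy,sensitivity Numeric vectors.
#' @return Vector of non-negative distances (bits).
#' @export
nullcline_distance <- function(degeneracy, sensitivity) {
  abs(sensitivity - degeneracy) / sqrt(2)
}

#' Plot causal-plane trajectories
#'
#' One path per layer in the (degeneracy, sensitivity) plane, with the EI
#' nullcline drawn as a dashed 45-degree line. Requires ggplot2.
#'
#' @param trajectory A trajectory data.frame from [track_training()] (needs
#'   columns `degeneracy_bits`, `sensitivity_bits`, `layer`, `step`).
#' @return A ggplot object.
#' @export
plot_causal_plane <- function(trajectory) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  lim <- range(c(trajectory$degeneracy_bits, trajectory$sensitivity_bits, 0))
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$degeneracy_bits, y = .data$sensitivity_bits,
                               colour = factor(.data$layer), group = .data$layer)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"), type = "closed")) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "degeneracy (bits)", y = "sensitivity (bits)",
                  colour = "layer", title = "Causal plane") +
    ggplot2::theme_minimal()
}
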
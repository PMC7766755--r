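#' Track causal-structure trajectories across training checkpoints
#'
#' For every checkpoint of a training run and every layer-to-layer
#' connection, computes the full measurement ([measure_layer()]: EI,
#' sensitivity, degeneracy, EI_parts, phi) and aligns it with the recorded
#' train/test losses. The perturbation seed of each (step, layer)
#' measurement is derived from one master seed, so adding checkpoints or
#' layers never changes the samples used elsewhere.
#'
#' @param run An `ei_training_run` from [train_network()], or a list of
#'   `ei_network` checkpoints with `meta$step` set.
#' @param n_samples Intervention samples per measurement point.
#' @param n_bins Bins per node.
#' @param seed Master measurement seed.
#' @param convergence_tol If not `NULL`, additionally runs [converge_ei()]
#'   per point with this tolerance and reports its flag in the `converged`
#'   column; if `NULL` the column is `NA`.
#' @return A data.frame with one row per (step, layer): columns `step`,
#'   `layer`, `ei_bits`, `sensitivity_bits`, `degeneracy_bits`,
#'   `ei_parts_bits`, `phi_bits`, `train_loss`, `test_loss`, `n_samples`,
#'   `n_bins`, `converged`.
#' @examples
#' task <- make_synthetic_task("iris_like", seed = 1)
#' net <- init_network(c(4, 5, 5, 3), "sigmoid", seed = 1)
#' run <- train_network(net, task, train_config(2, 10, schedule = c(0, 2)))
#' tr <- track_training(run, n_samples = 5e3, seed = 1)
#' nrow(tr) # 2 steps x 3 layers
#' @export
track_training <- function(run, n_samples = 1e5, n_bins = 16, seed = 1,
                           convergence_tol = NULL) {
  checkpoints <- if (inherits(run, "ei_training_run")) run$checkpoints else run
  losses <- if (inherits(run, "ei_training_run")) run$losses else NULL
  rows <- list()
  for (ck in checkpoints) {
    step <- ck$meta$step %||% NA_integer_
    for (k in seq_along(ck$layers)) {
      ly <- ck$layers[[k]]
      cfg <- intervention_config(n_samples,
                                 seed = derive_seed(seed, "measure", step, k))
      res <- measure_layer(ly, cfg, n_bins, layer_id = k, step = step)
      converged <- NA
      if (!is.null(convergence_tol)) {
        converged <- converge_ei(ly, tol = convergence_tol,
                                 max_samples = n_samples,
                                 seed = derive_seed(seed, "measure", step, k),
                                 n_bins = n_bins)$converged
      }
      rows[[length(rows) + 1]] <- data.frame(
        step = step, layer = k,
        ei_bits = res$ei_bits, sensitivity_bits = res$sensitivity_bits,
        degeneracy_bits = res$degeneracy_bits, ei_parts_bits = res$ei_parts_bits,
        phi_bits = res$phi_feedforward_bits,
        train_loss = if (is.null(losses)) NA_real_ else losses$train_loss[match(step, losses$step)],
        test_loss = if (is.null(losses)) NA_real_ else losses$test_loss[match(step, losses$step)],
        n_samples = n_samples, n_bins = n_bins, converged = converged
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$step, out$layer), , drop = FALSE]
}

default_architecture <- function(task_kind) {
  switch(task_kind,
         iris_like = c(4L, 5L, 5L, 3L),
         mnist_like = c(25L, 6L, 6L, 5L),
         stop("no default architecture for task '", task_kind, "'", call. = FALSE))
}

default_train_config <- function(task_kind, seed, epochs = NULL, schedule = NULL,
                                 n_schedule = 10) {
  if (task_kind == "iris_like") {
    epochs <- epochs %||% 4000L; batch <- 10L
  } else {
    epochs <- epochs %||% 500L; batch <- 50L
  }
  train_config(epochs, batch, learning_rate = 0.01,
               schedule = schedule %||% geometric_schedule(epochs, n_schedule),
               seed = derive_seed(seed, "shuffle-master"))
}

#' Run one full tracked experiment
#'
#' Generates the synthetic task, initializes the network with uniform
#' fan-in weights, trains with the reference protocol (MSE loss, vanilla
#' gradient descent, lr 0.01; 4000 epochs at batch 10 for `iris_like`,
#' 500 epochs at batch 50 for `mnist_like`, sigmoid activations, no
#' biases), and tracks the causal-plane / phi trajectory at the scheduled
#' checkpoints. The whole experiment is a pure function of `seed`.
#'
#' @param task_kind `"iris_like"` or `"mnist_like"`.
#' @param seed Master seed (expanded into data / init / shuffle /
#'   measurement sub-streams).
#' @param architecture Layer widths; defaults to 4-5-5-3 (iris_like) or
#'   25-6-6-5 (mnist_like).
#' @param activation Activation name (default `"sigmoid"`).
#' @param epochs,schedule Optional overrides of the training length and
#'   checkpoint schedule.
#' @param measure_samples Intervention samples per measurement point
#'   (desk-scale default 1e5; increase toward 1e7 for protocol-scale runs).
#' @param n_bins Bins per node (default 16).
#' @param convergence_tol Passed to [track_training()].
#' @return List of class `ei_experiment`: `task`, `run` (training run),
#'   `trajectory` (data.frame), `final_accuracy`, `seed`.
#' @export
run_experiment <- function(task_kind, seed, architecture = NULL,
                           activation = "sigmoid", epochs = NULL,
                           schedule = NULL, measure_samples = 1e5,
                           n_bins = 16, convergence_tol = NULL) {
  task <- make_synthetic_task(task_kind, seed = derive_seed(seed, "data"))
  architecture <- architecture %||% default_architecture(task_kind)
  net <- init_network(architecture, activation, seed = derive_seed(seed, "weights"))
  cfg <- default_train_config(task_kind, seed, epochs = epochs, schedule = schedule)
  run <- train_network(net, task, cfg)
  traj <- track_training(run, n_samples = measure_samples, n_bins = n_bins,
                         seed = derive_seed(seed, "measure-master"),
                         convergence_tol = convergence_tol)
  structure(list(task = task, run = run, trajectory = traj,
                 final_accuracy = network_accuracy(run$checkpoints[[length(run$checkpoints)]], task),
                 seed = seed, architecture = architecture),
            class = "ei_experiment")
}

#' Per-layer causal-plane summary of a trajectory
#'
#' @param trajectory Trajectory data.frame from [track_training()].
#' @return data.frame with one row per layer: `path_length` (total
#'   causal-plane displacement) and `mean_nullcline_distance`.
#' @export
summarize_causal_plane <- function(trajectory) {
  do.call(rbind, lapply(split(trajectory, trajectory$layer), function(d) {
    d <- d[order(d$step), ]
    data.frame(layer = d$layer[1],
               path_length = causal_path_length(d$degeneracy_bits, d$sensitivity_bits),
               mean_nullcline_distance = mean(nullcline_distance(d$degeneracy_bits,
                                                                 d$sensitivity_bits)))
  }))
}

#' Do the largest EI changes coincide with the steepest loss changes?
#'
#' For each layer, finds the schedule interval with the largest absolute
#' EI change and checks whether it coincides with the interval of the
#' largest absolute training-loss change. A descriptive diagnostic (the
#' coupling is a tendency, not a law), returned per layer.
#'
#' @param trajectory Trajectory data.frame from [track_training()] (with
#'   loss columns filled).
#' @return data.frame per layer: the step interval of the largest |dEI|,
#'   of the largest |dloss|, and `coincide` (logical).
#' @export
ei_loss_coupling <- function(trajectory) {
  do.call(rbind, lapply(split(trajectory, trajectory$layer), function(d) {
    d <- d[order(d$step), ]
    if (nrow(d) < 2) return(NULL)
    dei <- abs(diff(d$ei_bits)); dl <- abs(diff(d$train_loss))
    i <- which.max(dei); j <- which.max(dl)
    data.frame(layer = d$layer[1],
               ei_interval_start = d$step[i], ei_interval_end = d$step[i + 1],
               loss_interval_start = d$step[j], loss_interval_end = d$step[j + 1],
               coincide = i == j)
  }))
}

#' Redundant-layer experiment
#'
#' Trains three variants of the mnist-shaped network — the base
#' architecture, one with a hidden layer removed, and one with
#' `n_extra_hidden` redundant hidden layers added — and compares their
#' causal-plane behavior. Redundant layers are expected to move little
#' (small path length) and to sit near the EI nullcline. Final test losses
#' and accuracies of the variants are reported side by side; at desk scale
#' the deeper variant can train substantially more slowly than the base
#' (vanishing gradients through many bias-free sigmoid layers), which is
#' visible in that table.
#'
#' @param task_kind Task (default `"mnist_like"`).
#' @param seed Master seed; the same task data is shared by all variants.
#' @param n_extra_hidden Redundant hidden layers added in the "added"
#'   variant (default 3, giving five hidden layers in total for the
#'   default base). With `n_extra_hidden = 0` the added variant is the
#'   base run repeated.
#' @param epochs,measure_samples,n_bins,schedule See [run_experiment()].
#' @return List of class `ei_redundancy`: per variant (`base`, `removed`,
#'   `added`) the experiment and its [summarize_causal_plane()] table, plus
#'   a comparison data.frame of final losses/accuracies.
#' @export
redundancy_experiment <- function(task_kind = "mnist_like", seed,
                                  n_extra_hidden = 3, epochs = NULL,
                                  measure_samples = 1e5, n_bins = 16,
                                  schedule = NULL) {
  base_arch <- default_architecture(task_kind)
  hidden <- base_arch[-c(1, length(base_arch))]
  variants <- list(
    base = base_arch,
    removed = c(base_arch[1], hidden[-1], base_arch[length(base_arch)]),
    added = c(base_arch[1], hidden,
              rep(hidden[length(hidden)], n_extra_hidden),
              base_arch[length(base_arch)])
  )
  out <- lapply(names(variants), function(v) {
    ex <- run_experiment(task_kind, seed, architecture = variants[[v]],
                         epochs = epochs, schedule = schedule,
                         measure_samples = measure_samples, n_bins = n_bins)
    list(experiment = ex, summary = summarize_causal_plane(ex$trajectory))
  })
  names(out) <- names(variants)
  cmp <- do.call(rbind, lapply(names(out), function(v) {
    lf <- out[[v]]$experiment$run$losses
    data.frame(variant = v,
               architecture = paste(variants[[v]], collapse = "-"),
               final_test_loss = lf$test_loss[nrow(lf)],
               final_accuracy = out[[v]]$experiment$final_accuracy)
  }))
  structure(c(out, list(comparison = cmp)), class = "ei_redundancy")
}
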
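#' Training configuration
#'
#' The reference protocol: mean-squared-error loss on one-hot targets and
#' vanilla (non-momentum) mini-batch gradient descent with learning rate
#' 0.01 — batch size 10 for the iris-shaped task, 50 for the mnist-shaped
#' one; 4000 and 500 epochs respectively. The measurement `schedule` is the
#' strictly increasing list of epochs at which weights are snapshotted and
#' losses recorded; it must include epoch 0 (the untrained network) and the
#' final epoch.
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Gradient-descent step size.
#' @param schedule Integer vector of checkpoint epochs; default
#'   [geometric_schedule()] of 12 points (denser early, where the loss and
#'   the causal structure move fastest).
#' @param seed Seed controlling the shuffling stream.
#' @return An object of class `ei_train_config`.
#' @export
train_config <- function(epochs, batch_size, learning_rate = 0.01,
                         schedule = NULL, seed = 1) {
  epochs <- as.integer(epochs)
  if (is.null(schedule)) schedule <- geometric_schedule(epochs)
  schedule <- as.integer(sort(unique(schedule)))
  if (any(diff(schedule) <= 0) || schedule[1] != 0 ||
      schedule[length(schedule)] != epochs)
    stop("schedule must be strictly increasing and include epoch 0 and the final epoch",
         call. = FALSE)
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, schedule = schedule,
                 seed = as.integer(seed)),
            class = "ei_train_config")
}

#' Geometrically spaced checkpoint schedule
#'
#' Checkpoint epochs spaced roughly geometrically between 1 and `epochs`,
#' always including 0 and `epochs`.
#'
#' @param epochs Final epoch.
#' @param n_points Number of schedule points (including 0 and the end).
#' @return Integer vector of epochs.
#' @export
geometric_schedule <- function(epochs, n_points = 12) {
  if (epochs < 1) return(c(0L, as.integer(epochs)))
  pts <- unique(round(exp(seq(0, log(epochs), length.out = max(2, n_points - 1)))))
  sort(unique(as.integer(c(0L, pts, epochs))))
}

one_hot <- function(y, k) {
  t <- matrix(0, length(y), k)
  t[cbind(seq_along(y), y)] <- 1
  t
}

# per-sample squared error summed over output nodes, averaged over samples
mse_loss <- function(pred, target) sum((pred - target)^2) / nrow(pred)

#' Train a network with vanilla gradient descent
#'
#' Mini-batch gradient descent on the mean-squared error between network
#' outputs and one-hot class targets, with hand-rolled backpropagation. The
#' loss convention is the per-sample squared error summed over output
#' nodes, averaged over the batch. The
#' shuffling stream is a deterministic function of the config seed, so a
#' full run is reproducible; weight snapshots taken at scheduled epochs are
#' deep copies, independent of later training.
#'
#' @param net An `ei_network` whose first-layer width equals the task's
#'   feature count and last width its class count.
#' @param task An `ei_task` from [make_synthetic_task()] or
#'   [task_from_csv()].
#' @param config An [train_config()].
#' @return An object of class `ei_training_run`: list with `checkpoints`
#'   (one `ei_network` per scheduled epoch, `meta$step` set), `losses`
#'   (data.frame step/train_loss/test_loss), `task_name`, `config`.
#' @examples
#' task <- make_synthetic_task("iris_like", seed = 1)
#' net <- init_network(c(4, 5, 5, 3), "sigmoid", seed = 1)
#' run <- train_network(net, task, train_config(5, 10, schedule = c(0, 5)))
#' run$losses
#' @export
train_network <- function(net, task, config) {
  stopifnot(inherits(net, "ei_network"), inherits(task, "ei_task"),
            inherits(config, "ei_train_config"))
  arch <- net$architecture
  if (arch[1] != task$n_features || arch[length(arch)] != task$n_classes)
    stop("dimension mismatch: network is ", arch[1], " -> ... -> ",
         arch[length(arch)], " but task has ", task$n_features,
         " features and ", task$n_classes, " classes", call. = FALSE)
  x <- task$train$x
  t_train <- one_hot(task$train$y, task$n_classes)
  t_test <- one_hot(task$test$y, task$n_classes)
  nl <- length(net$layers)
  W <- lapply(net$layers, function(l) l$weights)
  bias <- lapply(net$layers, function(l) l$bias)
  act <- net$layers[[1]]$activation
  lr <- config$learning_rate
  n <- nrow(x)

  snapshot <- function(step) {
    layers <- lapply(seq_len(nl), function(k) {
      feedforward_layer(W[[k]], act, bias = bias[[k]],
                        input_range = net$layers[[k]]$input_range,
                        output_range = net$layers[[k]]$output_range)
    })
    meta <- net$meta
    meta$step <- step
    meta$task <- task$name
    network_spec(layers, meta)
  }
  fwd <- function(xm) {
    a <- xm
    for (k in seq_len(nl)) {
      z <- a %*% W[[k]]
      if (!is.null(bias[[k]])) z <- sweep(z, 2, bias[[k]], "+")
      a <- act$fn(z)
    }
    a
  }

  checkpoints <- list()
  losses <- data.frame(step = config$schedule, train_loss = NA_real_,
                       test_loss = NA_real_)
  record <- function(step) {
    i <- match(step, config$schedule)
    checkpoints[[as.character(step)]] <<- snapshot(step)
    losses$train_loss[i] <<- mse_loss(fwd(x), t_train)
    losses$test_loss[i] <<- mse_loss(fwd(task$test$x), t_test)
  }
  record(0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", epoch), sample.int(n))
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      tb <- t_train[idx, , drop = FALSE]
      # forward with caches
      a <- vector("list", nl + 1); z <- vector("list", nl)
      a[[1]] <- xb
      for (k in seq_len(nl)) {
        z[[k]] <- a[[k]] %*% W[[k]]
        if (!is.null(bias[[k]])) z[[k]] <- sweep(z[[k]], 2, bias[[k]], "+")
        a[[k + 1]] <- act$fn(z[[k]])
      }
      # backward: dL/da_L for L = mean over the batch of the per-sample
      # squared error summed over output nodes
      delta <- 2 * (a[[nl + 1]] - tb) / nrow(tb) * act$grad(a[[nl + 1]], z[[nl]])
      for (k in nl:1) {
        gW <- crossprod(a[[k]], delta)
        if (!is.null(bias[[k]])) bias[[k]] <- bias[[k]] - lr * colSums(delta)
        if (k > 1)
          delta <- (delta %*% t(W[[k]])) * act$grad(a[[k]], z[[k - 1]])
        W[[k]] <- W[[k]] - lr * gW
      }
    }
    if (epoch %in% config$schedule) record(epoch)
  }
  structure(list(checkpoints = checkpoints, losses = losses,
                 task_name = task$name, config = config,
                 architecture = arch),
            class = "ei_training_run")
}

#' Classification accuracy of a network on a task split
#'
#' @param net An `ei_network`.
#' @param task An `ei_task`.
#' @param split `"test"` (default) or `"train"`.
#' @return Fraction of samples whose argmax output matches the label.
#' @export
network_accuracy <- function(net, task, split = "test") {
  s <- task[[match.arg(split, c("test", "train"))]]
  pred <- max.col(network_forward(net, s$x), ties.method = "first")
  mean(pred == s$y)
}

#' @export
print.ei_training_run <- function(x, ...) {
  lf <- x$losses[nrow(x$losses), ]
  cat(sprintf("<ei_training_run> %s, %s epochs, %d checkpoints; final train/test MSE %.4f / %.4f\n",
              x$task_name, x$config$epochs, length(x$checkpoints),
              lf$train_loss, lf$test_loss))
  invisible(x)
}
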
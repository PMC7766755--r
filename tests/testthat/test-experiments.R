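test_that("synthetic tasks are balanced, bounded, reproducible, and validated", {
  t1 <- make_synthetic_task("iris_like", seed = 1)
  expect_equal(as.integer(table(t1$train$y)), rep(50, 3))
  expect_true(all(t1$train$x >= 0 & t1$train$x <= 1))
  expect_equal(dim(t1$train$x), c(150, 4))

  t1b <- make_synthetic_task("iris_like", seed = 1)
  expect_identical(t1$train$x, t1b$train$x)
  t1c <- make_synthetic_task("iris_like", seed = 2)
  expect_false(identical(t1$train$x, t1c$train$x))

  t2 <- make_synthetic_task("mnist_like", seed = 1, n_train = 500, n_test = 100)
  expect_equal(t2$n_features, 25)
  expect_equal(as.integer(table(t2$train$y)), rep(100, 5))
  expect_true(all(t2$train$x >= 0 & t2$train$x <= 1))

  expect_error(make_synthetic_task("cifar_like", seed = 1), "unknown task")
})

test_that("iris_like is mostly linearly separable while mnist_like is not", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nnet")
  t1 <- make_synthetic_task("iris_like", seed = 3)
  fit <- MASS::lda(t1$train$x, grouping = t1$train$y)
  acc_lin_iris <- mean(predict(fit, t1$test$x)$class == t1$test$y)
  expect_gte(acc_lin_iris, 0.9)

  t2 <- make_synthetic_task("mnist_like", seed = 3, n_train = 2000, n_test = 500)
  fit2 <- MASS::lda(t2$train$x, grouping = t2$train$y)
  acc_lin <- mean(predict(fit2, t2$test$x)$class == t2$test$y)
  mlp <- with_seed_test(1, nnet::nnet(t2$train$x, effectinfo:::one_hot(t2$train$y, 5),
                                      size = 10, maxit = 300, trace = FALSE))
  acc_mlp <- mean(max.col(predict(mlp, t2$test$x)) == t2$test$y)
  # a one-hidden-layer MLP beats the linear classifier by a clear margin
  expect_gt(acc_mlp, acc_lin + 0.03)
})

test_that("training is reproducible, learns, and respects degenerate settings", {
  task <- make_synthetic_task("iris_like", seed = 5)
  net <- init_network(c(4, 5, 5, 3), "sigmoid", seed = 5)

  # zero learning rate: weights unchanged at every checkpoint
  frozen <- train_network(net, task, train_config(3, 10, learning_rate = 0,
                                                  schedule = c(0, 3), seed = 1))
  expect_identical(frozen$checkpoints[["0"]]$layers[[1]]$weights,
                   frozen$checkpoints[["3"]]$layers[[1]]$weights)
  expect_identical(frozen$checkpoints[["3"]]$layers[[1]]$weights,
                   net$layers[[1]]$weights)

  # a short real run reduces the training loss and is seed-reproducible
  cfg <- train_config(300, 10, schedule = c(0, 100, 300), seed = 2)
  run1 <- train_network(net, task, cfg)
  run2 <- train_network(net, task, cfg)
  expect_identical(run1$losses, run2$losses)
  expect_lt(run1$losses$train_loss[3], run1$losses$train_loss[1])
  expect_equal(run1$checkpoints[["100"]]$meta$step, 100)

  # dimension mismatches are refused
  bad <- init_network(c(5, 5, 3), "sigmoid", seed = 1)
  expect_error(train_network(bad, task, cfg), "dimension mismatch")
  expect_error(train_config(10, 5, schedule = c(1, 10)), "schedule")
  expect_error(train_config(10, 5, schedule = c(0, 4)), "schedule")
})

test_that("backpropagation gradients match finite differences", {
  task <- make_synthetic_task("iris_like", seed = 9, n_train = 30, n_test = 9)
  net <- init_network(c(4, 3, 3), "sigmoid", seed = 9)
  x <- task$train$x
  tt <- effectinfo:::one_hot(task$train$y, 3)
  loss_at <- function(W) {
    a <- x
    for (k in seq_along(W)) a <- plogis(a %*% W[[k]])
    sum((a - tt)^2) / nrow(a)
  }
  W <- lapply(net$layers, `[[`, "weights")
  # one full-batch GD step with a tiny lr approximates -lr * gradient
  lr <- 1e-3
  run <- train_network(net, structure(list(name = "iris_like", n_features = 4,
                                           n_classes = 3, seed = 9,
                                           train = task$train, test = task$test),
                                      class = "ei_task"),
                       train_config(1, 30, learning_rate = lr, schedule = c(0, 1), seed = 1))
  W_after <- lapply(run$checkpoints[["1"]]$layers, `[[`, "weights")
  for (k in seq_along(W)) {
    g_step <- (W[[k]] - W_after[[k]]) / lr
    g_num <- W[[k]]
    eps <- 1e-6
    for (i in seq_len(nrow(W[[k]]))) for (j in seq_len(ncol(W[[k]]))) {
      Wp <- W; Wp[[k]][i, j] <- Wp[[k]][i, j] + eps
      Wm <- W; Wm[[k]][i, j] <- Wm[[k]][i, j] - eps
      g_num[i, j] <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
    }
    expect_equal(g_step, g_num, tolerance = 1e-4)
  }
})

test_that("trajectory tracking yields one row per step and layer, aligned with losses", {
  task <- make_synthetic_task("iris_like", seed = 4)
  net <- init_network(c(4, 5, 5, 3), "sigmoid", seed = 4)
  run <- train_network(net, task, train_config(100, 10, schedule = c(0, 10, 100), seed = 4))
  tr <- track_training(run, n_samples = 5e3, seed = 4)
  expect_equal(nrow(tr), 3 * 3) # 3 scheduled steps x 3 layer connections
  expect_setequal(unique(tr$step), c(0, 10, 100))
  expect_setequal(unique(tr$layer), 1:3)
  expect_false(any(is.na(tr$train_loss)))
  expect_identical(tr$degeneracy_bits, tr$sensitivity_bits - tr$ei_bits)

  # trained and untrained measurements differ
  first <- tr[tr$step == 0, "ei_bits"]
  last <- tr[tr$step == 100, "ei_bits"]
  expect_false(isTRUE(all.equal(first, last)))

  cp <- summarize_causal_plane(tr)
  expect_equal(nrow(cp), 3)
  expect_true(all(cp$path_length >= 0))
  cpl <- ei_loss_coupling(tr)
  expect_type(cpl$coincide, "logical")

  # convergence flags are reported when requested
  tr2 <- track_training(run, n_samples = 4e3, seed = 4, convergence_tol = 0.5)
  expect_type(tr2$converged, "logical")
})

test_that("the redundancy experiment with no extra layers reduces to the base run", {
  red <- redundancy_experiment("mnist_like", seed = 21, n_extra_hidden = 0,
                               epochs = 2, measure_samples = 3e3,
                               schedule = c(0L, 2L))
  expect_identical(red$base$experiment$trajectory, red$added$experiment$trajectory)
  expect_equal(red$comparison$variant, c("base", "removed", "added"))
  # removed variant has one layer fewer
  expect_equal(length(red$removed$experiment$run$checkpoints[[1]]$layers),
               length(red$base$experiment$run$checkpoints[[1]]$layers) - 1)
})
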
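#' Bundled synthetic classification tasks
#'
#' Two reproducible stand-in tasks whose dimensions, class counts and
#' separability character emulate the two benchmark settings the training
#' experiments are built around, with no external data:
#'
#' * `iris_like` — 4 features, 3 balanced classes drawn from diagonal
#'   Gaussian blobs in \[0,1\]^4; one class is well separated and the other
#'   two overlap slightly, so the classes are mostly linearly separable.
#' * `mnist_like` — 25 features, 5 balanced classes built like coarse
#'   digit images: sparse positive class templates with two
#'   "writing-style" variants per class, the second style bridging toward
#'   the next class's template (a degenerate many-to-few map), plus
#'   per-sample intensity variation and pixel noise. Class means alone
#'   mis-sort part of every class, so a linear classifier is materially
#'   worse than a small nonlinear network. The larger default training set
#'   (6000 samples) mirrors the many-updates-per-epoch character of the
#'   benchmark it stands in for.
#'
#' Features are clipped to \[0,1\], matching the first-layer perturbation
#' range convention.
#'
#' @param kind `"iris_like"` or `"mnist_like"`.
#' @param seed Integer seed; the same seed reproduces identical tables.
#' @param n_train,n_test Per-split sample counts (balanced across classes;
#'   rounded down to a multiple of the class count). Defaults: 150/60 for
#'   iris_like, 6000/500 for mnist_like.
#' @return An object of class `ei_task`: list with `name`, `n_features`,
#'   `n_classes`, `seed`, and `train`/`test` lists each holding a feature
#'   matrix `x` and an integer label vector `y` (1-based).
#' @examples
#' task <- make_synthetic_task("iris_like", seed = 1)
#' table(task$train$y)
#' @export
make_synthetic_task <- function(kind, seed, n_train = NULL, n_test = NULL) {
  if (!kind %in% c("iris_like", "mnist_like"))
    stop("unknown task kind '", kind, "' (expected iris_like or mnist_like)",
         call. = FALSE)
  if (kind == "iris_like") {
    n_train <- n_train %||% 150; n_test <- n_test %||% 60
    gen <- gen_iris_like; k <- 3L; d <- 4L
  } else {
    n_train <- n_train %||% 6000; n_test <- n_test %||% 500
    gen <- gen_mnist_like; k <- 5L; d <- 25L
  }
  train <- with_seed(derive_seed(seed, "task", kind, "train"), gen(n_train))
  test <- with_seed(derive_seed(seed, "task", kind, "test"), gen(n_test))
  structure(list(name = kind, n_features = d, n_classes = k, seed = seed,
                 train = train, test = test),
            class = "ei_task")
}

# three Gaussian blobs in [0,1]^4; class 1 separable, classes 2 and 3 close
gen_iris_like <- function(n) {
  means <- rbind(c(0.20, 0.70, 0.15, 0.10),
                 c(0.55, 0.45, 0.55, 0.55),
                 c(0.72, 0.38, 0.72, 0.78))
  sds <- c(0.06, 0.09, 0.09)
  per <- n %/% 3
  y <- rep(1:3, each = per)
  x <- do.call(rbind, lapply(1:3, function(c) {
    matrix(stats::rnorm(per * 4, mean = rep(means[c, ], each = per), sd = sds[c]),
           per, 4)
  }))
  list(x = pmin(pmax(x, 0), 1), y = y)
}

# Five template-based classes in [0,1]^25, in the style of coarse digit
# images: each class has two "writing-style" templates (sparse positive
# pixel patterns), the second being a bridge mixture toward the next
# class's template, so class means alone mis-sort part of every class (a
# degenerate many-to-few structure that trips up linear classifiers) while
# a small nonlinear network can bind both styles. Samples vary by a global
# intensity factor plus pixel noise.
gen_mnist_like <- function(n, bridge = 0.6, noise = 0.15, intensity_sd = 0.12) {
  k <- 5L; d <- 25L
  # fixed generator geometry (independent of the data stream)
  geom <- with_seed(20201218, {
    base <- lapply(1:k, function(c) stats::runif(d) * (stats::runif(d) < 0.4))
    lapply(1:k, function(c) list(
      t1 = base[[c]],
      t2 = (1 - bridge) * base[[c]] + bridge * base[[c %% k + 1]]))
  })
  per <- n %/% k
  y <- rep(1:k, each = per)
  x <- do.call(rbind, lapply(1:k, function(c) {
    pick <- sample(c(TRUE, FALSE), per, replace = TRUE) # style choice
    tm <- rbind(geom[[c]]$t1, geom[[c]]$t2)[2L - pick, , drop = FALSE]
    g <- pmax(stats::rnorm(per, 1, intensity_sd), 0.3)
    tm * g + matrix(stats::rnorm(per * d, sd = noise), per, d)
  }))
  list(x = pmin(pmax(x, 0), 1), y = y)
}

#' Load a task from CSV tables
#'
#' Adapter for user-supplied data: plain CSV with one column of integer
#' class labels and the remaining columns numeric features. Features are
#' expected in (or are min-max rescaled to) \[0,1\].
#'
#' @param train_csv,test_csv Paths to CSV files with a header row.
#' @param label_col Name of the label column (default `"label"`).
#' @param rescale If `TRUE` (default), min-max rescale features to \[0,1\]
#'   using the training-split ranges (test values clipped).
#' @return An `ei_task`.
#' @export
task_from_csv <- function(train_csv, test_csv, label_col = "label",
                          rescale = TRUE) {
  read_split <- function(path) {
    df <- utils::read.csv(path)
    if (!label_col %in% names(df))
      stop("no '", label_col, "' column in ", path, call. = FALSE)
    y <- as.integer(factor(df[[label_col]]))
    x <- as.matrix(df[setdiff(names(df), label_col)])
    storage.mode(x) <- "double"
    list(x = x, y = y)
  }
  train <- read_split(train_csv)
  test <- read_split(test_csv)
  if (rescale) {
    lo <- apply(train$x, 2, min); hi <- apply(train$x, 2, max)
    wd <- ifelse(hi - lo > 0, hi - lo, 1)
    scale01 <- function(x) pmin(pmax(sweep(sweep(x, 2, lo), 2, wd, "/"), 0), 1)
    train$x <- scale01(train$x); test$x <- scale01(test$x)
  }
  structure(list(name = "csv", n_features = ncol(train$x),
                 n_classes = max(train$y), seed = NA_integer_,
                 train = train, test = test),
            class = "ei_task")
}

#' @export
print.ei_task <- function(x, ...) {
  cat(sprintf("<ei_task> %s: %d features, %d classes, %d train / %d test samples\n",
              x$name, x$n_features, x$n_classes,
              length(x$train$y), length(x$test$y)))
  invisible(x)
}
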
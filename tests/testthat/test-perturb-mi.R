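test_that("discretization follows the edge, top-bin and clipping conventions", {
  sc <- binning_scheme(8, c(0, 1))
  expect_equal(as.integer(discretize(0.0, sc)), 0L)   # lower edge
  expect_equal(as.integer(discretize(1.0, sc)), 7L)   # top bin is closed
  expect_equal(as.integer(discretize(1.7, sc)), 7L)   # clipped above
  expect_equal(as.integer(discretize(-0.3, sc)), 0L)  # clipped below
  expect_equal(as.integer(discretize(0.999, sc)), 7L)
  expect_equal(as.integer(discretize(0.125, sc)), 1L) # half-open left edges
  # every in-range value maps to exactly one bin in [0, B)
  v <- seq(0, 1, length.out = 1001)
  b <- discretize(v, sc)
  expect_true(all(b >= 0 & b <= 7))
  expect_error(binning_scheme(8, c(0.5, 0.5)), "zero-width")
  expect_error(binning_scheme(0, c(0, 1)), "positive")
})

test_that("plug-in MI reproduces exact values on constructed distributions", {
  # identity channel, X uniform over 8 labels: exactly H(X) = 3 bits
  x <- rep(0:7, each = 100)
  est <- mutual_information(x, x)
  expect_equal(est$value_bits, 3)
  expect_equal(est$n_distinct_joint, 8L)

  # constant effect: exactly zero
  expect_identical(mutual_information(x, rep(1, length(x)))$value_bits, 0)

  # X uniform over {0..3}, Y = X mod 2: exact enumeration gives 1 bit
  x <- rep(0:3, each = 50)
  expect_equal(mutual_information(x, x %% 2)$value_bits, 1)

  # grouping labels loses H(X|Y) = 1 bit relative to identity
  x <- rep(0:7, each = 100)
  expect_equal(mutual_information(x, x %/% 2)$value_bits, 2)

  expect_error(mutual_information(numeric(0), numeric(0)), "empty")
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("intervention samples are in-range, reproducible, independent, and paired", {
  ly <- edge_layer("sigmoid", 1.5)
  ps <- sample_intervention(ly, intervention_config(1e5, seed = 7))
  expect_true(all(ps$inputs >= 0 & ps$inputs <= 1))
  expect_true(all(ps$outputs > 0 & ps$outputs < 1))

  ps2 <- sample_intervention(ly, intervention_config(1e5, seed = 7))
  expect_identical(ps$inputs, ps2$inputs)

  # tanh layer samples over (-1, 1); the two input columns are independent
  ly2 <- two_in_layer("tanh", 1, -1)
  ps3 <- sample_intervention(ly2, intervention_config(1e5, seed = 11))
  expect_true(all(ps3$inputs > -1 & ps3$inputs < 1))
  expect_lt(abs(cor(ps3$inputs[, 1], ps3$inputs[, 2])), 0.01)

  # outputs are exactly the forward image of the inputs
  expect_equal(ps3$outputs, layer_forward(ly2, ps3$inputs))

  expect_error(intervention_config(0, seed = 1), "positive")
})

test_that("EI obeys its bounds, symmetries and exact special cases", {
  # zero weight -> constant output -> EI exactly 0
  expect_identical(effective_information(edge_layer("sigmoid", 0), quick_cfg())$value_bits, 0)

  # relu identity edge: input and output bins coincide -> EI ~ log2(B)
  est <- effective_information(edge_layer("relu", 1), intervention_config(1e5, seed = 2),
                               n_bins = 16)
  expect_equal(est$value_bits, 4, tolerance = 0.01)

  # mirror symmetry of the sigmoid edge under w -> -w
  e_pos <- effective_information(edge_layer("sigmoid", 2), intervention_config(1e5, seed = 3))
  e_neg <- effective_information(edge_layer("sigmoid", -2), intervention_config(1e5, seed = 4))
  expect_equal(e_pos$value_bits, e_neg$value_bits, tolerance = 0.03)

  # upper bound min(n_in, n_out) * log2(B) for random layers, and
  # invariance under permuting input nodes together with weight rows
  for (s in 1:4) {
    ly <- random_layer(s, 3, 2)
    est <- effective_information(ly, intervention_config(3e4, seed = s), n_bins = 8)
    expect_lte(est$value_bits, 2 * log2(8))
    perm <- c(3, 1, 2)
    lyp <- feedforward_layer(ly$weights[perm, ], "sigmoid")
    estp <- effective_information(lyp, intervention_config(3e4, seed = s), n_bins = 8)
    expect_equal(est$value_bits, estp$value_bits, tolerance = 0.05)
  }
})

test_that("streamed batches and one-shot sampling give the same estimate structure", {
  ly <- two_in_layer("sigmoid", 1.2, -0.7)
  whole <- effective_information(ly, intervention_config(4e4, seed = 5, batch_size = 4e4))
  batched <- effective_information(ly, intervention_config(4e4, seed = 5, batch_size = 7000))
  # same sample budget, same seed policy; estimates agree to MC tolerance
  expect_equal(whole$value_bits, batched$value_bits, tolerance = 0.05)
  expect_equal(batched$n_samples, 4e4)
})

test_that("convergence control doubles the budget and flags the outcome", {
  ly <- edge_layer("sigmoid", 2)
  r <- converge_ei(ly, tol = 0.01, max_samples = 1e6, seed = 1, start_samples = 1e4)
  expect_true(r$converged)
  expect_lt(r$trace[nrow(r$trace), "n"], 1e6 + 1)
  # each schedule entry doubles the previous
  ns <- r$trace[, "n"]
  if (length(ns) > 1) expect_equal(ns[-1] / ns[-length(ns)], rep(2, length(ns) - 1))

  # budget smaller than two schedule points: flagged, not an error
  r2 <- converge_ei(ly, tol = 1e-6, max_samples = 2e4, seed = 1, start_samples = 1e4)
  expect_false(r2$converged)
  expect_error(converge_ei(ly, tol = 0), "tol")
})

test_that("Monte-Carlo EI matches the deterministic quadrature oracle", {
  for (act in c("sigmoid", "tanh", "relu")) {
    ly <- edge_layer(act, 1.7)
    mc <- effective_information(ly, intervention_config(2e5, seed = 9))
    qd <- quadrature_ei(ly)
    expect_equal(mc$value_bits, qd$value_bits, tolerance = 0.05, info = act)
  }
  ly2 <- two_in_layer("sigmoid", 2, -1)
  mc <- effective_information(ly2, intervention_config(2e5, seed = 9))
  qd <- quadrature_ei(ly2, total_cells = 1e6)
  expect_equal(mc$value_bits, qd$value_bits, tolerance = 0.05)
})
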
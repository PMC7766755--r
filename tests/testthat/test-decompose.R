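test_that("sensitivity equals EI for single-input layers and is exactly zero without edges", {
  # 1 -> 1: only one edge, no overlap, so sensitivity ~ EI
  ly <- edge_layer("sigmoid", 2.5)
  cfg <- intervention_config(1e5, seed = 3)
  s <- sensitivity(ly, cfg)
  e <- effective_information(ly, cfg)
  expect_equal(s$value_bits, e$value_bits, tolerance = 0.02)

  # all-zero weights: exact zero, no sampling at all
  z <- feedforward_layer(matrix(0, 3, 2), "sigmoid")
  expect_identical(sensitivity(z, cfg)$value_bits, 0)

  # 2 -> 1 with one zero edge: the zero edge contributes exactly nothing
  ly2 <- two_in_layer("sigmoid", 1.8, 0)
  s2 <- sensitivity(ly2, cfg)
  expect_identical(s2$per_edge[2, 1], 0)
  e1 <- effective_information(edge_layer("sigmoid", 1.8), cfg)
  expect_equal(s2$value_bits, e1$value_bits, tolerance = 0.02)
})

test_that("degeneracy and phi identities hold exactly by construction", {
  for (s in 1:4) {
    ly <- random_layer(s, 3, 2)
    res <- measure_layer(ly, intervention_config(2e4, seed = s))
    expect_identical(res$degeneracy_bits, res$sensitivity_bits - res$ei_bits)
    expect_identical(res$phi_feedforward_bits, res$ei_bits - res$ei_parts_bits)
    expect_gte(res$sensitivity_bits, 0)
    expect_gte(res$ei_parts_bits, 0)
  }
})

test_that("overlapping connectivity is degenerate; isolated connectivity is not", {
  cfg <- intervention_config(1e5, seed = 6)
  # two equal large weights into one node: pre-image reconstruction is
  # ambiguous -> positive degeneracy (verified against the quadrature oracle)
  ly <- two_in_layer("sigmoid", 3, 3)
  res <- measure_layer(ly, cfg)
  expect_gt(res$degeneracy_bits, 0.2)
  qd <- quadrature_ei(ly, total_cells = 1e6)
  expect_equal(res$ei_bits, qd$value_bits, tolerance = 0.05)

  # one-to-one diagonal relu: each node has a unique edge, so phi ~ 0 and
  # degeneracy ~ 0
  diag_ly <- feedforward_layer(diag(2), "relu")
  resd <- measure_layer(diag_ly, cfg)
  expect_lt(abs(resd$phi_feedforward_bits), 0.02)
  expect_lt(abs(resd$degeneracy_bits), 0.02)

  # all-zero weights: every component exactly zero
  z <- feedforward_layer(matrix(0, 2, 2), "tanh")
  resz <- measure_layer(z, cfg)
  expect_identical(resz$ei_bits, 0)
  expect_identical(resz$sensitivity_bits, 0)
  expect_identical(resz$ei_parts_bits, 0)
  expect_identical(resz$phi_feedforward_bits, 0)
})

test_that("EI_parts equals EI for single-edge layers and phi detects joint effects", {
  cfg <- intervention_config(1e5, seed = 8)
  # single output node fed by a single edge: EI and EI_parts are computed
  # from the very same samples, so they agree exactly
  ly <- edge_layer("tanh", 1.3)
  res <- measure_layer(ly, cfg)
  expect_equal(res$ei_parts_bits, res$ei_bits, tolerance = 1e-12)
  expect_equal(res$phi_feedforward_bits, 0, tolerance = 1e-12)

  # XOR-like construction: output depends jointly on both inputs, pairwise
  # MIs are small, so phi > 0
  xor_ly <- two_in_layer("tanh", 10, -10)
  resx <- measure_layer(xor_ly, cfg)
  expect_gt(resx$phi_feedforward_bits, 0.5)
  # the joint EI itself is confirmed by the oracle
  qd <- quadrature_ei(xor_ly, total_cells = 1e6)
  expect_equal(resx$ei_bits, qd$value_bits, tolerance = 0.05)
})

test_that("single-edge EI curve has the rise-and-decay shape with a located argmax", {
  cv <- ei_curve_single_edge("sigmoid", c(0.5, 1, 1.5, 2, 4, 6, 8),
                             n_samples = 1e5, seed = 2)
  ei <- cv$ei_bits
  # increasing on [0.5, 2]
  expect_true(all(diff(ei[1:4]) > 0))
  # decreasing on [4, 8]
  expect_true(all(diff(ei[5:7]) < 0))
  expect_equal(attr(cv, "argmax"), cv$weight[which.max(cv$ei_bits)])
  expect_error(ei_curve_single_edge("sigmoid", numeric(0)), "empty")
})

test_that("two-input manifolds have the expected symmetries and exact identity", {
  g <- c(-2, -1, 0, 1, 2)
  mf <- ei_manifold_two_inputs("sigmoid", g, g, n_samples = 4e4, seed = 3)
  expect_equal(nrow(mf), 25)
  # pointwise identity EI = sensitivity - degeneracy, exact
  expect_identical(mf$degeneracy_bits, mf$sensitivity_bits - mf$ei_bits)
  # origin: all three surfaces zero
  o <- mf[mf$wA == 0 & mf$wB == 0, ]
  expect_identical(o$ei_bits, 0)
  expect_identical(o$sensitivity_bits, 0)
  # swap symmetry (wA, wB) <-> (wB, wA) for identical input ranges
  for (k in seq_len(nrow(mf))) {
    tw <- mf[mf$wA == mf$wB[k] & mf$wB == mf$wA[k], ]
    expect_equal(mf$ei_bits[k], tw$ei_bits, tolerance = 0.1)
  }
  # sign-flip (approximate two-fold) symmetry of the sigmoid manifold
  for (k in seq_len(nrow(mf))) {
    fl <- mf[mf$wA == -mf$wA[k] & mf$wB == -mf$wB[k], ]
    expect_equal(mf$ei_bits[k], fl$ei_bits, tolerance = 0.12)
  }
})

test_that("causal-plane projection is a pure extraction", {
  ly <- edge_layer("sigmoid", 2)
  res <- measure_layer(ly, intervention_config(5e4, seed = 4), step = 10, layer_id = 1)
  pt <- causal_plane_point(res)
  expect_equal(pt$degeneracy, res$sensitivity_bits - res$ei_bits)
  expect_equal(pt$sensitivity, res$sensitivity_bits)
  expect_equal(pt$step, 10)
  # single edge: no overlap, point sits at ~ (0, EI)
  expect_lt(abs(pt$degeneracy), 0.02)
  expect_equal(pt$sensitivity, res$ei_bits, tolerance = 0.02)

  # algebraic example: sensitivity 3.1, EI 2.0 -> point (1.1, 3.1)
  fake <- res
  fake$sensitivity_bits <- 3.1
  fake$ei_bits <- 2.0
  fake$degeneracy_bits <- 3.1 - 2.0
  pt2 <- causal_plane_point(fake)
  expect_equal(unlist(pt2[c("degeneracy", "sensitivity")]),
               c(degeneracy = 1.1, sensitivity = 3.1))

  expect_equal(nullcline_distance(c(2, 1), c(2, 3)), c(0, sqrt(2)))
  expect_equal(causal_path_length(c(0, 3), c(0, 7)), sqrt(9 + 49))
})
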
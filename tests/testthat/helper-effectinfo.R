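# shared fixtures: tiny layers and measurement configs built in code

edge_layer <- function(activation, w) {
  feedforward_layer(matrix(w, 1, 1), activation)
}

two_in_layer <- function(activation, wA, wB) {
  feedforward_layer(matrix(c(wA, wB), 2, 1), activation)
}

quick_cfg <- function(n = 2e4, seed = 1) intervention_config(n, seed = seed)

# small random layer generator for property-style loops
random_layer <- function(seed, n_in = 3, n_out = 2, activation = "sigmoid") {
  w <- with_seed_test(seed, matrix(stats::runif(n_in * n_out, -2, 2), n_in, n_out))
  feedforward_layer(w, activation)
}

# memoized single-edge curves so acceptance checks that share a grid do not
# recompute identical Monte-Carlo scans
.curve_cache <- new.env(parent = emptyenv())
cached_curve <- function(activation, weights, n_bins, n_samples, seed = 1) {
  key <- paste(activation, n_bins, n_samples, seed,
               weights[1], weights[length(weights)], length(weights), sep = "|")
  if (is.null(.curve_cache[[key]])) {
    .curve_cache[[key]] <- ei_curve_single_edge(activation, weights,
                                                n_bins = n_bins,
                                                n_samples = n_samples,
                                                seed = seed)
  }
  .curve_cache[[key]]
}

# memoized experiment runs shared by the qualitative acceptance checks
.exp_cache <- new.env(parent = emptyenv())
cached_experiment <- function(kind, seed, measure_samples = 3e4) {
  key <- paste(kind, seed, measure_samples, sep = "|")
  if (is.null(.exp_cache[[key]])) {
    .exp_cache[[key]] <- run_experiment(kind, seed,
                                        measure_samples = measure_samples)
  }
  .exp_cache[[key]]
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
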
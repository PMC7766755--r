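#' Derive a reproducible sub-stream seed
#'
#' Expands one master seed into named, independent sub-stream seeds so that
#' adding a measurement (e.g. one more perturbation) never perturbs the
#' random stream of another stage (initialization, data generation,
#' shuffling, ...). The derivation is a deterministic polynomial rolling
#' hash of the master seed together with an arbitrary sequence of labels,
#' reduced modulo a prime below 2^31 so the result is always a valid R
#' integer seed.
#'
#' @param master Integer master seed.
#' @param ... Labels (character or numeric) naming the sub-stream, e.g.
#'   `derive_seed(7, "perturb", layer = 2, step = 100)`.
#' @return A positive integer seed, strictly below 2^31.
#' @examples
#' derive_seed(1, "init")
#' derive_seed(1, "measure", 3, 250)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), unlist(lapply(list(...), as.character))),
               collapse = "/")
  p <- 2147483629 # prime < 2^31
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% p
  as.integer(h %% (p - 1L) + 1L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
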
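# Deterministic derivation of sub-stream seeds from one master seed, so
# that e.g. subject k's draws do not change when more subjects are added,
# and per-fold inner-CV assignments are reproducible. Arithmetic is done in
# doubles (exact below 2^53) and reduced mod 2^31 - 1 to stay a valid R seed.
derive_seed <- function(master, stream) {
  m <- 2147483647
  x <- (as.numeric(master) %% m + m) %% m
  x <- (x * 48271 + 11) %% m
  x <- (x + (as.numeric(stream) * 2654435761) %% m) %% m
  x <- (x * 69621 + 1) %% m
  as.integer(x)
}

# run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @importFrom stats predict
#' @importFrom utils head
NULL
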
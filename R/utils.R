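# internal helpers: RNG stream bookkeeping and numerics

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(1 + exp(x)); accurate for |x| up to ~700
softplus <- function(x) {
  out <- numeric(length(x))
  hi <- x > 30
  out[hi] <- x[hi] + log1p(exp(-x[hi]))
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

# make sure .Random.seed exists before we capture it
ensure_rng <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  invisible(NULL)
}

rng_state <- function() {
  ensure_rng()
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# draw n sub-seeds from the current RNG stream (kept below 2^31)
derive_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  ensure_rng()
  invisible(NULL)
}
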
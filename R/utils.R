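#' @importFrom methods as is
#' @importFrom stats cor cor.test rnorm runif sd var t.test
#' @importFrom utils write.table read.table modifyList
NULL

# Derive a reproducible 32-bit sub-seed from a base seed and a named stream.
# All randomness in the package flows from one run seed through these
# substreams so that e.g. subject 3's warp does not depend on how many
# sessions subject 2 drew.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 + h * 7919 + index * 104729) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
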
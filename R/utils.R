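#' @importFrom stats cor lm coef oneway.test optimize pf pt qnorm qt rnorm sd var
NULL

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Composite-Simpson nodes/weights on [-h/2, h/2] (n must be even).
simpson_rule <- function(width, n = 512L) {
  stopifnot(n %% 2L == 0L)
  x <- seq(-width / 2, width / 2, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  w <- w / sum(w)  # normalised so sum(w * f(x)) is the mean of f
  list(nodes = x, weights = w)
}

# FNV-1a hash of a JSON-serialisable object; used only for provenance stamps.
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
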
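# Internal helpers shared across modules.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Largest-remainder apportionment of n items into round(n * frac) counts
# that sum exactly to n.
apportion <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

tpName <- function(t) paste0("t", t)

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
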
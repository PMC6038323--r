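# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library calls never disturb user RNG.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic, locale-independent sort
sort_c <- function(x) sort(x, method = "radix")

# 1-based lexicographic rank of each element (C locale)
lex_rank <- function(x) {
  r <- integer(length(x))
  r[order(x, method = "radix")] <- seq_along(x)
  r
}

pair_key <- function(source, target) paste(source, target, sep = "\x1f")

`%||%` <- function(a, b) if (is.null(a)) b else a
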
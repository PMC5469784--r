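# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a string; used to derive independent per-arm
# seeds from a master seed so that adding an arm to a grid never perturbs
# another arm's random stream.
string_seed <- function(...) {
  s <- paste(..., sep = "|")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147480009
  as.integer(h)
}

# Split `total` into integer parts proportional to non-negative `weights`
# (largest-remainder rounding; ties broken by position order).
largest_remainder <- function(total, weights) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum to > 0")
  exact <- total * weights / sum(weights)
  parts <- floor(exact)
  short <- total - sum(parts)
  if (short > 0) {
    ord <- order(exact - parts, decreasing = TRUE)  # stable: ties keep order
    parts[ord[seq_len(short)]] <- parts[ord[seq_len(short)]] + 1
  }
  as.integer(parts)
}
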
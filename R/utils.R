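# Internal helpers: classed conditions, seed handling, small numerics.

# Signal a classed error so callers can test for specific failure modes
# (e.g. "plvnet_invalid_band") rather than matching message strings.
plv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("plvnet_", class), "plvnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

plv_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("plvnet_", class), "plvnet_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic code in the package funnels
# through this so one master seed reproduces everything.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a parent seed and a label, so
# per-subject / per-stage streams are independent of evaluation order.
# Keeps results inside [1, 2^31 - 2] (R seeds are 32-bit signed).
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(x) else as.numeric(x)
  })))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% m) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
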
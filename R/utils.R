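# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a small deterministic sub-seed from a base seed and stream index,
# kept well inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 1e6) * 2011 + index * 7919) %% 2147483647L
}

usage_error <- function(...) {
  stop(structure(
    class = c("hse_usage_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
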
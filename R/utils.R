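#' @keywords internal
"_PACKAGE"

# Classed conditions: input errors (bad data) vs configuration errors (bad
# settings), so callers can distinguish them programmatically.
abort_input <- function(msg) {
  stop(structure(
    class = c("emofuse_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(msg) {
  stop(structure(
    class = c("emofuse_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-trial child seed from a root seed; kept below 2^31 - 1.
derive_seed <- function(root, index) {
  (as.numeric(root) * 7919 + as.numeric(index) * 104729) %% 2147483629
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
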
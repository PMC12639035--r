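# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_config <- function(...) {
  stop(structure(
    class = c("climladder_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_validation <- function(...) {
  stop(structure(
    class = c("climladder_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_wholenumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Derive a stream of sub-seeds from one master seed, keeping them < 2^31.
derive_seeds <- function(seed, n, offset = 0L) {
  (as.integer(seed) + offset + 104729L * seq_len(n)) %% 2147483579L
}
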
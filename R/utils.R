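# internal numerics shared across modules

# row-wise log(sum(exp(x))) without overflow
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# floor applied to Poisson rates so all-zero groups stay finite
RATE_FLOOR <- 1e-10

stop_arg <- function(...) stop(..., call. = FALSE)
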
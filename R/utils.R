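# internal helpers shared across modules

# derive a reproducible child seed from a base seed and a few small indices;
# kept strictly below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) + sum(as.double(idx) * 10007^seq_along(idx))) %% 2147483629
  as.integer(s)
}

# numerically stable log(sum(exp(x))) over matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(lower)))
  }
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
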
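# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# seed the global RNG stream when a seed is supplied (NULL = leave alone)
set_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is_number(seed)) stopf("seed must be a single finite number")
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# raw (unscaled) median absolute deviation, the convention used for
# median +/- MAD summaries throughout
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

# truncated-normal sampler (lower bound only), vectorised rejection
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}
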
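# internal helpers shared across modules

# counts -> transcripts-per-million; x: numeric vector of counts (or any
# abundance proportional to reads), len: effective lengths in nt
tpm_from_counts <- function(x, len) {
  stopifnot(length(x) == length(len), all(len > 0))
  rate <- x / len
  rate / sum(rate) * 1e6
}

# scale a vector of non-negative values so it sums to 1e6 (TPM convention)
scale_to_tpm <- function(x) {
  s <- sum(x)
  if (s <= 0) abort("cannot TPM-normalise a column with non-positive total")
  x / s * 1e6
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1 && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number",
                  name, if (strict) "positive" else "non-negative"))
  }
  invisible(as.numeric(x))
}

# NB sampling parameterised by mean and dispersion alpha, var = mu + alpha mu^2;
# alpha -> 0 degenerates to Poisson
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / alpha)
}

log2_ratio <- function(num, den, pseudo = 0.5) {
  log2((num + pseudo) / (den + pseudo))
}
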
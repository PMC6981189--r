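# Internal numeric helpers shared across modules.

# Pearson correlation that returns 0 (not NA) for zero-variance input.
safe_cor <- function(x, y, method = "pearson") {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  out <- stats::cor(x, y, method = method)
  if (!is.finite(out)) 0 else out
}

# Column-wise correlation matrix between two numeric matrices, with
# zero-variance columns mapped to 0 instead of NA.
safe_cor_matrix <- function(X, Y, method = "pearson") {
  stopifnot(nrow(X) == nrow(Y))
  out <- suppressWarnings(stats::cor(X, Y, method = method))
  out[!is.finite(out)] <- 0  # zero-variance columns yield NA in cor()
  out
}

# z-score columns by supplied (training) centre/scale; zero scales become 1.
standardise_cols <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || x < 0 || x != round(x)) {
    abort(paste0("`", name, "` must be a single non-negative integer"))
  }
  as.integer(x)
}

# Derive a 32-bit sub-seed from a base seed and a stream index, so that
# independent artifacts drawn from one user seed do not share streams.
sub_seed <- function(seed, k) {
  # double arithmetic: exact below 2^53, immune to integer overflow
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2147483629)
}
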
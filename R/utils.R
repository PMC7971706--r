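# Internal helpers shared by the plug-in estimators.

# 0-based mixed-radix code for a list of symbol columns, all in 1..A.
# Codes are kept as doubles so that alphabets up to A^k > 2^31 do not
# overflow; callers that tabulate convert back when the range is small.
tuple_code0 <- function(cols, A) {
  code <- as.double(cols[[1]]) - 1
  mult <- 1
  for (j in seq_along(cols)[-1]) {
    mult <- mult * A
    code <- code + (as.double(cols[[j]]) - 1) * mult
  }
  code
}

# Shannon entropy (bits) of the empirical distribution of a 0-based code
# vector with `nbins` possible values. tabulate() is used when the range
# is small; otherwise codes are matched against their unique values.
entropy_code0 <- function(code, nbins) {
  n <- length(code)
  if (n == 0L) return(0)
  if (nbins <= 2^20) {
    cnt <- tabulate(as.integer(code) + 1L, nbins = as.integer(nbins))
  } else {
    cnt <- tabulate(match(code, unique(code)))
  }
  cnt <- cnt[cnt > 0]
  p <- cnt / n
  -sum(p * log2(p))
}

# Column of symbols at lag l for the eligible samples t = (L+1):n.
# l = 0 gives the target column x_t itself.
lag_column <- function(x, l, L) {
  n <- length(x)
  x[(L + 1L - l):(n - l)]
}

# Entropy (bits) of a vector of counts or probabilities.
entropy_p <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
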
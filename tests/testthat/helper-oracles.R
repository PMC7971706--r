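# Independent brute-force oracles used to pin down expected values.
# These deliberately use naive table()/loop implementations, not the
# package's coded-tuple estimators.

oracle_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# joint relative frequencies of (x_t, x_{t-l1}, ...) over t = max(lags)+1..n,
# as a named vector keyed by the pasted tuple
oracle_tuple_freqs <- function(x, lags) {
  L <- if (length(lags)) max(lags) else 0
  idx <- (L + 1):length(x)
  key <- vapply(idx, function(t) {
    paste(c(x[t], x[t - lags]), collapse = "-")
  }, character(1))
  table(key) / length(idx)
}

# conditional entropy H(X_t | X_{t-1}) from exhaustive frequency tables
oracle_gte <- function(x) {
  n <- length(x)
  joint <- table(factor(x[2:n]), factor(x[1:(n - 1)])) / (n - 1)
  prev <- table(factor(x[1:(n - 1)])) / (n - 1)
  oracle_entropy(as.vector(joint)) - oracle_entropy(as.vector(prev))
}

# mutual information I(X_t; past tuple at `lags`) on t = max(lags)+1..n
oracle_ais <- function(x, lags) {
  L <- max(lags)
  idx <- (L + 1):length(x)
  tgt <- x[idx]
  past <- vapply(idx, function(t) paste(x[t - lags], collapse = "-"),
                 character(1))
  joint <- table(tgt, past) / length(idx)
  oracle_entropy(as.vector(table(tgt))) +
    oracle_entropy(as.vector(table(past))) -
    oracle_entropy(as.vector(joint))
}

# CMI I(X_{t-cand}; X_t | X_{t-cond...}) from exhaustive 3-way tables,
# on the eligible set t = max(cand, cond)+1..n
oracle_cmi <- function(x, cand, cond) {
  L <- max(c(cand, cond))
  idx <- (L + 1):length(x)
  tgt <- x[idx]
  cc <- x[idx - cand]
  zz <- if (length(cond)) {
    vapply(idx, function(t) paste(x[t - cond], collapse = "-"), character(1))
  } else {
    rep("_", length(idx))
  }
  n <- length(idx)
  h <- function(...) oracle_entropy(as.vector(table(...)))
  h(paste(tgt, zz)) + h(paste(cc, zz)) - h(paste(tgt, cc, zz)) - h(zz)
}

# local values at each eligible t from exhaustively counted tables
oracle_local <- function(x, lags) {
  L <- max(lags)
  idx <- (L + 1):length(x)
  n_eff <- length(idx)
  tgt <- x[idx]
  past <- vapply(idx, function(t) paste(x[t - lags], collapse = "-"),
                 character(1))
  jkey <- paste(tgt, past)
  cj <- table(jkey)[jkey]
  cp <- table(past)[past]
  ct <- table(tgt)[as.character(tgt)]
  tibble::tibble(
    t = idx,
    lais = log2((as.vector(cj) / as.vector(cp)) / (as.vector(ct) / n_eff)),
    h_local = -log2(as.vector(ct) / n_eff),
    h_joint = -log2(as.vector(cj) / n_eff)
  )
}

# Spearman rank correlation via the rank formula with average ties
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# small fixation-table fixture
make_fix_table <- function(aoi, onset = seq_along(aoi),
                           duration_ms = rep(300, length(aoi)),
                           confidence = rep(1, length(aoi)),
                           participant = "p1", session = "s1") {
  tibble::tibble(
    participant = participant, session = session, onset = onset,
    duration_ms = duration_ms, aoi = aoi, confidence = confidence
  )
}

make_events <- function(onset, lane_change, end,
                        difficulty = rep("easy", length(onset)),
                        valid = rep(TRUE, length(onset)),
                        participant = NULL) {
  ev <- tibble::tibble(
    trial_id = seq_along(onset), onset = onset, lane_change = lane_change,
    end = end, difficulty = difficulty, valid = valid
  )
  if (!is.null(participant)) ev$participant <- participant
  ev
}
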
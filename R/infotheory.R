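#' Plug-in joint distribution of a fixation and its lagged past
#'
#' Estimates the joint distribution of the tuple
#' `(x_t, x_{t-l1}, ..., x_{t-lk})` by relative frequencies over all
#' time points with a complete past, i.e. `t = max(lags)+1, ..., n`.
#' With an empty lag set the marginal distribution of `x_t` over all
#' `t` is returned.
#'
#' @param path A [scanpath()] (or integer vector, see [as_scanpath()]).
#' @param lags Strictly increasing positive integer lags.
#' @param A Alphabet size used when `path` is a bare vector.
#' @return A tibble of class `"gaze_joint_dist"` with one row per
#'   observed tuple: columns `x_t`, `x_tm<lag>` for every lag, `n`
#'   (count) and `p` (relative frequency); attributes `n_eff`, `A` and
#'   `lags`.
#' @export
plugin_distribution <- function(path, lags = integer(), A = 8) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  lags <- check_lags(lags, allow_empty = TRUE)
  n <- length(path)
  L <- if (length(lags)) max(lags) else 0L
  if (n <= L) {
    stop(sprintf("insufficient data: path length %d <= max lag %d", n, L),
         call. = FALSE)
  }
  x <- unclass(path)
  cols <- c(list(x_t = lag_column(x, 0L, L)),
            stats::setNames(
              lapply(lags, function(l) lag_column(x, l, L)),
              if (length(lags)) paste0("x_tm", lags) else character()
            ))
  out <- dplyr::count(tibble::as_tibble(cols), dplyr::across(
    dplyr::everything()
  ))
  out$p <- out$n / sum(out$n)
  attr(out, "n_eff") <- n - L
  attr(out, "A") <- A
  attr(out, "lags") <- lags
  class(out) <- c("gaze_joint_dist", class(out))
  out
}

check_lags <- function(lags, allow_empty = FALSE, l_max = NULL) {
  lags <- as.integer(lags)
  if (!length(lags)) {
    if (allow_empty) return(integer()) else
      stop("at least one lag is required", call. = FALSE)
  }
  if (anyNA(lags) || any(lags < 1L)) {
    stop("lags must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(lags)) stop("lags must be unique", call. = FALSE)
  if (is.unsorted(lags)) lags <- sort(lags)
  if (!is.null(l_max) && any(lags > l_max)) {
    stop(sprintf("lags must not exceed l_max = %d", l_max), call. = FALSE)
  }
  lags
}

#' Shannon entropy in bits
#'
#' Computes `-sum(p * log2(p))` with the convention `0 * log(0) = 0`.
#'
#' @param dist A `"gaze_joint_dist"` (from [plugin_distribution()]) or a
#'   numeric probability vector summing to 1.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(1 / 8, 8)) # 3 bits
#' @export
shannon_entropy <- function(dist) {
  if (inherits(dist, "gaze_joint_dist")) {
    p <- dist$p
  } else if (is.numeric(dist)) {
    p <- dist
  } else {
    stop("`dist` must be a gaze_joint_dist or a numeric probability vector",
         call. = FALSE)
  }
  if (any(p < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  entropy_p(p)
}

#' Gaze transition entropy (GTE)
#'
#' The conditional entropy of the current fixation given the immediately
#' preceding one, `H(X_t | X_{t-1}) = H(X_t, X_{t-1}) - H(X_{t-1})`,
#' estimated by plug-in over all transitions `t = 2, ..., n`. Low values
#' indicate regular, predictable transitions; high values erratic ones.
#' GTE presumes a first-order Markov chain: information carried by
#' fixations further in the past is ignored.
#'
#' @inheritParams plugin_distribution
#' @return GTE in bits.
#' @export
gaze_transition_entropy <- function(path, A = 8) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  n <- length(path)
  if (n < 2L) stop("insufficient data: GTE requires at least 2 fixations",
                   call. = FALSE)
  x <- unclass(path)
  tgt <- lag_column(x, 0L, 1L)
  prev <- lag_column(x, 1L, 1L)
  joint <- tuple_code0(list(tgt, prev), A)
  entropy_code0(joint, A^2) - entropy_code0(prev - 1, A)
}

#' Active information storage (AIS)
#'
#' The mutual information between the next fixation and its past state,
#' `I(X_t^-; X_t) = H(X_t) + H(X_t^-) - H(X_t, X_t^-)`, where the past
#' state `X_t^-` collects the fixations at the given lags. All three
#' entropies are plug-in estimates over the same eligible samples,
#' `t = max(min_history, max(lags)) + 1, ..., n`. AIS is a direct
#' measure of scan-path predictability: zero for memoryless sequences,
#' up to `min(H(X_t), H(X_t^-))` for perfectly predictable ones.
#'
#' @inheritParams plugin_distribution
#' @param min_history Controls the eligible-sample convention: samples
#'   with `t > max(min_history, max(lags))` enter the estimate. The
#'   default (`max(lags)`) uses every sample with a complete past;
#'   passing a larger value forces a common sample set when comparing
#'   lag sets of different depth.
#' @return AIS in bits (0, with a warning, for an empty lag set).
#' @export
active_information_storage <- function(path, lags, A = 8,
                                       min_history = NULL) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  lags <- check_lags(lags, allow_empty = TRUE)
  if (!length(lags)) {
    warning("empty lag set: AIS is defined as 0", call. = FALSE)
    return(0)
  }
  L <- max(c(max(lags), min_history %||% 0L))
  n <- length(path)
  if (n <= L) {
    stop(sprintf("insufficient data: path length %d <= history %d", n, L),
         call. = FALSE)
  }
  x <- unclass(path)
  tgt <- lag_column(x, 0L, L)
  past <- tuple_code0(lapply(lags, function(l) lag_column(x, l, L)), A)
  k_past <- A^length(lags)
  joint <- (tgt - 1) + A * past
  entropy_code0(tgt - 1, A) + entropy_code0(past, k_past) -
    entropy_code0(joint, A * k_past)
}

#' Stationary gaze entropy (SGE)
#'
#' Shannon entropy of the marginal AOI distribution: a measure of the
#' overall spatial dispersion of gaze, between 0 (all fixations in one
#' AOI) and `log2(A)` (uniform use of all AOIs).
#'
#' @inheritParams plugin_distribution
#' @return SGE in bits.
#' @export
stationary_gaze_entropy <- function(path, A = 8) {
  path <- as_scanpath(path, A)
  entropy_p(tabulate(unclass(path), nbins = alphabet_size(path)))
}

#' Conditional mutual information between a lagged fixation and the next
#'
#' Plug-in estimate of `I(X_{t-candidate}; X_t | X_conditioning)`, the
#' additional information a candidate past fixation provides about the
#' next fixation beyond an already selected conditioning set. This is
#' the selection statistic of the greedy embedding optimization.
#'
#' @inheritParams active_information_storage
#' @param candidate_lag Positive integer lag, not in `conditioning`.
#' @param conditioning Integer vector of conditioning lags (may be
#'   empty, in which case plain mutual information is returned).
#' @return CMI in bits (plug-in CMI is non-negative).
#' @export
conditional_mutual_information <- function(path, candidate_lag,
                                           conditioning = integer(), A = 8,
                                           min_history = NULL) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  candidate_lag <- as.integer(candidate_lag)
  stopifnot(length(candidate_lag) == 1L, candidate_lag >= 1L)
  conditioning <- check_lags(conditioning, allow_empty = TRUE)
  if (candidate_lag %in% conditioning) {
    stop("`candidate_lag` must not be in `conditioning`", call. = FALSE)
  }
  L <- max(c(candidate_lag, conditioning, min_history %||% 0L))
  n <- length(path)
  if (n <= L) {
    stop(sprintf("insufficient data: path length %d <= history %d", n, L),
         call. = FALSE)
  }
  x <- unclass(path)
  tgt <- lag_column(x, 0L, L) - 1
  cand <- lag_column(x, candidate_lag, L) - 1
  if (length(conditioning)) {
    cond <- tuple_code0(lapply(conditioning, function(l) lag_column(x, l, L)),
                        A)
    k_cond <- A^length(conditioning)
  } else {
    cond <- numeric(length(tgt))
    k_cond <- 1
  }
  cmi_code0(tgt, cand, cond, A, k_cond)
}

# CMI from 0-based target/candidate symbols and a 0-based conditioning
# code with cardinality k_cond. Shared by the public estimator and the
# permutation test (which permutes `cand` only).
cmi_code0 <- function(tgt, cand, cond, A, k_cond) {
  h_tc <- entropy_code0(tgt + A * cond, A * k_cond)
  h_cc <- entropy_code0(cand + A * cond, A * k_cond)
  h_tcc <- entropy_code0(tgt + A * cand + A * A * cond, A * A * k_cond)
  h_c <- entropy_code0(cond, k_cond)
  h_tc + h_cc - h_tcc - h_c
}

#' Per-fixation (local) information measures
#'
#' Evaluates the local active information storage, local gaze transition
#' entropy, local entropy and local joint entropies at every fixation of
#' the scan path. The underlying probability distributions are plug-in
#' estimates from *all* eligible samples of the path (the measures are
#' local in what they evaluate, global in what they are estimated from):
#'
#' * `lais(t) = log2( p(x_t | x_t^-) / p(x_t) )` for the given lag set
#'   (may be negative: a misinformative past);
#' * `lgte(t) = -log2 p(x_t | x_{t-1})`, always the lag-1 conditional
#'   regardless of the lag set — this is the deliberate comparison
#'   design between the two measures;
#' * `h_local(t) = -log2 p(x_t)`;
#' * `h_joint_ais(t) = -log2 p(x_t, x_t^-)` and
#'   `h_joint_gte(t) = -log2 p(x_t, x_{t-1})`, used downstream to
#'   normalize period averages.
#'
#' LAIS-side values are defined from `t = max(lags) + 1` on and `NA`
#' before; LGTE-side values from `t = 2` on. The mean of each local
#' series equals the corresponding global measure on the same eligible
#' samples. With an empty lag set (no predictive past found) the
#' LAIS-side columns are `NA` and `h_local` is estimated from the full
#' marginal.
#'
#' @inheritParams active_information_storage
#' @return A tibble of class `"gaze_local_measures"` with columns `t`,
#'   `aoi`, `lais`, `lgte`, `h_local`, `h_joint_ais`, `h_joint_gte`,
#'   plus attributes `lags`, `ais` and `gte`.
#' @export
local_measures <- function(path, lags, A = 8) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  lags <- check_lags(lags, allow_empty = TRUE)
  n <- length(path)
  if (n < 2L) stop("insufficient data: need at least 2 fixations",
                   call. = FALSE)
  x <- unclass(path)

  out <- tibble::tibble(
    t = seq_len(n), aoi = x,
    lais = NA_real_, lgte = NA_real_, h_local = NA_real_,
    h_joint_ais = NA_real_, h_joint_gte = NA_real_
  )

  # LGTE side: lag-1 transition distribution over t = 2..n
  idx1 <- 2:n
  tgt1 <- x[idx1]
  prev1 <- x[idx1 - 1L]
  n1 <- length(idx1)
  cnt_joint1 <- tabulate((tgt1 - 1L) + A * (prev1 - 1L) + 1L, nbins = A * A)
  cnt_prev1 <- tabulate(prev1, nbins = A)
  cj1 <- cnt_joint1[(tgt1 - 1L) + A * (prev1 - 1L) + 1L]
  cp1 <- cnt_prev1[prev1]
  out$lgte[idx1] <- -log2(cj1 / cp1)
  out$h_joint_gte[idx1] <- -log2(cj1 / n1)

  if (length(lags)) {
    L <- max(lags)
    if (n <= L) {
      stop(sprintf("insufficient data: path length %d <= max lag %d", n, L),
           call. = FALSE)
    }
    idx <- (L + 1L):n
    tgt <- x[idx]
    past <- tuple_code0(lapply(lags, function(l) x[idx - l]), A)
    neff <- length(idx)
    k_past <- A^length(lags)
    joint0 <- (tgt - 1) + A * past
    cnt_t <- tabulate(tgt, nbins = A)
    cnt_p <- count_code0(past, k_past)
    cnt_j <- count_code0(joint0, A * k_past)
    ct <- cnt_t[tgt]
    cp <- lookup_code0(cnt_p, past)
    cj <- lookup_code0(cnt_j, joint0)
    out$lais[idx] <- log2((cj / cp) / (ct / neff))
    out$h_local[idx] <- -log2(ct / neff)
    out$h_joint_ais[idx] <- -log2(cj / neff)
    ais <- mean(out$lais[idx])
  } else {
    # no predictive past: only the marginal information content
    cnt_t <- tabulate(x, nbins = A)
    out$h_local <- -log2(cnt_t[x] / n)
    ais <- NA_real_
  }

  attr(out, "lags") <- lags
  attr(out, "A") <- A
  attr(out, "ais") <- ais
  attr(out, "gte") <- mean(out$lgte[idx1])
  class(out) <- c("gaze_local_measures", class(out))
  out
}

# Count table over 0-based codes, returned as either a dense vector
# (small range) or a named lookup environment-free list.
count_code0 <- function(code, nbins) {
  if (nbins <= 2^20) {
    list(dense = tabulate(as.integer(code) + 1L, nbins = as.integer(nbins)))
  } else {
    u <- unique(code)
    list(keys = u, counts = tabulate(match(code, u)))
  }
}

lookup_code0 <- function(cnt, code) {
  if (!is.null(cnt$dense)) cnt$dense[as.integer(code) + 1L]
  else cnt$counts[match(code, cnt$keys)]
}
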
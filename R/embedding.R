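#' Configuration for permutation-based significance testing
#'
#' @param n_permutations Number of surrogate rounds. Must satisfy
#'   `n_permutations >= 1/alpha - 1` so the smallest attainable p-value,
#'   `1 / (n_permutations + 1)`, can reach `alpha`.
#' @param alpha Significance level in (0, 1).
#' @param seed Optional integer master seed; per-step surrogate seeds
#'   are derived from it deterministically. `NULL` uses the current RNG
#'   state.
#' @return A list of class `"permutation_config"`.
#' @export
permutation_config <- function(n_permutations = 200, alpha = 0.05,
                               seed = NULL) {
  n_permutations <- as.integer(n_permutations)
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1L)
  if (n_permutations < 1 / alpha - 1) {
    stop(sprintf(
      "n_permutations = %d cannot resolve alpha = %g; need at least %d",
      n_permutations, alpha, ceiling(1 / alpha - 1)
    ), call. = FALSE)
  }
  structure(
    list(n_permutations = n_permutations, alpha = alpha,
         seed = if (!is.null(seed)) as.integer(seed),
         surrogate_scheme = "shuffle-candidate"),
    class = "permutation_config"
  )
}

step_seed <- function(seed, step) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 97003 * step) %% 2147483647)
}

#' Max-statistic permutation test over a set of candidate lags
#'
#' Computes the plug-in conditional mutual information of every
#' candidate lag with the next fixation, given the conditioning lags,
#' on the common eligible sample set `t > max(candidates, conditioning)`.
#' The winning lag is the CMI argmax (ties broken toward the smallest
#' lag). Its p-value is the fraction of surrogate rounds whose *maximum*
#' CMI across all candidates reaches the observed winning CMI, where
#' each round permutes every candidate's realizations independently
#' while target and conditioning stay intact. Taking the maximum over
#' candidates controls the family-wise error rate of the selection step;
#' because surrogates share the finite-sample bias of the plug-in
#' estimator, the test also absorbs that bias. The p-value uses the
#' add-one correction `p = (1 + #{surrogate >= observed}) /
#' (1 + n_permutations)`.
#'
#' @inheritParams active_information_storage
#' @param candidates Nonempty integer vector of candidate lags, disjoint
#'   from `conditioning`.
#' @param conditioning Already selected lags (possibly empty).
#' @param cfg A [permutation_config()].
#' @return A list of class `"gaze_lag_test"`: `lag`, `cmi` (bits),
#'   `p_value`, `candidates` (tibble of per-candidate observed CMI),
#'   `surrogate_max` (numeric vector of the per-round maxima), `n_eff`.
#' @export
max_statistic_test <- function(path, candidates, conditioning = integer(),
                               cfg = permutation_config(), A = 8) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  candidates <- check_lags(candidates)
  conditioning <- check_lags(conditioning, allow_empty = TRUE)
  if (length(intersect(candidates, conditioning))) {
    stop("candidates must be disjoint from conditioning", call. = FALSE)
  }
  n <- length(path)
  L <- max(c(candidates, conditioning))
  if (n <= L) {
    stop(sprintf("insufficient data: path length %d <= history %d", n, L),
         call. = FALSE)
  }
  x <- unclass(path)
  tgt <- lag_column(x, 0L, L) - 1
  cand_cols <- lapply(candidates, function(l) lag_column(x, l, L) - 1)
  if (length(conditioning)) {
    cond <- tuple_code0(lapply(conditioning, function(l) lag_column(x, l, L)),
                        A)
    k_cond <- A^length(conditioning)
  } else {
    cond <- numeric(length(tgt))
    k_cond <- 1
  }

  observed <- vapply(cand_cols, function(cc) cmi_code0(tgt, cc, cond, A,
                                                       k_cond), numeric(1))
  win <- which.max(observed) # candidates sorted ascending: ties -> smallest
  obs_win <- observed[win]

  run_surrogates <- function() {
    m <- length(tgt)
    vapply(seq_len(cfg$n_permutations), function(r) {
      max(vapply(cand_cols, function(cc) {
        cmi_code0(tgt, cc[sample.int(m)], cond, A, k_cond)
      }, numeric(1)))
    }, numeric(1))
  }
  sur <- if (is.null(cfg$seed)) run_surrogates() else
    withr::with_seed(cfg$seed, run_surrogates())

  p <- (1 + sum(sur >= obs_win - 1e-12)) / (1 + cfg$n_permutations)
  structure(
    list(
      lag = candidates[win], cmi = obs_win, p_value = p,
      candidates = tibble::tibble(lag = candidates, cmi = observed),
      surrogate_max = sur, n_eff = length(tgt), cfg = cfg
    ),
    class = "gaze_lag_test"
  )
}

#' @export
print.gaze_lag_test <- function(x, ...) {
  cat(sprintf(
    "<gaze_lag_test> winner lag %d: CMI = %.4f bits, p = %.4f (%d surrogates)\n",
    x$lag, x$cmi, x$p_value, length(x$surrogate_max)
  ))
  invisible(x)
}

#' Optimize the predictive past state of a scan path
#'
#' Greedy forward selection of a non-uniform embedding: starting from an
#' empty past state, the candidate lag in `1..l_max` with the largest
#' conditional mutual information given the already selected lags is
#' tested with [max_statistic_test()]; if significant at `cfg$alpha` it
#' joins the selection and the next round starts, otherwise the
#' procedure terminates. The resulting lag set is the data-driven past
#' state `X_t^-` used for AIS estimation; an empty selection means no
#' significant predictive past was found (the participant is flagged
#' non-significant downstream).
#'
#' @inheritParams max_statistic_test
#' @param l_max Maximum admissible lag (default 5).
#' @return An object of class `"gaze_embedding"`: `selected` (lags in
#'   selection order), `steps` (per-step tibble with candidate, CMI,
#'   p-value), `terminated_reason`, `significant`, `ais` (plug-in AIS of
#'   the selected set, `NA` when empty), `l_max`, `cfg`, `n`.
#' @export
optimize_past_state <- function(path, l_max = 5, cfg = permutation_config(),
                                A = 8) {
  path <- as_scanpath(path, A)
  A <- alphabet_size(path)
  l_max <- as.integer(l_max)
  stopifnot(l_max >= 1L)
  n <- length(path)
  if (n <= 10L * A) {
    stop(sprintf(
      "insufficient data: path length %d fails the n > 10 * A guard (A = %d)",
      n, A
    ), call. = FALSE)
  }
  candidates <- seq_len(l_max)
  selected <- integer()
  steps <- list()
  reason <- "l_max-exhausted"
  step <- 0L
  while (length(candidates)) {
    step <- step + 1L
    cfg_step <- cfg
    cfg_step$seed <- step_seed(cfg$seed, step)
    res <- max_statistic_test(path, candidates, selected, cfg_step, A)
    sig <- res$p_value <= cfg$alpha
    steps[[step]] <- tibble::tibble(
      step = step, lag = res$lag, cmi = res$cmi, p_value = res$p_value,
      selected = sig,
      surrogate_max_q95 = stats::quantile(res$surrogate_max, 0.95,
                                          names = FALSE)
    )
    if (!sig) {
      reason <- "no-significant-candidate"
      break
    }
    selected <- c(selected, res$lag)
    candidates <- setdiff(candidates, res$lag)
  }
  ais <- if (length(selected)) {
    active_information_storage(path, selected, A)
  } else {
    NA_real_
  }
  structure(
    list(
      selected = selected,
      steps = dplyr::bind_rows(steps),
      terminated_reason = reason,
      significant = length(selected) > 0L,
      ais = ais, l_max = l_max, cfg = cfg, n = n, A = A
    ),
    class = "gaze_embedding"
  )
}

#' @export
print.gaze_embedding <- function(x, ...) {
  cat("<gaze_embedding>\n")
  if (x$significant) {
    cat(sprintf(
      "  selected lags: {%s} (selection order), AIS = %.4f bits\n",
      paste(x$selected, collapse = ", "), x$ais
    ))
  } else {
    cat("  no significant predictive past found\n")
  }
  cat(sprintf("  termination: %s after %d step(s), l_max = %d, n = %d\n",
              x$terminated_reason, nrow(x$steps), x$l_max, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-step record of a past-state optimization
#'
#' @param x A `"gaze_embedding"`.
#' @param ... Unused.
#' @return The `steps` tibble: one row per greedy step with the winning
#'   candidate lag, its CMI (bits), permutation p-value and whether it
#'   was selected.
#' @method tidy gaze_embedding
#' @export
tidy.gaze_embedding <- function(x, ...) {
  x$steps
}

#' One-row summary of a past-state optimization
#'
#' @param x A `"gaze_embedding"`.
#' @param ... Unused.
#' @return A one-row tibble with the selected lag set, AIS, significance
#'   flag, termination reason and sample size.
#' @export
glance.gaze_embedding <- function(x, ...) {
  tibble::tibble(
    selected = paste(x$selected, collapse = ","),
    n_lags = length(x$selected),
    max_lag = if (length(x$selected)) max(x$selected) else NA_integer_,
    ais = x$ais,
    significant = x$significant,
    terminated_reason = x$terminated_reason,
    n = x$n
  )
}
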
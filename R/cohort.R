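#' Configuration for a synthetic cohort of scan-path recordings
#'
#' The defaults emulate the structure of an 11-driver highway-overtaking
#' session: each participant contributes one recording of on average 866
#' fixations (SD 74) over 8 AOIs, containing 12 overtaking trials (half
#' easy, half hard, in random order), each trial consisting of a
#' 5-fixation baseline, a before-lane-change period and an
#' after-lane-change period, with inter-trial stretches in between.
#' Participants differ in the true lag set of their gaze chain: by
#' default six are first-order (`{1}`), four are higher-order (`{2}`,
#' `{3}`, `{4}`, `{2}`) and one is memoryless (i.i.d.; expected to
#' be flagged non-significant by the embedding). The higher-order lag
#' sets deliberately exclude lag 1, so that for this group the
#' predictive structure — and any change in it — lies strictly beyond
#' the reach of a first-order (lag-1) measure; this is the structural
#' contrast the cohort is designed to exhibit. Chains use refixation
#' (`"repeat"`) dynamics, under which the stationary AOI distribution
#' equals the base marginal: the baseline marginal places 80% of its
#' mass on AOIs 5 and 8 (dashboard and ego lane), task-period marginals
#' are more dispersed. Predictability increases after the lane change
#' through a coupling boost `rho_alc_boost`.
#'
#' @param n_participants Cohort size.
#' @param true_lag_sets List of integer lag sets, one per participant;
#'   `integer(0)` denotes a memoryless participant. `NULL` uses the
#'   default mix described above (requires `n_participants = 11`).
#' @param A Alphabet size.
#' @param rho Coupling strength outside the after-lane-change period.
#' @param rho_alc_boost Added to `rho` during after-lane-change periods
#'   (capped at 0.98).
#' @param marginal_baseline,marginal_task Base marginals used during
#'   baseline/inter-trial and task periods. `NULL` uses the skewed
#'   defaults described above.
#' @param n_fixations_mean,n_fixations_sd Per-participant fixation count
#'   distribution (normal, rounded).
#' @param n_trials Number of trials (half easy, half hard).
#' @param task_period_mean Mean fixation count of each task period.
#' @param n_baseline Baseline length in fixations.
#' @param duration_means_ms Named mean fixation durations per period
#'   (lognormal synthesis; I/O realism only).
#' @param seed Optional integer seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 11, true_lag_sets = NULL,
                          A = 8, rho = 0.8, rho_alc_boost = 0.15,
                          marginal_baseline = NULL, marginal_task = NULL,
                          n_fixations_mean = 866, n_fixations_sd = 74,
                          n_trials = 12, task_period_mean = 18,
                          n_baseline = 5,
                          duration_means_ms = c(
                            baseline = 630, before_lane_change = 530,
                            after_lane_change = 500, none = 600
                          ),
                          seed = NULL) {
  if (is.null(true_lag_sets)) {
    if (n_participants != 11) {
      stop("default `true_lag_sets` requires n_participants = 11",
           call. = FALSE)
    }
    true_lag_sets <- c(
      rep(list(1L), 6),
      list(2L, 3L, 4L, 2L),
      list(integer())
    )
  }
  stopifnot(length(true_lag_sets) == n_participants, A >= 2,
            rho >= 0, rho <= 1, n_trials %% 2 == 0)
  heavy <- c(min(5L, A - 1L), A) # dashboard and ego lane for A = 8
  if (is.null(marginal_baseline)) {
    marginal_baseline <- rep(0.2 / (A - 2), A)
    marginal_baseline[heavy] <- 0.4
  }
  if (is.null(marginal_task)) {
    marginal_task <- rep(0.36 / (A - 2), A)
    marginal_task[heavy] <- c(0.30, 0.34)
  }
  structure(
    list(
      n_participants = n_participants, true_lag_sets = true_lag_sets,
      A = A, rho = rho, rho_alc_boost = rho_alc_boost,
      marginal_baseline = marginal_baseline, marginal_task = marginal_task,
      n_fixations_mean = n_fixations_mean, n_fixations_sd = n_fixations_sd,
      n_trials = n_trials, task_period_mean = task_period_mean,
      n_baseline = n_baseline, duration_means_ms = duration_means_ms,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a cohort of AOI fixation recordings
#'
#' Generates, for every participant, a fixation table (onsets and
#' durations synthesized, confidence 1.0, AOI symbols from the
#' participant's Markov chain with period-specific coupling and marginal
#' skew), a trial-event table, and a ground-truth manifest recording the
#' true lag set and period parameters. Period effects are
#' piecewise-stationary parameter switches; the chain state carries
#' across period boundaries so each recording is one consecutive scan
#' path, exactly what the estimation pipeline assumes.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `"gaze_cohort"` with tibbles `fixations`
#'   (all participants), `events`, and `truth` (one row per participant:
#'   `participant`, `true_lags` (list-column), `true_order`,
#'   `rho`, `rho_alc`, `expected_group`), plus `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  run <- function() {
    parts <- lapply(seq_len(cfg$n_participants), function(i) {
      simulate_participant(cfg, i)
    })
    truth <- tibble::tibble(
      participant = vapply(parts, function(p) p$participant, character(1)),
      true_lags = lapply(cfg$true_lag_sets, as.integer),
      true_order = vapply(cfg$true_lag_sets, function(l) {
        if (length(l)) max(l) else 0L
      }, integer(1)),
      rho = ifelse(lengths(cfg$true_lag_sets) > 0, cfg$rho, 0),
      rho_alc = ifelse(lengths(cfg$true_lag_sets) > 0,
                       min(cfg$rho + cfg$rho_alc_boost, 0.98), 0),
      expected_group = vapply(cfg$true_lag_sets, function(l) {
        if (!length(l)) "excluded"
        else if (max(l) > 1L) "order_gt1"
        else "order1"
      }, character(1))
    )
    structure(
      list(
        fixations = dplyr::bind_rows(lapply(parts, `[[`, "fixations")),
        events = dplyr::bind_rows(lapply(parts, `[[`, "events")),
        truth = truth,
        config = cfg
      ),
      class = "gaze_cohort"
    )
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

# Period layout of one recording: a vector of period labels plus trial ids.
cohort_layout <- function(cfg) {
  n_tr <- cfg$n_trials
  repeat {
    N <- max(400L, round(stats::rnorm(1, cfg$n_fixations_mean,
                                      cfg$n_fixations_sd)))
    blc <- pmax(6L, stats::rpois(n_tr, cfg$task_period_mean))
    alc <- pmax(6L, stats::rpois(n_tr, cfg$task_period_mean))
    n_gapfree <- sum(blc) + sum(alc) + n_tr * cfg$n_baseline
    gap_budget <- N - n_gapfree - (n_tr + 1L) * 2L
    if (gap_budget >= 0L) break
  }
  extra <- if (gap_budget > 0L) {
    as.integer(stats::rmultinom(1, gap_budget, rep(1, n_tr + 1L)))
  } else {
    integer(n_tr + 1L)
  }
  gaps <- 2L + extra # every inter-trial stretch has >= 2 unlabeled fixations
  period <- character(0)
  trial <- integer(0)
  for (k in seq_len(n_tr)) {
    period <- c(period, rep("none", gaps[k]),
                rep("baseline", cfg$n_baseline),
                rep("before_lane_change", blc[k]),
                rep("after_lane_change", alc[k]))
    trial <- c(trial, rep(NA_integer_, gaps[k]),
               rep(k, cfg$n_baseline + blc[k] + alc[k]))
  }
  period <- c(period, rep("none", gaps[n_tr + 1L]))
  trial <- c(trial, rep(NA_integer_, gaps[n_tr + 1L]))
  list(period = period, trial = trial)
}

simulate_participant <- function(cfg, i) {
  id <- sprintf("P%02d", i)
  lags <- as.integer(cfg$true_lag_sets[[i]])
  iid <- length(lags) == 0L
  rho_base <- if (iid) 0 else cfg$rho
  rho_alc <- if (iid) 0 else min(cfg$rho + cfg$rho_alc_boost, 0.98)
  chain_lags <- if (iid) 1L else lags

  # refixation ("repeat") dynamics: the stationary AOI distribution equals
  # the base marginal, so the baseline skew survives strong coupling
  conds <- list(
    none = build_chain(cfg$A, chain_lags, rho_base, cfg$marginal_baseline,
                       map = "repeat"),
    baseline = build_chain(cfg$A, chain_lags, rho_base,
                           cfg$marginal_baseline, map = "repeat"),
    before_lane_change = build_chain(cfg$A, chain_lags, rho_base,
                                     cfg$marginal_task, map = "repeat"),
    after_lane_change = build_chain(cfg$A, chain_lags, rho_alc,
                                    cfg$marginal_task, map = "repeat")
  )
  m <- conds$none$m
  A <- cfg$A
  cums <- lapply(conds, function(s) t(apply(s$cond, 1L, cumsum)))

  layout <- cohort_layout(cfg)
  n <- length(layout$period)

  # symbols: one consecutive chain with period-switched conditionals
  pi0 <- stationary_vector(conds$none)
  state <- sample.int(length(pi0), 1L, prob = pi0) - 1L
  a_low <- A^(m - 1L)
  u <- stats::runif(n)
  sym <- integer(n)
  for (t in seq_len(n)) {
    row <- cums[[layout$period[t]]][state + 1L, ]
    y <- 1L + sum(row < u[t])
    sym[t] <- y
    state <- (y - 1L) + A * (state %% a_low)
  }

  # durations (lognormal around per-period means, clamped inside the QC
  # window so the synthesized recording passes preprocessing unchanged)
  mu <- cfg$duration_means_ms[layout$period]
  sdlog <- 0.25
  dur <- stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  dur <- pmin(pmax(dur, 110), 1400)
  gap_s <- stats::runif(n, 0.03, 0.08)
  onset <- cumsum(c(0, (dur[-n] / 1000) + gap_s[-n]))

  fixations <- tibble::tibble(
    participant = id, session = "s1", onset = onset, duration_ms = dur,
    aoi = sym, confidence = 1.0
  )

  # trial events derived from the realized onsets
  difficulty <- sample(rep(c("easy", "hard"), cfg$n_trials / 2L))
  events <- lapply(seq_len(cfg$n_trials), function(k) {
    in_tr <- which(layout$trial == k)
    blc_idx <- in_tr[layout$period[in_tr] == "before_lane_change"]
    alc_idx <- in_tr[layout$period[in_tr] == "after_lane_change"]
    t_onset <- onset[blc_idx[1]] - 0.001
    t_lc <- onset[alc_idx[1]] - 0.001
    t_end <- onset[alc_idx[length(alc_idx)]] +
      dur[alc_idx[length(alc_idx)]] / 1000
    tibble::tibble(
      participant = id, trial_id = k, onset = t_onset, lane_change = t_lc,
      end = t_end, difficulty = difficulty[k], valid = TRUE
    )
  })
  list(participant = id, fixations = fixations,
       events = dplyr::bind_rows(events),
       true_period = layout$period, true_trial = layout$trial)
}
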
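#' Run the full per-participant analysis
#'
#' Reproduces the study-style analysis chain for one labeled recording:
#' optimize the predictive past state on the complete consecutive scan
#' path, estimate the local measures (LAIS with the selected lags, LGTE
#' with lag 1, local and joint local entropies) from the full path,
#' re-attach them to the fixation table, and average each local series
#' within every `(trial, period)`, normalizing the means by the matching
#' mean local joint entropy. Participants whose embedding finds no
#' significant past are flagged excluded and produce LGTE-only
#' summaries.
#'
#' @param labeled A labeled fixation table (see [assign_periods()]) for
#'   a single participant/session, already quality-filtered.
#' @param l_max Maximum admissible lag for the embedding (default 5).
#' @param cfg A [permutation_config()].
#' @param A Alphabet size.
#' @return A list of class `"gaze_participant_analysis"`: `embedding`
#'   (a `"gaze_embedding"`), `local` (the fixation table joined with the
#'   local measure columns), `summaries` (one row per trial x period,
#'   see below), `excluded`.
#'
#'   `summaries` columns: `participant`, `trial_id`, `difficulty`,
#'   `period`, `n_fixations_in_period`, `mean_lais`, `mean_lgte`,
#'   `mean_joint_entropy_ais`, `mean_joint_entropy_gte`,
#'   `normalized_lais`, `normalized_lgte`, `valid` (FALSE when fewer
#'   than 2 eligible fixations or a zero mean joint entropy).
#' @export
analyze_participant <- function(labeled, l_max = 5,
                                cfg = permutation_config(), A = 8) {
  stopifnot(is.data.frame(labeled))
  need <- c("aoi", "period", "trial_id")
  miss <- setdiff(need, names(labeled))
  if (length(miss)) {
    stop("labeled table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  path <- encode_scanpath(labeled, A)
  emb <- optimize_past_state(path, l_max = l_max, cfg = cfg, A = A)
  loc <- local_measures(path, emb$selected, A = A)
  # back_index is the identity here (the path was encoded from `labeled`
  # itself), so local rows align 1:1 with the fixation rows
  loc_cols <- c("lais", "lgte", "h_local", "h_joint_ais", "h_joint_gte")
  row_of <- match(seq_len(nrow(labeled)), attr(path, "back_index"))
  joined <- dplyr::bind_cols(
    labeled,
    tibble::as_tibble(loc)[row_of, loc_cols]
  )
  summaries <- summarize_periods(joined)
  if ("participant" %in% names(labeled)) {
    summaries <- dplyr::mutate(summaries,
                               participant = labeled$participant[1],
                               .before = 1L)
  }
  structure(
    list(embedding = emb, local = joined, summaries = summaries,
         excluded = !emb$significant),
    class = "gaze_participant_analysis"
  )
}

summarize_periods <- function(joined) {
  labeled_rows <- dplyr::filter(joined, .data$period != "none",
                                !is.na(.data$trial_id))
  out <- labeled_rows |>
    dplyr::group_by(.data$trial_id, .data$difficulty, .data$period) |>
    dplyr::summarise(
      n_fixations_in_period = dplyr::n(),
      mean_lais = mean(.data$lais, na.rm = TRUE),
      mean_lgte = mean(.data$lgte, na.rm = TRUE),
      mean_joint_entropy_ais = mean(.data$h_joint_ais, na.rm = TRUE),
      mean_joint_entropy_gte = mean(.data$h_joint_gte, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("mean_"), ~ replace(., is.nan(.),
                                                           NA_real_)),
      valid = .data$n_fixations_in_period >= 2L,
      normalized_lais = ifelse(
        .data$valid & .data$mean_joint_entropy_ais > 0,
        .data$mean_lais / .data$mean_joint_entropy_ais, NA_real_
      ),
      normalized_lgte = ifelse(
        .data$valid & .data$mean_joint_entropy_gte > 0,
        .data$mean_lgte / .data$mean_joint_entropy_gte, NA_real_
      )
    )
  out$period <- factor(as.character(out$period),
                       levels = period_levels()[1:3])
  dplyr::arrange(out, .data$trial_id, .data$period)
}

#' Split participants into groups by detected Markov order
#'
#' @param embeddings A named list of `"gaze_embedding"` objects (names =
#'   participant ids).
#' @return A tibble with columns `participant`, `group` (`"order1"` when
#'   the selected past is exactly lag sets with maximum 1, `"order_gt1"`
#'   when any selected lag exceeds 1, `"excluded"` when no significant
#'   past was found), `selected` (list-column) and `max_lag`.
#' @export
split_by_markov_order <- function(embeddings) {
  stopifnot(is.list(embeddings), length(embeddings) > 0)
  ids <- names(embeddings) %||% as.character(seq_along(embeddings))
  tibble::tibble(
    participant = ids,
    selected = unname(lapply(embeddings, `[[`, "selected")),
    max_lag = unname(vapply(embeddings, function(e) {
      if (length(e$selected)) max(e$selected) else NA_integer_
    }, integer(1))),
    group = unname(vapply(embeddings, function(e) {
      if (!e$significant) "excluded"
      else if (max(e$selected) > 1L) "order_gt1"
      else "order1"
    }, character(1)))
  )
}

#' Analyze a whole cohort end to end
#'
#' Applies quality filtering, period labelling, per-participant past
#' state optimization, local measures and period summaries to every
#' participant, splits participants into groups by detected Markov
#' order, and fits the contrast-coded mixed models for both normalized
#' measures in each group.
#'
#' @param fixations Fixation table covering all participants.
#' @param events Trial-event table covering all participants.
#' @param l_max,cfg,A As in [analyze_participant()]. Each participant's
#'   permutation seed is derived from `cfg$seed` and the participant's
#'   position so results are reproducible yet independent across
#'   participants.
#' @param filter Apply [filter_fixations()] with default thresholds
#'   first (default TRUE).
#' @param random Random-effect structure handed to [fit_lmem()].
#' @return A list of class `"gaze_cohort_analysis"`: `analyses` (named
#'   list of per-participant results), `groups` (from
#'   [split_by_markov_order()]), `summaries` (all period summaries),
#'   `models` (named list `<group>_<measure>` of `"gaze_lmem"` fits).
#' @export
analyze_cohort <- function(fixations, events, l_max = 5,
                           cfg = permutation_config(), A = 8,
                           filter = TRUE, random = "slope") {
  parts <- unique(fixations$participant)
  analyses <- lapply(seq_along(parts), function(i) {
    p <- parts[i]
    tab <- fixations[fixations$participant == p, , drop = FALSE]
    if (filter) tab <- filter_fixations(tab)
    lab <- assign_periods(tab, events[events$participant == p, ,
                                      drop = FALSE])
    cfg_p <- cfg
    cfg_p$seed <- step_seed(cfg$seed, 1000L * i)
    analyze_participant(lab, l_max = l_max, cfg = cfg_p, A = A)
  })
  names(analyses) <- parts
  groups <- split_by_markov_order(lapply(analyses, `[[`, "embedding"))
  summaries <- dplyr::bind_rows(lapply(analyses, `[[`, "summaries"))

  models <- list()
  for (g in c("order1", "order_gt1")) {
    members <- groups$participant[groups$group == g]
    if (length(members) < 2L) next
    sub <- summaries[summaries$participant %in% members, , drop = FALSE]
    for (meas in c("normalized_lais", "normalized_lgte")) {
      fit <- tryCatch(
        fit_lmem(build_design(sub, response = meas), random = random),
        error = function(e) NULL
      )
      models[[paste(g, meas, sep = "_")]] <- fit
    }
  }
  structure(
    list(analyses = analyses, groups = groups, summaries = summaries,
         models = models),
    class = "gaze_cohort_analysis"
  )
}

#' Descriptive fixation statistics
#'
#' Computes the relative proportion of fixated AOIs per trial period,
#' mean fixation durations per participant and condition (the three
#' trial periods and the two difficulty levels), and the Spearman
#' rank-correlation matrix of the per-participant duration means across
#' conditions (a consistency measure of inter-individual differences;
#' ties receive average ranks).
#'
#' @param labeled A labeled fixation table (all participants).
#' @return A list of class `"gaze_fixation_stats"` with tibbles
#'   `aoi_proportions` (`period`, `aoi`, `n`, `prop`; proportions sum
#'   to 1 within each period), `mean_durations` (`participant`,
#'   `condition`, `mean_duration_ms`), and the matrix
#'   `spearman_consistency`.
#' @export
fixation_statistics <- function(labeled) {
  stopifnot(is.data.frame(labeled),
            all(c("aoi", "period", "duration_ms") %in% names(labeled)))
  in_period <- dplyr::filter(labeled, .data$period != "none")
  aoi_proportions <- in_period |>
    dplyr::count(.data$period, .data$aoi) |>
    dplyr::group_by(.data$period) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  by_period <- in_period |>
    dplyr::group_by(.data$participant, condition = as.character(.data$period)) |>
    dplyr::summarise(mean_duration_ms = mean(.data$duration_ms),
                     .groups = "drop")
  by_diff <- in_period |>
    dplyr::filter(!is.na(.data$difficulty)) |>
    dplyr::group_by(.data$participant, condition = .data$difficulty) |>
    dplyr::summarise(mean_duration_ms = mean(.data$duration_ms),
                     .groups = "drop")
  mean_durations <- dplyr::bind_rows(by_period, by_diff)

  wide <- tidyr::pivot_wider(mean_durations, names_from = "condition",
                             values_from = "mean_duration_ms")
  mat <- as.matrix(wide[, setdiff(names(wide), "participant"), drop = FALSE])
  spearman <- if (nrow(mat) >= 2L) {
    # zero-variance conditions have no defined rank correlation -> NA
    suppressWarnings(
      stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
    )
  } else {
    matrix(NA_real_, ncol(mat), ncol(mat),
           dimnames = list(colnames(mat), colnames(mat)))
  }
  structure(
    list(aoi_proportions = aoi_proportions,
         mean_durations = mean_durations,
         spearman_consistency = spearman),
    class = "gaze_fixation_stats"
  )
}
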
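#' Default column-name mapping for fixation tables
#'
#' Maps the canonical field names used throughout the package to the
#' column names found in a delimited input file.
#'
#' @return A named list with entries `onset`, `duration_ms`, `aoi`,
#'   `confidence`, `participant`, `session`.
#' @export
default_schema <- function() {
  list(
    onset = "onset", duration_ms = "duration_ms", aoi = "aoi",
    confidence = "confidence", participant = "participant",
    session = "session"
  )
}

#' Read a delimited fixation table
#'
#' Reads one row per fixation: onset time (s), duration (ms), AOI label,
#' tracker confidence in \[0, 1\], plus optional participant/session
#' identifiers. Rows are returned sorted by `(participant, session,
#' onset)`. The AOI alphabet is fixed by `A`; labels outside `1..A` are
#' an error listing the offending rows.
#'
#' @param file Path to a delimited text file with a header row.
#' @param schema Column-name mapping, see [default_schema()]. Entries
#'   `participant` and `session` may be `NULL` or absent from the file,
#'   in which case a constant identifier is filled in.
#' @param A Alphabet size.
#' @param delim Field delimiter (default `","`).
#' @return A tibble with canonical columns `participant`, `session`,
#'   `onset`, `duration_ms`, `aoi`, `confidence`.
#' @export
read_fixations <- function(file, schema = default_schema(), A = 8,
                           delim = ",") {
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  schema <- utils::modifyList(default_schema(), schema)
  required <- c("onset", "duration_ms", "aoi", "confidence")
  for (field in required) {
    col <- schema[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop(sprintf("schema error: required column `%s` (field `%s`) not found",
                   col %||% "<unset>", field), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    participant = fetch_id(raw, schema$participant, "p1"),
    session = fetch_id(raw, schema$session, "s1"),
    onset = parse_num(raw[[schema$onset]], "onset"),
    duration_ms = parse_num(raw[[schema$duration_ms]], "duration_ms"),
    aoi = raw[[schema$aoi]],
    confidence = parse_num(raw[[schema$confidence]], "confidence")
  )
  aoi_num <- suppressWarnings(as.numeric(out$aoi))
  bad <- which(is.na(aoi_num) | aoi_num != round(aoi_num) |
                 aoi_num < 1 | aoi_num > A)
  if (length(bad)) {
    stop(sprintf(
      "validation error: `aoi` outside alphabet 1..%d in rows: %s", A,
      paste(utils::head(bad, 20L), collapse = ", ")
    ), call. = FALSE)
  }
  out$aoi <- as.integer(aoi_num)
  if (any(out$duration_ms <= 0)) {
    stop("validation error: `duration_ms` must be positive", call. = FALSE)
  }
  if (any(out$confidence < 0 | out$confidence > 1)) {
    stop("validation error: `confidence` must lie in [0, 1]", call. = FALSE)
  }
  dplyr::arrange(out, .data$participant, .data$session, .data$onset)
}

fetch_id <- function(raw, col, default) {
  if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
  else rep(default, nrow(raw))
}

parse_num <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) || anyNA(x)) {
    bad <- union(bad, which(is.na(x)))
    stop(sprintf("parse error: non-numeric `%s` in rows: %s", name,
                 paste(utils::head(sort(bad), 20L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Quality-filter fixations by duration and tracker confidence
#'
#' Retains fixations with `min_duration_ms <= duration_ms <=
#' max_duration_ms` and `confidence >= min_confidence`. Both duration
#' bounds are inclusive: fixations *below* the lower bound and *above*
#' the upper bound are excluded, so exact boundary values are kept; the
#' confidence cut likewise drops values *below* the threshold. The
#' defaults (100 ms, 1500 ms, 0.9) are the usual quality criteria for
#' video-based eye tracking in driving studies.
#'
#' Counts removed per criterion are attached as the `"filter_log"`
#' attribute (a tibble); a row failing several criteria is counted under
#' each. The operation is idempotent.
#'
#' @param table Fixation table with `duration_ms` and `confidence`.
#' @param min_duration_ms,max_duration_ms Inclusive duration bounds (ms).
#' @param min_confidence Inclusive lower confidence bound.
#' @return The filtered tibble with a `"filter_log"` attribute.
#' @export
filter_fixations <- function(table, min_duration_ms = 100,
                             max_duration_ms = 1500, min_confidence = 0.9) {
  stopifnot(min_duration_ms > 0, min_duration_ms < max_duration_ms)
  too_short <- table$duration_ms < min_duration_ms
  too_long <- table$duration_ms > max_duration_ms
  low_conf <- table$confidence < min_confidence
  keep <- !(too_short | too_long | low_conf)
  out <- table[keep, , drop = FALSE]
  log <- tibble::tibble(
    criterion = c("duration_below_min", "duration_above_max",
                  "confidence_below_min"),
    threshold = c(min_duration_ms, max_duration_ms, min_confidence),
    n_removed = c(sum(too_short), sum(too_long), sum(low_conf))
  )
  attr(out, "filter_log") <- log
  if (nrow(out) == 0L) {
    warning("all fixations removed by quality filtering", call. = FALSE)
  }
  out
}

#' Label fixations with trial periods
#'
#' Given a trial-event table (trial onset = the front car decelerating,
#' lane-change time, trial end), labels each fixation with a period:
#' `before_lane_change` for onsets in `[onset, lane_change)`,
#' `after_lane_change` for `[lane_change, end]`, `baseline` for the 5
#' fixations immediately preceding a valid trial's onset (fewer, with a
#' warning, when not available), and `none` otherwise. Invalid trials
#' (`valid == FALSE`) produce no labels. The lane-change boundary is
#' half-open so the partition is unambiguous: every fixation carries at
#' most one period label.
#'
#' @param table Fixation table (typically filtered), sorted by onset.
#' @param events Trial-event table with columns `trial_id`, `onset`,
#'   `lane_change`, `end`, `difficulty`, `valid`, and optionally
#'   `participant` (matched against the fixation table when present in
#'   both).
#' @param n_baseline Number of pre-trial fixations forming the baseline
#'   (default 5).
#' @return The input tibble with added columns `period` (factor:
#'   baseline, before_lane_change, after_lane_change, none), `trial_id`
#'   and `difficulty` (NA outside trials).
#' @export
assign_periods <- function(table, events, n_baseline = 5L) {
  stopifnot(is.data.frame(table), is.data.frame(events))
  needed <- c("trial_id", "onset", "lane_change", "end", "valid")
  miss <- setdiff(needed, names(events))
  if (length(miss)) {
    stop("events table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"difficulty" %in% names(events)) events$difficulty <- NA_character_
  by_part <- "participant" %in% names(table) &&
    "participant" %in% names(events)
  if (by_part) {
    parts <- unique(table$participant)
    out <- lapply(parts, function(p) {
      assign_periods_one(
        table[table$participant == p, , drop = FALSE],
        events[events$participant == p, , drop = FALSE], n_baseline
      )
    })
    out <- dplyr::bind_rows(out)
  } else {
    out <- assign_periods_one(table, events, n_baseline)
  }
  out$period <- factor(out$period, levels = period_levels())
  out
}

period_levels <- function() {
  c("baseline", "before_lane_change", "after_lane_change", "none")
}

assign_periods_one <- function(table, events, n_baseline) {
  events <- events[order(events$onset), , drop = FALSE]
  if (any(!(events$onset < events$lane_change &
              events$lane_change < events$end))) {
    stop("structural error: each trial requires onset < lane_change < end",
         call. = FALSE)
  }
  if (nrow(events) > 1L &&
      any(events$onset[-1] <= events$end[-nrow(events)])) {
    stop("structural error: overlapping trials in event table",
         call. = FALSE)
  }
  n <- nrow(table)
  period <- rep("none", n)
  trial <- rep(NA_integer_, n)
  diffc <- rep(NA_character_, n)
  valid_events <- events[events$valid, , drop = FALSE]
  for (k in seq_len(nrow(valid_events))) {
    ev <- valid_events[k, ]
    blc <- table$onset >= ev$onset & table$onset < ev$lane_change
    alc <- table$onset >= ev$lane_change & table$onset <= ev$end
    period[blc] <- "before_lane_change"
    period[alc] <- "after_lane_change"
    trial[blc | alc] <- ev$trial_id
    diffc[blc | alc] <- as.character(ev$difficulty)
  }
  for (k in seq_len(nrow(valid_events))) {
    ev <- valid_events[k, ]
    pool <- which(period == "none" & table$onset < ev$onset)
    if (length(pool) < n_baseline) {
      warning(sprintf(
        "trial %s: only %d fixations available for a baseline of %d",
        ev$trial_id, length(pool), n_baseline
      ), call. = FALSE)
    }
    base <- utils::tail(pool, n_baseline)
    period[base] <- "baseline"
    trial[base] <- ev$trial_id
    diffc[base] <- as.character(ev$difficulty)
  }
  table$period <- period
  table$trial_id <- trial
  table$difficulty <- diffc
  table
}
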
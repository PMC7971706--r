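#' Build the contrast-coded design for the mixed-model stage
#'
#' One observation per `(participant, trial, period)`. The trial-period
#' factor is encoded with two Helmert contrasts matching the planned
#' comparisons: `period_blc` compares baseline against before lane
#' change (baseline -1/2, before +1/2, after 0) and `period_alc`
#' compares the mean of those two against after lane change (-1/3, -1/3,
#' +2/3); positive coefficients mean the later period is higher.
#' Difficulty is deviation-coded (easy +1, hard -1), comparing easy with
#' the grand mean. Interaction columns are products. Baseline
#' observations carry the upcoming trial's difficulty, so the factorial
#' is complete.
#'
#' @param summaries Period summaries, as produced by
#'   [analyze_participant()], for the participants entering one model.
#' @param response Which normalized measure is the response:
#'   `"normalized_lais"` or `"normalized_lgte"` (or any numeric column).
#' @return A tibble of class `"gaze_design"` with columns `participant`,
#'   `trial_id`, `period`, `difficulty`, `y`, `difficulty_dev`,
#'   `period_blc`, `period_alc`, `diff_blc`, `diff_alc`; rows with a
#'   missing response are dropped and listed in the
#'   `"completeness_report"` attribute. Contrast coding is recorded in
#'   the `"coding"` attribute.
#' @export
build_design <- function(summaries, response = "normalized_lais") {
  stopifnot(is.data.frame(summaries), response %in% names(summaries))
  need <- c("participant", "trial_id", "period", "difficulty")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) {
    stop("summaries lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  period_chr <- as.character(summaries$period)
  blc_code <- c(baseline = -1 / 2, before_lane_change = 1 / 2,
                after_lane_change = 0)
  alc_code <- c(baseline = -1 / 3, before_lane_change = -1 / 3,
                after_lane_change = 2 / 3)
  diff_code <- c(easy = 1, hard = -1)
  out <- tibble::tibble(
    participant = summaries$participant,
    trial_id = summaries$trial_id,
    period = period_chr,
    difficulty = summaries$difficulty,
    y = summaries[[response]],
    difficulty_dev = unname(diff_code[summaries$difficulty]),
    period_blc = unname(blc_code[period_chr]),
    period_alc = unname(alc_code[period_chr])
  )
  out$diff_blc <- out$difficulty_dev * out$period_blc
  out$diff_alc <- out$difficulty_dev * out$period_alc
  dropped <- out[is.na(out$y) | is.na(out$difficulty_dev) |
                   is.na(out$period_blc), c("participant", "trial_id",
                                            "period")]
  out <- out[stats::complete.cases(out[, c("y", "difficulty_dev",
                                           "period_blc", "period_alc")]), ,
             drop = FALSE]
  attr(out, "response") <- response
  attr(out, "coding") <- list(
    period_blc = blc_code, period_alc = alc_code,
    difficulty_dev = diff_code
  )
  attr(out, "completeness_report") <- dropped
  class(out) <- c("gaze_design", class(out))
  out
}

#' Fit the linear mixed-effects model of the analysis stage
#'
#' Fits, by REML via `lmerTest`, the model
#' `y ~ difficulty_dev + period_blc + period_alc + diff_blc + diff_alc`
#' with a per-participant random intercept and (by default) random
#' slopes over the two period contrasts. Fixed-effect tests use
#' Satterthwaite's approximation of the denominator degrees of freedom.
#' With few participants the slope fit is typically singular (a boundary
#' estimate of the random-effect covariance); the fit is kept — a
#' boundary fit is a valid REML solution and the Satterthwaite df
#' account for the estimated structure — and singularity is recorded
#' (see [glance.gaze_lmem()]). Only when the slope model cannot be
#' fitted at all does the function fall back to the
#' random-intercept-only model, with a warning recorded in the result.
#'
#' @param design A `"gaze_design"` from [build_design()].
#' @param random `"slope"` (intercept + period-contrast slopes per
#'   participant) or `"intercept"`.
#' @return An object of class `"gaze_lmem"`: `table` (tibble with
#'   `term`, `estimate`, `se`, `df`, `t_value`, `p_value`), `fit` (the
#'   `lmerModLmerTest` object), `random` (structure actually used),
#'   `fallback`, `response`, `coding`.
#' @export
fit_lmem <- function(design, random = c("slope", "intercept")) {
  random <- match.arg(random)
  stopifnot(inherits(design, "gaze_design"))
  if (length(unique(design$participant)) < 2L) {
    stop("at least 2 participants are required for a mixed model",
         call. = FALSE)
  }
  fixed <- "y ~ difficulty_dev + period_blc + period_alc + diff_blc + diff_alc"
  f_slope <- stats::as.formula(
    paste(fixed, "+ (1 + period_blc + period_alc | participant)")
  )
  f_int <- stats::as.formula(paste(fixed, "+ (1 | participant)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fallback <- FALSE
  fit <- NULL
  if (random == "slope") {
    fit <- tryCatch(
      suppressWarnings(
        suppressMessages(lmerTest::lmer(f_slope, data = design, REML = TRUE,
                                        control = ctrl))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning("random-slope model could not be fitted; falling back to ",
              "random-intercept-only", call. = FALSE)
      fallback <- TRUE
    }
  }
  used <- if (random == "slope" && !fallback) "slope" else "intercept"
  if (is.null(fit)) {
    fit <- suppressWarnings(
      suppressMessages(lmerTest::lmer(f_int, data = design, REML = TRUE,
                                      control = ctrl))
    )
  }
  smry <- stats::coef(summary(fit))
  table <- tibble::tibble(
    term = rownames(smry),
    estimate = unname(smry[, "Estimate"]),
    se = unname(smry[, "Std. Error"]),
    df = unname(smry[, "df"]),
    t_value = unname(smry[, "t value"]),
    p_value = unname(smry[, "Pr(>|t|)"])
  )
  structure(
    list(table = table, fit = fit, random = used,
         fallback = fallback && random == "slope",
         response = attr(design, "response"),
         coding = attr(design, "coding")),
    class = "gaze_lmem"
  )
}

#' @export
print.gaze_lmem <- function(x, ...) {
  cat(sprintf("<gaze_lmem> response: %s, random: %s%s\n", x$response,
              x$random, if (x$fallback) " (fallback)" else ""))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy the coefficient table of a fitted mixed model
#'
#' @param x A `"gaze_lmem"`.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`,
#'   `estimate`, `se`, `df` (Satterthwaite), `t_value`, `p_value`.
#' @export
tidy.gaze_lmem <- function(x, ...) {
  x$table
}

#' One-row summary of a fitted mixed model
#'
#' @param x A `"gaze_lmem"`.
#' @param ... Unused.
#' @return A one-row tibble with `response`, `nobs`, `n_participants`,
#'   `random`, `fallback`, `singular`, `reml_crit`.
#' @export
glance.gaze_lmem <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    nobs = stats::nobs(x$fit),
    n_participants = length(unique(x$fit@frame$participant)),
    random = x$random,
    fallback = x$fallback,
    singular = lme4::isSingular(x$fit, tol = 1e-5),
    reml_crit = as.numeric(lme4::REMLcrit(x$fit))
  )
}
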
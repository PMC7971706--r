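test_that("read_fixations reads, sorts and validates a delimited table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant,session,onset,duration_ms,aoi,confidence",
    "p1,s1,2.0,300,2,0.95",
    "p1,s1,1.0,250,8,0.99",
    "p1,s1,3.0,400,5,0.91"
  ), f)
  tab <- read_fixations(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$onset, c(1, 2, 3)) # re-sorted by onset
  expect_equal(tab$aoi, c(8L, 2L, 5L))

  # missing required column -> schema error naming it
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,onset,aoi,confidence", "p1,1,2,0.9"), f2)
  expect_error(read_fixations(f2), "duration_ms")

  # out-of-alphabet AOI -> validation error listing rows
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "onset,duration_ms,aoi,confidence",
    "1,300,9,0.95", "2,300,2,0.95"
  ), f3)
  expect_error(read_fixations(f3, A = 8), "aoi.*1")

  # non-numeric duration -> parse error with row number
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "onset,duration_ms,aoi,confidence",
    "1,300,2,0.95", "2,oops,3,0.95"
  ), f4)
  expect_error(read_fixations(f4), "duration_ms.*2")

  # schema remapping of column names
  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,dur,roi,conf", "1,300,4,0.93"), f5)
  tab5 <- read_fixations(f5, schema = list(
    onset = "start", duration_ms = "dur", aoi = "roi", confidence = "conf"
  ))
  expect_equal(tab5$aoi, 4L)
  expect_equal(tab5$participant, "p1") # constant filled when absent
})

test_that("filter_fixations keeps inclusive boundaries and logs removals", {
  tab <- make_fix_table(aoi = c(1, 2, 3, 4),
                        duration_ms = c(90, 100, 1500, 1501))
  out <- filter_fixations(tab)
  # boundary durations 100 and 1500 are retained; 90 and 1501 excluded
  expect_equal(out$duration_ms, c(100, 1500))
  log <- attr(out, "filter_log")
  expect_equal(log$n_removed[log$criterion == "duration_below_min"], 1L)
  expect_equal(log$n_removed[log$criterion == "duration_above_max"], 1L)

  # confidence threshold inclusive: all 0.95 >= 0.9 retained
  tab2 <- make_fix_table(aoi = 1:4, confidence = rep(0.95, 4))
  expect_equal(nrow(filter_fixations(tab2)), 4L)
  # exactly at the threshold is kept
  tab3 <- make_fix_table(aoi = 1:2, confidence = c(0.9, 0.8999))
  expect_equal(nrow(filter_fixations(tab3)), 1L)
})

test_that("filter_fixations retains the hand-counted fraction and is idempotent", {
  withr::local_seed(71)
  n <- 1000
  tab <- make_fix_table(
    aoi = sample(1:8, n, TRUE),
    duration_ms = stats::runif(n, 0, 2000),
    confidence = stats::runif(n, 0.5, 1)
  )
  keep_hand <- sum(tab$duration_ms >= 100 & tab$duration_ms <= 1500 &
                     tab$confidence >= 0.9)
  out <- filter_fixations(tab)
  expect_equal(nrow(out), keep_hand)
  # idempotent (the second pass removes nothing; compare the rows,
  # not the pass-specific filter log)
  out2 <- filter_fixations(out)
  strip <- function(x) {
    attr(x, "filter_log") <- NULL
    x
  }
  expect_equal(strip(out2), strip(out))
  expect_equal(sum(attr(out2, "filter_log")$n_removed), 0L)
})

test_that("filter_fixations warns, not errors, on an empty result", {
  tab <- make_fix_table(aoi = 1:3, duration_ms = rep(50, 3))
  expect_warning(out <- filter_fixations(tab), "all fixations removed")
  expect_equal(nrow(out), 0L)
})

test_that("assign_periods matches a brute-force interval check", {
  onset <- c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  tab <- make_fix_table(aoi = rep(1, 12), onset = onset)
  ev <- make_events(onset = 6.5, lane_change = 8.5, end = 10.5)
  lab <- assign_periods(tab, ev)

  # brute force: interval check per fixation + last-5 baseline
  expected <- rep("none", 12)
  expected[onset >= 6.5 & onset < 8.5] <- "before_lane_change"
  expected[onset >= 8.5 & onset <= 10.5] <- "after_lane_change"
  pool <- which(expected == "none" & onset < 6.5)
  expected[utils::tail(pool, 5)] <- "baseline"
  expect_equal(as.character(lab$period), expected)
  expect_equal(unique(lab$trial_id[lab$period != "none"]), 1L)
})

test_that("invalid trials produce no labels and short baselines warn", {
  tab <- make_fix_table(aoi = rep(1, 10), onset = 1:10)
  ev_invalid <- make_events(onset = 4.5, lane_change = 6.5, end = 8.5,
                            valid = FALSE)
  lab <- assign_periods(tab, ev_invalid)
  expect_true(all(lab$period == "none"))

  # only 3 fixations exist before the trial onset -> baseline of 3 + warning
  ev <- make_events(onset = 3.5, lane_change = 5.5, end = 7.5)
  expect_warning(lab2 <- assign_periods(tab, ev), "baseline")
  expect_equal(sum(lab2$period == "baseline"), 3L)

  # overlapping trials -> structural error
  ev_bad <- make_events(onset = c(1.5, 3.5), lane_change = c(2.5, 4.5),
                        end = c(4, 6))
  expect_error(assign_periods(tab, ev_bad), "overlap")
})

test_that("assign_periods yields a partition of labeled fixations", {
  withr::local_seed(5)
  tab <- make_fix_table(aoi = sample(1:8, 120, TRUE), onset = seq_len(120))
  ev <- make_events(onset = c(20.5, 60.5, 95.5),
                    lane_change = c(30.5, 70.5, 100.5),
                    end = c(40.5, 80.5, 110.5))
  lab <- assign_periods(tab, ev)
  # every fixation carries exactly one period label
  expect_equal(length(lab$period), 120L)
  expect_false(anyNA(lab$period))
  counts <- table(lab$period)
  expect_equal(sum(counts), 120)
  expect_equal(unname(counts["baseline"]), 15) # 3 trials x 5
})

test_that("encode_scanpath round-trips the AOI column via the back-index", {
  tab <- make_fix_table(aoi = c(8, 8, 2, 8))
  p <- encode_scanpath(tab)
  expect_s3_class(p, "scanpath")
  expect_equal(unclass(p), c(8L, 8L, 2L, 8L), ignore_attr = TRUE)
  expect_equal(attr(p, "back_index"), 1:4)
  # decode via back-index reproduces the input column
  expect_equal(tab$aoi[attr(p, "back_index")], as.integer(unclass(p)),
               ignore_attr = TRUE)

  # filtered table: back-index stays valid against the filtered rows
  tab2 <- make_fix_table(aoi = 1:6, duration_ms = c(300, 50, 300, 50, 300,
                                                    300))
  kept <- filter_fixations(tab2)
  p2 <- encode_scanpath(kept)
  expect_equal(unclass(p2), c(1L, 3L, 5L, 6L), ignore_attr = TRUE)

  # multiple sessions without explicit split -> error
  tab3 <- make_fix_table(aoi = 1:4, session = c("s1", "s1", "s2", "s2"))
  expect_error(encode_scanpath(tab3), "multiple")
})

test_that("scanpath validates its alphabet", {
  expect_error(scanpath(c(1, 9, 2), A = 8), "outside the alphabet")
  expect_error(scanpath(integer(), A = 8), "at least one")
  expect_equal(alphabet_size(scanpath(1:4, A = 4)), 4L)
})
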
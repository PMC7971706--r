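test_that("plugin_distribution matches brute-force tuple counting", {
  # alternating chain: only two transition tuples, each probability 1/2
  p <- scanpath(rep(c(1, 2), 3), A = 2)
  d <- plugin_distribution(p, lags = 1)
  expect_equal(sort(d$p), c(0.4, 0.6)) # 5 transitions: 2-1 x3? no: check
  # n = 6, transitions t = 2..6: (2,1),(1,2),(2,1),(1,2),(2,1)
  expect_equal(d$p[d$x_t == 2 & d$x_tm1 == 1], 3 / 5)
  expect_equal(d$p[d$x_t == 1 & d$x_tm1 == 2], 2 / 5)

  # constant path: point mass
  d2 <- plugin_distribution(scanpath(rep(3, 4), A = 8), lags = 1)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$p, 1)
  expect_equal(d2$x_t, 3L)

  # random 50-symbol path, lags {1, 3}: every mass equals the
  # hand-counted tuple frequency
  withr::local_seed(42)
  x <- sample(1:4, 50, TRUE)
  d3 <- plugin_distribution(scanpath(x, A = 4), lags = c(1, 3))
  expect_equal(attr(d3, "n_eff"), 47L)
  expect_equal(sum(d3$p), 1, tolerance = 1e-12)
  ref <- oracle_tuple_freqs(x, c(1, 3))
  key <- paste(d3$x_t, d3$x_tm1, d3$x_tm3, sep = "-")
  expect_equal(unname(d3$p), unname(as.numeric(ref[key])))

  expect_error(plugin_distribution(scanpath(1:3, A = 8), lags = 5),
               "insufficient")
})

test_that("shannon_entropy reproduces closed-form values", {
  expect_equal(shannon_entropy(rep(1 / 8, 8)), 3)
  expect_equal(shannon_entropy(c(1, rep(0, 5))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.2)), "sum to 1")
})

test_that("GTE matches the brute-force conditional entropy", {
  # deterministic transitions: zero conditional entropy
  expect_equal(gaze_transition_entropy(scanpath(rep(1:2, 500), A = 2)), 0)
  expect_equal(gaze_transition_entropy(scanpath(rep(4, 50), A = 8)), 0)
  expect_error(gaze_transition_entropy(scanpath(3, A = 8)), "insufficient")

  # 30-symbol toy path against exhaustive frequency tables
  withr::local_seed(7)
  x <- sample(1:5, 30, TRUE)
  expect_equal(gaze_transition_entropy(scanpath(x, A = 5)), oracle_gte(x),
               tolerance = 1e-12)
})

test_that("AIS reproduces forced and enumerated values", {
  # alternating 2-symbol path: H(X_t) = 1, GTE = 0, so AIS = 1
  # (odd length so the eligible target marginal is exactly uniform)
  alt <- scanpath(c(rep(c(1, 2), 500), 1), A = 2)
  expect_equal(active_information_storage(alt, 1), 1)

  # x_t = x_{t-2} holds on the alternating orbit: lag 2 is fully
  # informative there as well (up to one-sample marginal imbalance)
  expect_equal(active_information_storage(alt, 2), 1, tolerance = 1e-5)

  # at the process level, a lag-2 ("return to the AOI two fixations
  # back") chain makes lag 2 informative and lag 1 exactly useless:
  # the two parity subsequences are independent
  spec2 <- build_chain(A = 2, active_lags = 2, rho = 0.9, map = "repeat")
  ex2 <- exact_measures(spec2, 2)
  ex1 <- exact_measures(spec2, 1)
  expect_gt(ex2$ais, 0.5)
  expect_equal(ex1$ais, 0, tolerance = 1e-10)
  long2 <- simulate_scanpath(spec2, 2e4, seed = 51)
  expect_equal(active_information_storage(long2, 2), ex2$ais,
               tolerance = 0.02)
  expect_lt(active_information_storage(long2, 1), 0.01)

  # i.i.d. uniform path: AIS at bias level only
  withr::local_seed(11)
  iid <- scanpath(sample(1:4, 1e5, TRUE), A = 4)
  expect_lt(active_information_storage(iid, 1), 0.005)

  # brute-force oracle on a random path
  withr::local_seed(13)
  y <- sample(1:3, 60, TRUE)
  expect_equal(active_information_storage(scanpath(y, A = 3), c(1, 2)),
               oracle_ais(y, c(1, 2)), tolerance = 1e-12)

  expect_warning(out <- active_information_storage(alt, integer()),
                 "empty lag set")
  expect_equal(out, 0)
})

test_that("plug-in AIS is monotone in the lag set on a common sample base", {
  withr::local_seed(17)
  x <- scanpath(sample(1:4, 300, TRUE), A = 4)
  sets <- list(1L, c(1L, 2L), c(1L, 2L, 4L), c(1L, 2L, 4L, 5L))
  vals <- vapply(sets, function(s) {
    active_information_storage(x, s, min_history = 5)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("stationary gaze entropy reflects marginal dispersion", {
  expect_equal(stationary_gaze_entropy(scanpath(rep(2, 10), A = 8)), 0)
  expect_equal(stationary_gaze_entropy(scanpath(rep(1:8, 5), A = 8)), 3)
  x <- c(rep(1, 5), rep(2, 3), rep(3, 2))
  expect_equal(stationary_gaze_entropy(scanpath(x, A = 3)),
               oracle_entropy(c(0.5, 0.3, 0.2)))
})

test_that("CMI reduces to MI without conditioning and matches 3-way tables", {
  withr::local_seed(19)
  x <- sample(1:3, 200, TRUE)
  p <- scanpath(x, A = 3)
  expect_equal(conditional_mutual_information(p, 2),
               oracle_cmi(x, 2, integer()), tolerance = 1e-12)

  # 15-symbol toy path with conditioning
  withr::local_seed(23)
  y <- sample(1:2, 15, TRUE)
  expect_equal(conditional_mutual_information(scanpath(y, A = 2), 2, 1),
               oracle_cmi(y, 2, 1), tolerance = 1e-12)

  # order-1 chain: CMI of lag 2 given {1} is bias-level at n = 1e5
  spec <- build_chain(A = 3, active_lags = 1, rho = 0.6)
  long <- simulate_scanpath(spec, 1e5, seed = 29)
  expect_lt(conditional_mutual_information(long, 2, 1), 0.001)

  expect_error(conditional_mutual_information(p, 1, 1), "must not be in")
})

test_that("local measures agree with direct evaluation of logged ratios", {
  withr::local_seed(31)
  x <- sample(1:3, 20, TRUE)
  p <- scanpath(x, A = 3)
  lm1 <- local_measures(p, 1)
  ref <- oracle_local(x, 1)
  expect_equal(lm1$lais[ref$t], ref$lais, tolerance = 1e-12)
  expect_equal(lm1$h_local[ref$t], ref$h_local, tolerance = 1e-12)
  expect_equal(lm1$h_joint_ais[ref$t], ref$h_joint, tolerance = 1e-12)
  # lag-1 joint entropy equals the AIS-side joint for lags {1}
  expect_equal(lm1$h_joint_gte[ref$t], lm1$h_joint_ais[ref$t],
               tolerance = 1e-12)

  # with lags {1, 3}
  lm13 <- local_measures(p, c(1, 3))
  ref13 <- oracle_local(x, c(1, 3))
  expect_equal(lm13$lais[ref13$t], ref13$lais, tolerance = 1e-12)
  expect_true(all(is.na(lm13$lais[1:3])))
})

test_that("local series average to the global measures", {
  withr::local_seed(37)
  x <- scanpath(sample(1:8, 400, TRUE), A = 8)
  for (lags in list(1L, c(1L, 2L), c(2L, 4L))) {
    lm <- local_measures(x, lags)
    expect_equal(mean(lm$lais, na.rm = TRUE),
                 active_information_storage(x, lags), tolerance = 1e-10)
  }
  lm <- local_measures(x, 1L)
  expect_equal(mean(lm$lgte, na.rm = TRUE), gaze_transition_entropy(x),
               tolerance = 1e-10)
})

test_that("LAIS and LGTE sum to the local entropy for a lag-1 past state", {
  withr::local_seed(41)
  x <- scanpath(sample(1:6, 300, TRUE), A = 6)
  lm <- local_measures(x, 1)
  idx <- 2:length(x)
  expect_equal(lm$lais[idx] + lm$lgte[idx], lm$h_local[idx],
               tolerance = 1e-10)
})

test_that("negative LAIS values occur and flag misinformative pasts", {
  withr::local_seed(43)
  x <- scanpath(sample(1:4, 500, TRUE), A = 4)
  lm <- local_measures(x, 1)
  expect_true(any(lm$lais < 0, na.rm = TRUE))
  expect_true(all(lm$lgte >= 0, na.rm = TRUE))
})
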
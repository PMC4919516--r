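test_that("PSTH matches hand-counted and brute-force expectations", {
  w <- analysis_windows()
  # empty train: 20 zero bins
  ps <- compute_psth(numeric(0), onsets = 50, windows = w)
  expect_equal(length(ps$rate), 20)
  expect_equal(ps$rate, rep(0, 20))

  # single event with spikes 0.5 s and 1.5 s after onset: bins 6 and 7 at 1 Hz
  ps <- compute_psth(c(50.5, 51.5), onsets = 50, windows = w)
  expect_equal(ps$rate[6], 1)
  expect_equal(ps$rate[7], 1)
  expect_equal(sum(ps$rate), 2)

  # homogeneous Poisson at 5 Hz: every bin near 5 Hz
  set.seed(4)
  t_end <- 60 * 20 + 20
  times <- sort(runif(rpois(1, 5 * t_end), 0, t_end))
  onsets <- 10 + (0:49) * 20
  ps <- compute_psth(times, onsets, w)
  se <- sqrt(5 / 50)  # Poisson bin-count variance over 50 events
  expect_true(all(abs(ps$rate - 5) <= 3.5 * se))

  # brute-force agreement on random instances
  for (i in 1:25) {
    set.seed(i)
    times <- sort(runif(rpois(1, 100), 0, 200))
    onsets <- runif(3, 20, 150)
    expect_equal(compute_psth(times, onsets, w)$rate,
                 bf_psth(times, onsets), tolerance = 1e-12)
  }
})

test_that("PSTH mass equals mean spike count per event in the window", {
  w <- analysis_windows()
  for (i in 1:10) {
    set.seed(100 + i)
    times <- sort(runif(rpois(1, 300), 0, 400))
    onsets <- seq(20, 360, by = 40)
    ps <- compute_psth(times, onsets, w)
    in_win <- vapply(onsets, function(o)
      sum(times >= o - 5 & times < o + 15), numeric(1))
    expect_equal(sum(ps$rate) * w$psth_bin, mean(in_win), tolerance = 1e-12)
  }
})

test_that("events outside the recorded span are dropped and flagged", {
  w <- analysis_windows()
  ps <- compute_psth(c(3, 12), onsets = c(4, 50), windows = w, span = c(0, 100))
  expect_equal(ps$dropped, 1L)  # first onset's pre-window precedes 0
  expect_equal(ps$n_events, 1L)
  expect_error(compute_psth(1:3, onsets = 2, windows = w, span = c(0, 10)),
               class = "aobtune_validation_error")
})

test_that("delta-R is response rate minus baseline rate", {
  # 10 baseline spikes over 5 s, 12 response spikes over 4 s: 3 - 2 = 1 Hz
  times <- c(seq(5.1, 9.9, length.out = 10), seq(11.1, 14.9, length.out = 12))
  expect_equal(compute_delta_r(times, onset = 10), 1)
  expect_equal(compute_delta_r(numeric(0), onset = 10), 0)
})

test_that("delta-R equals the brute-force oracle on random spike sets", {
  w <- analysis_windows()
  for (i in 1:100) {
    set.seed(i)
    times <- sort(runif(rpois(1, 60), 0, 60))
    onset <- runif(1, 6, 50)
    expect_equal(compute_delta_r(times, onset, w), bf_delta_r(times, onset),
                 tolerance = 1e-12)
  }
})

test_that("planted-effect simulations recover Delta through delta-R", {
  p <- stimulus_panel(c("ringers", "dca"), control = "ringers")
  eff <- matrix(c(0, 10), 1, 2, dimnames = list(NULL, p$stimuli$id))
  cfg <- generator_config(1, p, baseline_hz = 1, effect_hz = eff,
                          trials_per_stimulus = 40, jitter_sd = 0.2, seed = 8)
  s <- simulate_session(cfg)
  resp <- session_responses(s)
  dr <- resp$delta_r_hz[resp$stimulus_id == "dca"]
  expect_true(abs(mean(dr) - 10) <= 3 * sd(dr) / sqrt(length(dr)))
})

test_that("significance calling applies both the t-test and the rate floor", {
  # identical draws in both groups: never significant
  x <- c(1.2, 1.4, 1.1, 1.3, 1.2)
  r <- call_response(x, x)
  expect_false(r$significant)
  expect_equal(r$p_value, 1, tolerance = 1e-9)

  # clear effect: significant
  r <- call_response(c(9, 10, 11, 10, 9.5), c(0.1, -0.2, 0, 0.1, 0))
  expect_true(r$significant)
  expect_lt(r$p_value, 0.05)

  # tiny but consistent increase: t-test passes, rate criterion fails
  r <- call_response(c(0.80, 0.81, 0.79, 0.80, 0.80), c(0, 0.01, -0.01, 0, 0))
  expect_lt(r$p_value, 0.05)
  expect_false(r$rate_ok)
  expect_false(r$significant)

  # under 3 trials: unanalyzable, not FALSE
  r <- call_response(c(5, 6), c(0, 0, 0))
  expect_true(is.na(r$significant))

  # absolute-rate reading uses the window rate itself
  r <- call_response(c(5, 6, 5.5, 6, 5), c(0, 0.1, -0.1, 0, 0.1),
                     rate_criterion = "absolute",
                     response_hz = c(7, 8, 7.5, 8, 7))
  expect_true(r$significant)
})

test_that("cell inclusion follows the response/control/trial-count rules", {
  r <- include_cell(c(FALSE, FALSE), FALSE, c(5, 5, 5))
  expect_false(r$included); expect_equal(r$reason, "no response")

  r <- include_cell(c(TRUE, FALSE), TRUE, c(5, 5, 5))
  expect_false(r$included); expect_equal(r$reason, "control responsive")

  r <- include_cell(c(TRUE, FALSE), FALSE, c(5, 5, 5))
  expect_true(r$included)

  r <- include_cell(c(TRUE, NA), FALSE, c(5, 2, 5))
  expect_false(r$included); expect_equal(r$reason, "insufficient trials")
})

test_that("tuning normalization scales the strongest response to +/-1", {
  expect_equal(normalize_tuning(c(2, 4, -1)), c(0.5, 1, -0.25))
  expect_equal(normalize_tuning(3), 1)
  for (i in 1:20) {
    set.seed(i)
    v <- rnorm(5)
    expect_equal(max(abs(normalize_tuning(v))), 1)
  }
  expect_error(normalize_tuning(c(0, 0)), class = "aobtune_validation_error")
})

test_that("the tuning table integrates calls, inclusion and normalization", {
  p <- demo_panel()
  eff <- matrix(0, 3, 3, dimnames = list(NULL, p$stimuli$id))
  eff[1, "urine"] <- 10
  eff[2, "faeces"] <- 10
  # cell 3 stays a non-responder
  s <- simulate_session(generator_config(3, p, baseline_hz = 1,
                                         effect_hz = eff, seed = 21))
  tt <- build_tuning_table(s)
  expect_s3_class(tt, "tuning_table")
  expect_equal(tt$cells$reason[3], "no response")
  expect_true(all(tt$cells$included[1:2]))
  m <- tuning_matrix(tt)
  expect_equal(dim(m), c(2, 2))
  expect_true(all(abs(m) <= 1))
  expect_equal(unname(m["cell_001", "urine"]), 1)
  rm <- response_matrix(tt)
  expect_identical(unname(rm),
                   matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2, byrow = TRUE))
})

test_that("fluorescence ratio divides post-stack mean by baseline mean", {
  expect_equal(compute_dff(c(100, 100, 100, 120, 120, 120), 4), 1.2)
  expect_equal(compute_dff(rep(7, 6), 4), 1)
  expect_equal(compute_dff(c(90, 100, 110, 200, 210, 190), 4), 2)
  expect_error(compute_dff(c(1, 2, 3, 4), 3),
               class = "aobtune_validation_error")
  expect_error(compute_dff(c(0, 0, 0, 1, 1, 1), 4),
               class = "aobtune_validation_error")
})
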
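test_that("d-prime evaluates the pooled-variance sensitivity index", {
  x <- c(1, 2, 3)
  expect_equal(dprime(x, x), 0)
  # equal variances, means 2 apart: |diff| / sqrt(var)
  x <- c(2.8, 4, 5.2, 3.2, 4.8); y <- x - 2
  expect_equal(dprime(x, y), 2 / sqrt(var(x)))
  # reference arithmetic: means 4 and 2 with both variances 2 give sqrt(2)
  x2 <- 4 + c(-1, -1, 1, 1) * sqrt(1.5); y2 <- x2 - 2  # var(x2) = 2
  expect_equal(var(x2), 2)
  expect_equal(dprime(x2, y2), sqrt(2))

  # symmetry and scale invariance
  for (i in 1:50) {
    set.seed(i)
    a <- rnorm(6, 2); b <- rnorm(6)
    expect_equal(dprime(a, b), dprime(b, a))
    c_ <- runif(1, 0.1, 10)
    expect_equal(dprime(c_ * a, c_ * b), dprime(a, b), tolerance = 1e-12)
    expect_equal(dprime(a, b), bf_dprime(a, b), tolerance = 1e-12)
  }

  expect_error(dprime(1, 2), class = "aobtune_validation_error")
  expect_equal(dprime(c(3, 3, 3), c(3, 3)), 0)
  expect_error(dprime(c(3, 3, 3), c(4, 4)),
               class = "aobtune_validation_error")
})

test_that("the fast two-group Kruskal-Wallis matches stats::kruskal.test", {
  for (i in 1:50) {
    set.seed(i)
    x <- rnorm(10)
    y <- rnorm(12, mean = runif(1, 0, 2))
    if (i %% 3 == 0) { x <- round(x); y <- round(y) }  # force ties
    expect_equal(aobtune:::kw2_pvalue(x, y),
                 stats::kruskal.test(list(x, y))$p.value, tolerance = 1e-10)
  }
})

test_that("shuffle test contracts: population size, n_model, determinism", {
  one <- list(c(1, 2, 3))
  expect_error(shuffle_test(one, one, n_model = 10),
               class = "aobtune_validation_error")
  two_a <- list(c(1, 2, 3), c(2, 3, 4))
  two_b <- list(c(0, 1, 2), c(1, 2, 3))
  expect_error(shuffle_test(two_a, two_b, n_model = 0),
               class = "aobtune_validation_error")
  s1 <- shuffle_test(two_a, two_b, n_model = 50, seed = 5)
  s2 <- shuffle_test(two_a, two_b, n_model = 50, seed = 5)
  expect_identical(s1$fraction_lower, s2$fraction_lower)
  expect_identical(s1$model_medians, s2$model_medians)
})

test_that("exchangeable populations are rarely called discriminating", {
  set.seed(31)
  trials_a <- replicate(60, rnorm(5, mean = 1), simplify = FALSE)
  trials_b <- replicate(60, rnorm(5, mean = 1), simplify = FALSE)
  sh <- shuffle_test(trials_a, trials_b, n_model = 1000, seed = 13)
  expect_lte(sh$fraction_lower, 0.05)
})

test_that("consistent per-cell selectivity drives the shuffle fraction up", {
  set.seed(32)
  # half the cells prefer stimulus A, half prefer B, strongly and reliably
  pref <- rep(c(0, 6), each = 25)
  trials_a <- lapply(pref, function(p) rnorm(5, mean = p, sd = 0.5))
  trials_b <- lapply(rev(pref), function(p) rnorm(5, mean = p, sd = 0.5))
  sh <- shuffle_test(trials_a, trials_b, n_model = 1000, seed = 13)
  expect_gt(sh$fraction_lower, 0.5)
})

test_that("values mode rebuilds trial sets from pooled normalized values", {
  set.seed(33)
  trials_a <- replicate(20, rnorm(5), simplify = FALSE)
  trials_b <- replicate(20, rnorm(4), simplify = FALSE)
  sh <- shuffle_test(trials_a, trials_b, n_model = 200, seed = 3,
                     mode = "values", keep_models = TRUE)
  expect_equal(dim(sh$model_dprime), c(20, 200))
  expect_true(all(sh$model_dprime >= 0))
  s2 <- shuffle_test(trials_a, trials_b, n_model = 200, seed = 3,
                     mode = "values")
  expect_identical(sh$fraction_lower, s2$fraction_lower)
})

test_that("d-prime histograms conserve cell counts and match nulls", {
  h <- dprime_histogram(0, bin_width = 0.25)
  expect_equal(h$observed_count[1], 1)
  expect_equal(sum(h$observed_count), 1)

  set.seed(34)
  trials_a <- replicate(40, rnorm(5), simplify = FALSE)
  trials_b <- replicate(40, rnorm(5), simplify = FALSE)
  sh <- shuffle_test(trials_a, trials_b, n_model = 400, seed = 7,
                     keep_models = TRUE)
  h <- dprime_histogram(sh, bin_width = 0.5)
  expect_equal(sum(h$observed_count), 40)
  expect_equal(sum(h$model_mean_count), 40, tolerance = 1e-9)
  # every model population also holds exactly 40 cells
  cnts <- apply(sh$model_dprime, 2, function(col)
    sum(col >= 0))
  expect_true(all(cnts == 40))
  # under exchangeability the shuffled-mean histogram resembles the observed
  ok <- h$observed_count + h$model_mean_count > 0
  chi <- suppressWarnings(chisq.test(h$observed_count[ok],
                                     p = h$model_mean_count[ok] /
                                       sum(h$model_mean_count[ok])))
  expect_gt(chi$p.value, 0.05)
})

test_that("trial_sets extracts per-cell normalized delta-R vectors", {
  p <- demo_panel()
  eff <- matrix(0, 2, 3, dimnames = list(NULL, p$stimuli$id))
  eff[, "urine"] <- c(10, 4); eff[, "faeces"] <- c(4, 10)
  s <- simulate_session(generator_config(2, p, baseline_hz = 1,
                                         effect_hz = eff, seed = 17))
  tt <- build_tuning_table(s)
  ts <- trial_sets(tt, "urine", "faeces")
  expect_equal(names(ts$trials_a), tt$cells$cell_id[tt$cells$included])
  # normalized scale: every trial value bounded by max |mean| ratio
  expect_true(all(vapply(ts$trials_a, length, 1L) == 5))
  raw <- trial_sets(tt, "urine", "faeces", normalized = FALSE)
  cell <- names(ts$trials_a)[1]
  mx <- max(abs(tt$calls$mean_delta_r[tt$calls$cell_id == cell]))
  expect_equal(ts$trials_a[[cell]], raw$trials_a[[cell]] / mx)
  expect_error(trial_sets(tt, "urine", "nope"),
               class = "aobtune_validation_error")
})
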
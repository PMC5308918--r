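test_that("window means average non-overlapping blocks and drop the tail", {
  expect_equal(window_means(1:10, 5)$means, c(3, 8))
  expect_equal(window_means(1:11, 5)$means, c(3, 8)) # partial tail dropped
  expect_equal(window_means(rep(7, 20), 4)$means, rep(7, 5))
  expect_equal(window_means(1:6, 1)$means, 1:6)
  expect_error(window_means(1:5, 3), "too short")
})

test_that("Mann-Kendall agrees with the Kendall correlation against time", {
  set.seed(30)
  x <- rnorm(40)
  mk <- mann_kendall_test(x)
  ct <- stats::cor.test(x, seq_along(x), method = "kendall")
  expect_equal(mk$details$S, unname(ct$estimate) * 40 * 39 / 2)
  expect_lt(abs(mk$p_value - ct$p.value), 0.05)

  # strictly monotone input: perfect concordance, minimal p
  mono <- mann_kendall_test(seq_len(30))
  expect_lt(mono$p_value, 1e-8)
  expect_true(mono$reject)
  expect_error(mann_kendall_test(1:3), "at least 4")
})

test_that("runs test flags oscillation and level shifts", {
  osc <- runs_test(rep(c(1, -1), 25))      # far too many runs
  expect_true(osc$reject)
  shift <- runs_test(c(rep(0, 25), rep(5, 25))) # two runs only
  expect_true(shift$reject)
  all_equal <- runs_test(rep(3, 20))       # no deviations from the median
  expect_equal(all_equal$p_value, 1)
  expect_false(all_equal$reject)
})

test_that("stationarity test rejects trends and tolerates white noise", {
  set.seed(31)
  # linear drift dominating the noise
  trend <- 0.1 * seq_len(2000) + rnorm(2000)
  out <- stationarity_test(trend, window_length = 50)
  expect_true(out$reject)
  expect_lt(out$p_value, 1e-6)

  # the combined decision is Bonferroni over the two component tests
  iid <- rnorm(2000)
  res <- stationarity_test(iid, window_length = 50, alpha = 0.05)
  p1 <- res$details$mann_kendall$p_value
  p2 <- res$details$runs$p_value
  expect_equal(res$p_value, min(1, 2 * min(p1, p2)))
  expect_equal(res$reject, res$p_value < 0.05)
  expect_error(stationarity_test(rnorm(160), window_length = 50), "4 windows")
})

test_that("autocorrelation time matches the AR(1) closed form", {
  set.seed(32)
  expect_equal(autocorr_time(rep(5, 100)), 1L)
  iid <- replicate(10, autocorr_time(rnorm(1000)))
  expect_true(median(iid) == 1)
  # phi = 0.9: first lag below 0.1 is ceil(log(0.1)/log(0.9)) = 22
  ar <- replicate(15, autocorr_time(as.numeric(
    stats::arima.sim(list(ar = 0.9), 5000))))
  expect_gt(median(ar), 15)
  expect_lt(median(ar), 30)
  expect_error(autocorr_time(rnorm(20)), "too short")
})

test_that("ergodicity test keeps identical samples and separates shifted ones", {
  set.seed(33)
  x <- rnorm(400)
  same <- ergodicity_test(x, x, thin_lag = 1)
  expect_false(same$reject)
  expect_true(same$details$ergodic)

  shifted <- ergodicity_test(rnorm(500, 1), rnorm(500, 0), thin_lag = 1)
  expect_true(shifted$reject)
  expect_false(shifted$details$ergodic)

  degen <- ergodicity_test(rep(2, 100), rep(2, 50))
  expect_equal(degen$p_value, 1)
  expect_false(degen$reject)

  expect_error(ergodicity_test(numeric(0), rnorm(5)), "non-empty")

  # thinning is applied to the time sample
  thl <- ergodicity_test(rnorm(600), rnorm(100), thin_lag = 3)
  expect_equal(thl$details$n_time, 200)
})

test_that("stationarity onset finds the settled part of a series", {
  set.seed(34)
  x <- c(seq(100, 0, length.out = 300) + rnorm(300),  # decaying transient
         rnorm(1200))                                  # settled regime
  on <- stationarity_onset(x, span = 600, window_length = 30)
  expect_false(is.na(on$start_index))
  expect_gt(on$start_index, 1)
  expect_lt(on$start_index, 700)
})
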
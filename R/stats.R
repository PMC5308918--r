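#' Test result container
#'
#' @param statistic test statistic.
#' @param p_value p-value in \[0, 1\].
#' @param alpha significance level.
#' @param method label of the procedure.
#' @param details optional list of component results.
#' @return object of class `"abm_test"`; `reject` is `p_value < alpha`.
#' @keywords internal
abm_test <- function(statistic, p_value, alpha, method, details = NULL) {
  out <- list(statistic = unname(statistic),
              p_value = min(max(unname(p_value), 0), 1),
              alpha = alpha, reject = unname(p_value) < alpha,
              method = method, details = details)
  class(out) <- "abm_test"
  out
}

#' @export
print.abm_test <- function(x, ...) {
  cat(sprintf("<abm_test> %s\n  statistic = %.4g, p = %.4g, alpha = %g -> %s\n",
              x$method, x$statistic, x$p_value, x$alpha,
              if (x$reject) "REJECT" else "do not reject"))
  invisible(x)
}

#' Non-overlapping window means
#'
#' Averages a series over consecutive non-overlapping windows of
#' `window_length` steps; a trailing partial window is dropped. Short-term
#' fluctuations of the raw output make step-wise stationarity tests reject
#' even in a settled regime, so the tests below operate on these window
#' means instead.
#'
#' @param x numeric vector (e.g. the `n` column of a [run_abm()] series).
#' @param window_length window size in recorded steps (>= 1).
#' @return object of class `"window_means"`: list with `window_length` and
#'   `means` (length `floor(length(x) / window_length)`).
#' @examples
#' window_means(1:10, 5)$means # 3, 8
#' @export
window_means <- function(x, window_length) {
  x <- as.numeric(x)
  window_length <- as.integer(window_length)
  if (window_length < 1) stop("window_length must be >= 1")
  if (length(x) < 2 * window_length)
    stop("series too short: need at least 2 windows of ", window_length)
  k <- length(x) %/% window_length
  m <- colMeans(matrix(x[seq_len(k * window_length)],
                       nrow = window_length, ncol = k))
  out <- list(window_length = window_length, means = m)
  class(out) <- "window_means"
  out
}

#' Mann-Kendall trend test
#'
#' Rank-based test for a monotone trend: the statistic
#' `S = sum_{i<j} sign(x_j - x_i)` is standardized by its null variance
#' (with tie correction and continuity correction) and referred to the
#' normal distribution.
#'
#' @param x numeric series.
#' @param alpha significance level.
#' @return an `"abm_test"`; `statistic` is the standardized `Z`, with the
#'   raw `S` and its variance in `details`.
#' @export
mann_kendall_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("Mann-Kendall test needs at least 4 observations")
  S <- 0
  for (i in seq_len(n - 1))
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (varS <= 0) return(abm_test(0, 1, alpha, "Mann-Kendall trend test",
                                 details = list(S = S, var_S = varS)))
  z <- (S - sign(S)) / sqrt(varS) # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  abm_test(z, p, alpha, "Mann-Kendall trend test",
           details = list(S = S, var_S = varS))
}

#' Runs test about the median
#'
#' Wald-Wolfowitz test of randomness: the series is reduced to the signs of
#' its deviations from the median (zeros dropped) and the number of runs of
#' equal signs is compared to its null distribution via the normal
#' approximation with continuity correction. Too few runs indicate
#' persistent level shifts; too many indicate oscillation.
#'
#' @param x numeric series.
#' @param alpha significance level.
#' @return an `"abm_test"`; `statistic` is the standardized `Z`, with run
#'   counts in `details`.
#' @export
runs_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  s <- sign(x - stats::median(x))
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0)
    return(abm_test(0, 1, alpha, "runs test (signs about the median)",
                    details = list(runs = NA, n_pos = n1, n_neg = n2)))
  r <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0)
    return(abm_test(0, 1, alpha, "runs test (signs about the median)",
                    details = list(runs = r, n_pos = n1, n_neg = n2)))
  z <- (r - mu + 0.5 * sign(mu - r)) / sqrt(v) # continuity correction
  if (r == mu) z <- 0
  p <- 2 * stats::pnorm(-abs(z))
  abm_test(z, p, alpha, "runs test (signs about the median)",
           details = list(runs = r, n_pos = n1, n_neg = n2, mean_runs = mu))
}

#' Stationarity test on window means
#'
#' Tests whether a series of simulator output has settled into a regime
#' without long-term changes. The series is averaged over non-overlapping
#' windows ([window_means()]) and two complementary tests are applied to
#' the window means: a Mann-Kendall trend test (drift in location) and a
#' runs test about the median (persistent excursions). Each component is
#' run at level `alpha / 2` and stationarity is rejected if either rejects
#' (Bonferroni), i.e. the combined p-value is `min(1, 2 * min(p1, p2))`.
#'
#' @param x numeric series, or a `population_ts` (its `n` column is used).
#' @param window_length window size in recorded steps.
#' @param alpha overall significance level.
#' @return an `"abm_test"` with the two component tests in `details`.
#' @export
stationarity_test <- function(x, window_length, alpha = 0.05) {
  if (is.data.frame(x)) x <- x$n
  wm <- window_means(x, window_length)
  if (length(wm$means) < 4)
    stop("need at least 4 windows for the stationarity test")
  mk <- mann_kendall_test(wm$means, alpha / 2)
  rt <- runs_test(wm$means, alpha / 2)
  p <- min(1, 2 * min(mk$p_value, rt$p_value))
  abm_test(mk$statistic, p, alpha,
           "stationarity of window means (Mann-Kendall + runs, Bonferroni)",
           details = list(mann_kendall = mk, runs = rt,
                          n_windows = length(wm$means),
                          window_length = window_length))
}

#' Autocorrelation time of a series
#'
#' The smallest lag at which the sample autocorrelation drops below 0.1
#' (at least 1), searched up to lag 500 (or the series length). Used to
#' thin dependent single-run samples before two-sample comparisons; slowly
#' wandering simulator output can carry correlations over hundreds of
#' recorded steps, so the search window must be generous. A constant
#' series is treated as uncorrelated.
#'
#' @param x numeric series of length >= 50.
#' @return integer lag >= 1.
#' @examples
#' autocorr_time(rnorm(500)) # 1
#' @export
autocorr_time <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 50) stop("series too short (need >= 50) for autocorr_time")
  if (stats::sd(x) == 0) return(1L)
  lag_max <- min(length(x) - 1, 500)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  below <- which(ac < 0.1)
  if (length(below) == 0) return(as.integer(lag_max))
  max(1L, as.integer(below[1]))
}

#' Ergodicity test
#'
#' Compares the output sample of a single long model run (one value per
#' recorded step) with an across-replicate sample taken at a fixed time.
#' The single-run sample is thinned by `thin_lag` (default: its estimated
#' [autocorr_time()]) to reduce serial dependence, and the two samples are
#' compared with a two-sample Kolmogorov-Smirnov test. The model is
#' considered ergodic if the null hypothesis that the samples come from the
#' same distribution is *not* rejected; rejection indicates variation over
#' time beyond replicate stochasticity, e.g. ongoing adaptation.
#'
#' @param time_sample numeric sample from a single run over time.
#' @param ensemble_sample numeric sample over replicates at a set time.
#' @param alpha significance level.
#' @param thin_lag thinning interval for the time sample (>= 1); `NULL`
#'   estimates it from the sample.
#' @return an `"abm_test"`; `details$ergodic` is `!reject`.
#' @export
ergodicity_test <- function(time_sample, ensemble_sample, alpha = 0.05,
                            thin_lag = NULL) {
  time_sample <- as.numeric(time_sample)
  ensemble_sample <- as.numeric(ensemble_sample)
  if (length(time_sample) == 0 || length(ensemble_sample) == 0)
    stop("both samples must be non-empty")
  if (is.null(thin_lag))
    thin_lag <- if (length(time_sample) >= 50) autocorr_time(time_sample)
                else 1L
  if (thin_lag < 1) stop("thin_lag must be >= 1")
  thinned <- time_sample[seq(1, length(time_sample), by = thin_lag)]
  if (stats::sd(c(thinned, ensemble_sample)) == 0) {
    # degenerate: both samples constant and equal
    t <- abm_test(0, 1, alpha, "ergodicity (two-sample Kolmogorov-Smirnov)",
                  details = list(thin_lag = thin_lag, ergodic = TRUE,
                                 n_time = length(thinned),
                                 n_ensemble = length(ensemble_sample)))
    return(t)
  }
  ks <- suppressWarnings(stats::ks.test(thinned, ensemble_sample))
  out <- abm_test(ks$statistic, ks$p.value, alpha,
                  "ergodicity (two-sample Kolmogorov-Smirnov)",
                  details = list(thin_lag = thin_lag,
                                 n_time = length(thinned),
                                 n_ensemble = length(ensemble_sample)))
  out$details$ergodic <- !out$reject
  out
}

#' Earliest stationary window of a series
#'
#' Scans candidate start times and returns the first one from which the
#' following `span` steps pass the [stationarity_test()]. This implements
#' the workflow in which the stationarity analysis feeds the starting point
#' of the ergodicity test.
#'
#' @param series a `population_ts` or numeric vector.
#' @param span length (in recorded steps) of the window tested at each
#'   candidate start.
#' @param window_length window size passed to [stationarity_test()].
#' @param alpha significance level per scan step.
#' @param candidates candidate start indices (default: 10 evenly spaced
#'   positions in the first half of the series).
#' @return list with `start_index` (`NA` if no candidate passes), `tested`
#'   (data frame of candidate starts and p-values).
#' @export
stationarity_onset <- function(series, span, window_length, alpha = 0.05,
                               candidates = NULL) {
  x <- if (is.data.frame(series)) series$n else as.numeric(series)
  if (is.null(candidates)) {
    last <- length(x) - span + 1
    if (last < 1) stop("span exceeds the series length")
    candidates <- unique(pmax(1, floor(seq(1, max(1, last / 2), length.out = 10))))
  }
  ps <- rep(NA_real_, length(candidates))
  hit <- NA_integer_
  for (k in seq_along(candidates)) {
    i0 <- candidates[k]
    seg <- x[i0:min(length(x), i0 + span - 1)]
    t <- tryCatch(stationarity_test(seg, window_length, alpha),
                  error = function(e) NULL)
    if (is.null(t)) next
    ps[k] <- t$p_value
    if (!t$reject) { hit <- i0; break }
  }
  list(start_index = hit,
       tested = data.frame(start = candidates, p_value = ps))
}
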
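#' Compare the adaptive and non-adaptive model variants
#'
#' The core measurement workflow: run replicate ensembles of the model with
#' adaptation enabled and disabled (all other settings shared), build the
#' time-dependent histograms of the population size, and quantify their
#' divergence with the adaptation-effect curve `Q(t)` (earth-mover's
#' distance per recorded time) and the adaptation rate `Q'(t)`.
#'
#' @param cfg a [sim_config()]; its `adaptive` field is overridden per
#'   variant.
#' @param n_rep replicates per variant.
#' @param t_end run length.
#' @param record_every recording interval (the grid on which `Q` and `Q'`
#'   live).
#' @param master_seed master seed; the two variants get independent
#'   streams.
#' @param shared_seeds if `TRUE`, both variants use identical replicate
#'   seeds (useful for interpreting `Q ~ 0` checks; the variants still
#'   diverge through their different inheritance draws).
#' @return list of class `"adaptation_comparison"` with elements
#'   `ens_adaptive`, `ens_nonadaptive`, `hist_adaptive`,
#'   `hist_nonadaptive`, `Q` (distance curve) and `Qprime`.
#' @export
compare_adaptation <- function(cfg, n_rep, t_end, record_every,
                               master_seed = 1, shared_seeds = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_a <- replicate_seed(master_seed, 1)
  seed_b <- if (shared_seeds) seed_a else replicate_seed(master_seed, 2)
  ens_a <- run_ensemble(update_config(cfg, adaptive = TRUE), n_rep = n_rep,
                        t_end = t_end, record_every = record_every,
                        master_seed = seed_a)
  ens_b <- run_ensemble(update_config(cfg, adaptive = FALSE), n_rep = n_rep,
                        t_end = t_end, record_every = record_every,
                        master_seed = seed_b)
  h_a <- time_dependent_histogram(ens_a)
  h_b <- time_dependent_histogram(ens_b)
  q <- adaptation_effect(h_a, h_b)
  out <- list(ens_adaptive = ens_a, ens_nonadaptive = ens_b,
              hist_adaptive = h_a, hist_nonadaptive = h_b,
              Q = q, Qprime = adaptation_rate(q))
  class(out) <- "adaptation_comparison"
  out
}

#' @export
print.adaptation_comparison <- function(x, ...) {
  cat(sprintf("<adaptation_comparison> %d replicates/variant, t up to %g\n",
              nrow(x$ens_adaptive$n_matrix), max(x$Q$t)))
  cat(sprintf("  Q: first %.3f, last %.3f, max %.3f\n", x$Q$Q[1],
              x$Q$Q[nrow(x$Q)], max(x$Q$Q)))
  invisible(x)
}

#' Stationarity-then-ergodicity diagnostic workflow
#'
#' Runs the two statistical diagnostics in their natural order for one
#' model variant. First a replicate ensemble is recorded and the
#' ensemble-mean series is scanned for the earliest window from which the
#' output is stationary ([stationarity_onset()]). That onset time then
#' anchors the ergodicity test: a single long run is recorded from the
#' onset to `t_long`, thinned, and compared (two-sample
#' Kolmogorov-Smirnov) against the across-replicate sample taken at the
#' onset time. An ergodic variant shows no variation over time beyond
#' replicate stochasticity; rejection signals ongoing adaptation.
#'
#' @param cfg a [sim_config()].
#' @param n_rep replicates for the ensemble stage.
#' @param t_station length of the ensemble stage (stationarity scan).
#' @param t_long length of the single long run (ergodicity stage).
#' @param record_every recording interval.
#' @param window_length window (in recorded steps) for the stationarity
#'   test.
#' @param alpha significance level for both tests.
#' @param master_seed master seed.
#' @return list of class `"diagnostic_result"` with `stationarity`
#'   (`abm_test` at the onset window), `onset_time`, `ergodicity`
#'   (`abm_test`), `ensemble` and `long_run`.
#' @export
run_diagnostics <- function(cfg, n_rep, t_station, t_long, record_every = 10,
                            window_length = 10, alpha = 0.05,
                            master_seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), t_long > t_station)
  ens <- run_ensemble(cfg, n_rep = n_rep, t_end = t_station,
                      record_every = record_every,
                      master_seed = replicate_seed(master_seed, 1))
  mean_n <- colMeans(ens$n_matrix)
  span <- max(4 * window_length, floor(length(mean_n) / 2))
  onset <- stationarity_onset(mean_n, span = span,
                              window_length = window_length, alpha = alpha)
  idx <- if (is.na(onset$start_index)) length(mean_n) %/% 2 + 1
         else onset$start_index
  onset_time <- ens$times[idx]
  stat_test <- stationarity_test(mean_n[idx:length(mean_n)],
                                 window_length = window_length,
                                 alpha = alpha)
  long <- run_abm(cfg, t_end = t_long, record_every = record_every,
                  seed = replicate_seed(master_seed, 2))
  time_sample <- long$n[long$t >= onset_time]
  ens_sample <- ens$n_matrix[, idx]
  erg <- ergodicity_test(time_sample, ens_sample, alpha = alpha)
  out <- list(stationarity = stat_test, onset_time = onset_time,
              onset = onset, ergodicity = erg, ensemble = ens,
              long_run = long)
  class(out) <- "diagnostic_result"
  out
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("<diagnostic_result>\n  stationarity onset at t =", x$onset_time, "\n")
  print(x$stationarity)
  print(x$ergodicity)
  invisible(x)
}
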
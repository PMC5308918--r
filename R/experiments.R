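#' Derive a per-replicate seed from a master seed
#'
#' Counter-based spawning: replicate `i` gets a seed that depends only on
#' `(master_seed, i)`, so adding replicates never perturbs earlier ones.
#' Seeds stay within the positive 32-bit integer range.
#'
#' @param master_seed integer master seed.
#' @param i replicate index (1-based), possibly a vector.
#' @return integer vector of seeds.
#' @export
replicate_seed <- function(master_seed, i) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m) + 1
  # two rounds of a multiplicative congruential mix per counter value
  v <- (s * 48271) %% m
  out <- ((v + as.numeric(i)) * 69621) %% m
  out <- (out * 16807 + 1) %% m
  as.integer(out)
}

#' Run a replicate ensemble
#'
#' Runs `n_rep` independent replicates of the model and collects the
#' population size at each recorded time into a replicate-by-time matrix.
#' Replicate seeds are spawned from `master_seed` via [replicate_seed()], so
#' the whole ensemble is exactly reproducible and extending `n_rep` leaves
#' earlier replicates unchanged.
#'
#' @param cfg a [sim_config()].
#' @param n_rep number of replicate runs (>= 1).
#' @param t_end final time-step of every run.
#' @param record_every recording interval in steps.
#' @param master_seed integer master seed.
#' @return an object of class `"ensemble_result"`: list with `times`
#'   (recorded steps, starting at 0), `n_matrix` (`n_rep` x `length(times)`
#'   integer matrix), `w_harvest` / `w_move` (matrices of population mean
#'   decision parameters, `NA` after extinction), `seeds`, and `config`.
#' @examples
#' ens <- run_ensemble(sim_config(grid_side = 10, n0 = 20), n_rep = 4,
#'                     t_end = 20, record_every = 10, master_seed = 1)
#' dim(ens$n_matrix)
#' @export
run_ensemble <- function(cfg, n_rep, t_end, record_every = 1,
                         master_seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_rep >= 1)
  seeds <- replicate_seed(master_seed, seq_len(n_rep))
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    rows[[i]] <- run_abm(cfg, t_end = t_end, record_every = record_every,
                         seed = seeds[i])
  }
  times <- rows[[1]]$t
  nm <- do.call(rbind, lapply(rows, function(r) r$n))
  wh <- do.call(rbind, lapply(rows, function(r) r$mean_w_harvest))
  wm <- do.call(rbind, lapply(rows, function(r) r$mean_w_move))
  ensemble_result(times, nm, config = cfg, seeds = seeds,
                  w_harvest = wh, w_move = wm)
}

#' Construct an ensemble result
#'
#' Low-level constructor, also used to inject synthetic replicate-by-time
#' matrices (e.g. iid draws standing in for the simulator) into the
#' analysis layer.
#'
#' @param times recorded time-steps.
#' @param n_matrix replicate-by-time matrix of non-negative population
#'   sizes.
#' @param config optional `sim_config` echo.
#' @param seeds optional per-replicate seeds.
#' @param w_harvest,w_move optional matrices of population mean decision
#'   parameters.
#' @return an `"ensemble_result"`.
#' @export
ensemble_result <- function(times, n_matrix, config = NULL, seeds = NULL,
                            w_harvest = NULL, w_move = NULL) {
  n_matrix <- as.matrix(n_matrix)
  stopifnot(length(times) == ncol(n_matrix), all(n_matrix >= 0))
  out <- list(times = as.numeric(times), n_matrix = n_matrix,
              config = config, seeds = seeds, w_harvest = w_harvest,
              w_move = w_move)
  class(out) <- "ensemble_result"
  out
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d replicates x %d recorded times (t %g..%g)\n",
              nrow(x$n_matrix), ncol(x$n_matrix), min(x$times), max(x$times)))
  last <- x$n_matrix[, ncol(x$n_matrix)]
  cat(sprintf("  final n: mean %.2f, extinct %d/%d\n", mean(last),
              sum(last == 0), length(last)))
  invisible(x)
}

#' Normalized histogram over integer population sizes
#'
#' The unit object of all distance measures: a discrete pdf on a strictly
#' increasing support with non-negative weights summing to one.
#'
#' @param support numeric vector of distinct output values (bin width 1
#'   agent).
#' @param weights non-negative weights; normalized to sum to 1 when
#'   `normalize = TRUE` (the default).
#' @param normalize divide weights by their sum.
#' @return an object of class `"binned_pdf"` with fields `support` and
#'   `weights`.
#' @examples
#' p <- binned_pdf(c(1, 2, 3), c(1, 1, 2))
#' sum(p$weights)
#' @export
binned_pdf <- function(support, weights, normalize = TRUE) {
  support <- as.numeric(support)
  weights <- as.numeric(weights)
  stopifnot(length(support) == length(weights), length(support) >= 1)
  o <- order(support)
  support <- support[o]; weights <- weights[o]
  if (any(diff(support) <= 0)) stop("support values must be distinct")
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("weights must have positive total mass")
  if (normalize) weights <- weights / tot
  out <- list(support = support, weights = weights)
  class(out) <- "binned_pdf"
  out
}

#' @export
print.binned_pdf <- function(x, ...) {
  cat(sprintf("<binned_pdf> %d bins on [%g, %g], mean %.3f\n",
              length(x$support), min(x$support), max(x$support),
              sum(x$support * x$weights)))
  invisible(x)
}

check_pdf <- function(p, arg = "pdf") {
  if (!inherits(p, "binned_pdf")) stop(arg, " must be a binned_pdf")
  if (abs(sum(p$weights) - 1) > 1e-12)
    stop(arg, " is not normalized (weights sum to ", sum(p$weights), ")")
  invisible(p)
}

pdf_from_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to histogram")
  tab <- table(values)
  binned_pdf(as.numeric(names(tab)), as.numeric(tab))
}

#' Mean and standard deviation of a binned pdf
#'
#' @param p a [binned_pdf()].
#' @return named numeric vector `c(mean=, sd=)`.
#' @export
pdf_moments <- function(p) {
  check_pdf(p)
  m <- sum(p$support * p$weights)
  v <- sum((p$support - m)^2 * p$weights)
  c(mean = m, sd = sqrt(v))
}

#' Time-dependent histogram of an ensemble
#'
#' The across-replicate distribution of the population size at one recorded
#' time: the histogram that, over many replicates, estimates the output pdf
#' `P(n, t)`.
#'
#' @param ens an [ensemble_result()].
#' @param t a recorded time.
#' @return a [binned_pdf()] with integer support and bin width 1.
#' @export
ensemble_histogram <- function(ens, t) {
  stopifnot(inherits(ens, "ensemble_result"))
  j <- match(t, ens$times)
  if (is.na(j)) stop("time ", t, " was not recorded (available: ",
                     paste(utils::head(ens$times, 10), collapse = ", "),
                     if (length(ens$times) > 10) ", ..." else "", ")")
  pdf_from_values(ens$n_matrix[, j])
}

#' Time-dependent histograms at every recorded time
#'
#' @param ens an [ensemble_result()].
#' @param times subset of recorded times (default: all).
#' @return an object of class `"td_histogram"`: list with `times` and
#'   `pdfs` (one [binned_pdf()] per time).
#' @export
time_dependent_histogram <- function(ens, times = NULL) {
  stopifnot(inherits(ens, "ensemble_result"))
  if (is.null(times)) times <- ens$times
  pdfs <- lapply(times, function(t) ensemble_histogram(ens, t))
  out <- list(times = as.numeric(times), pdfs = pdfs)
  class(out) <- "td_histogram"
  out
}

#' @export
print.td_histogram <- function(x, ...) {
  cat(sprintf("<td_histogram> %d time slices, t in [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Time-averaged histogram of a single run
#'
#' The distribution of the population size over successive recorded steps of
#' one long run, restricted to the window `[t_start, t_end]`. For an ergodic
#' model in its stationary regime this estimates the same pdf as
#' [ensemble_histogram()].
#'
#' @param series a `population_ts` from [run_abm()], or a data frame with
#'   columns `t` and `n`.
#' @param t_start,t_end inclusive window bounds.
#' @return a [binned_pdf()].
#' @export
time_averaged_histogram <- function(series, t_start, t_end) {
  stopifnot(t_start < t_end)
  idx <- series$t >= t_start & series$t <= t_end
  if (!any(idx)) stop("window [", t_start, ", ", t_end,
                      "] contains no recorded steps")
  pdf_from_values(series$n[idx])
}
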
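#' Survival curve of a replicate ensemble
#'
#' Counts, at every recorded time, the replicates whose population is still
#' positive. Because extinction is absorbing in the simulator, the curve is
#' non-increasing.
#'
#' @param ens an [ensemble_result()].
#' @return object of class `"survival_curve"`: data frame with columns `t`
#'   and `n_pos`, plus attribute `n_total`.
#' @export
survival_curve <- function(ens) {
  stopifnot(inherits(ens, "ensemble_result"))
  out <- data.frame(t = ens$times, n_pos = colSums(ens$n_matrix > 0))
  attr(out, "n_total") <- nrow(ens$n_matrix)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Construct a survival curve directly
#'
#' @param times recorded times.
#' @param n_pos replicates with positive population at each time.
#' @param n_total total number of replicates.
#' @return a `"survival_curve"`.
#' @export
make_survival_curve <- function(times, n_pos, n_total) {
  stopifnot(length(times) == length(n_pos), all(n_pos >= 0),
            all(n_pos <= n_total))
  out <- data.frame(t = as.numeric(times), n_pos = as.numeric(n_pos))
  attr(out, "n_total") <- n_total
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Exponential extinction fit
#'
#' Fits the exponential survival model `N_pos(t) = N_pos0 * exp(-lambda*t)`
#' to a survival curve by least squares in count space, with `N_pos0` fixed
#' at the known replicate total and `lambda >= 0` constrained. `lambda` is
#' the extinction rate: large values mean replicates rapidly go extinct and
#' `lambda = 0` means extinction does not occur at all. The fit is done in
#' count space (not log space) because the curve legitimately reaches zero.
#'
#' @param curve a [survival_curve()] (>= 3 time points, non-increasing).
#' @return object of class `"extinction_fit"`: list with `lambda` (per
#'   time-step), `mse` (mean squared residual), `n_total` and `fitted`.
#' @examples
#' cv <- make_survival_curve(seq(0, 1000, 100),
#'                           100 * exp(-0.01 * seq(0, 1000, 100)), 100)
#' fit_extinction(cv)$lambda
#' @export
fit_extinction <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (nrow(curve) < 3) stop("need at least 3 time points to fit")
  if (any(diff(curve$n_pos) > 1e-9))
    stop("survival curve must be non-increasing (extinction is absorbing)")
  n0 <- attr(curve, "n_total")
  t <- curve$t; y <- curve$n_pos
  sse <- function(lam) sum((n0 * exp(-lam * t) - y)^2)
  t_pos <- t[t > 0]
  if (length(t_pos) == 0) stop("need at least one positive time point")
  upper <- 50 / min(t_pos) # exp(-50) is numerically extinct at the 1st step
  opt <- stats::optimize(sse, interval = c(0, upper), tol = 1e-12)
  lambda <- opt$minimum
  if (sse(0) <= opt$objective) lambda <- 0 # flat curve: exact boundary fit
  fitted <- n0 * exp(-lambda * t)
  out <- list(lambda = lambda, mse = mean((fitted - y)^2), n_total = n0,
              fitted = fitted, times = t)
  class(out) <- "extinction_fit"
  out
}

#' @export
print.extinction_fit <- function(x, ...) {
  cat(sprintf("<extinction_fit> lambda = %.6g per step, MSE = %.4g (N0 = %d)\n",
              x$lambda, x$mse, x$n_total))
  invisible(x)
}

#' Harvest-cost sweep
#'
#' For each harvest cost `E_h` and for both the adaptive and the
#' non-adaptive variant, runs a replicate ensemble, builds the survival
#' curve and fits the extinction rate `lambda`. Lowering `E_h` lets agents
#' bank energy faster, drives boom-bust oscillations and eventually
#' destabilises the population, so `lambda` grows as `E_h` falls; adaptation
#' shifts that tipping point to lower `E_h`.
#'
#' @param base a [sim_config()] used as the template (its `adaptive` field
#'   is overridden per variant).
#' @param Eh_values harvest costs to sweep.
#' @param n_rep replicates per (E_h, variant) cell.
#' @param t_end run length of each replicate.
#' @param record_every recording interval.
#' @param master_seed master seed; each cell gets an independent stream.
#' @return data frame of class `"eh_sweep"` with columns `E_h`, `variant`,
#'   `lambda`, `mse`, `n_rep`, `surviving` (replicates alive at `t_end`).
#' @export
sweep_harvest_cost <- function(base, Eh_values, n_rep, t_end,
                               record_every = 100, master_seed = 1) {
  stopifnot(inherits(base, "sim_config"), length(Eh_values) >= 1)
  rows <- list()
  cell <- 0L
  for (variant in c("adaptive", "non-adaptive")) {
    for (eh in Eh_values) {
      cell <- cell + 1L
      cfg <- update_config(base, E_h = eh,
                           adaptive = variant == "adaptive")
      ens <- run_ensemble(cfg, n_rep = n_rep, t_end = t_end,
                          record_every = record_every,
                          master_seed = replicate_seed(master_seed, cell))
      fit <- fit_extinction(survival_curve(ens))
      rows[[cell]] <- data.frame(E_h = eh, variant = variant,
                                 lambda = fit$lambda, mse = fit$mse,
                                 n_rep = n_rep,
                                 surviving = sum(ens$n_matrix[, ncol(ens$n_matrix)] > 0))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eh_sweep", "data.frame")
  out
}

#' Pressure-ramp configuration
#'
#' The protocol for a run under steadily increasing pressure: the run
#' starts from `D = 0.1` with move cost `E_m = 0.1` and all agents pinned
#' at `w_harvest = w_move = 10`; during the run the diffusion coefficient
#' decreases at rate `rho` per step until it reaches `D_min = 0.05`,
#' forcing agents to search more actively for increasingly clumped
#' resource.
#'
#' @param base a [sim_config()] supplying all remaining (nominal)
#'   parameters.
#' @param rho pressure rate (decrease of `D` per step).
#' @param z inheritance deviation parameter (rate of adaptation).
#' @return a `sim_config` implementing the protocol (adaptive variant).
#' @export
pressure_config <- function(base, rho, z) {
  update_config(base, D = 0.1, D_min = 0.05, E_m = 0.1, w_min = 10,
                w_max = 10, rho = rho, z = z, adaptive = TRUE)
}

#' Single pressure-ramp run
#'
#' Runs the simulator under the pressure-ramp protocol (see
#' [pressure_config()]) and reports whether the population survived to
#' `t_end`.
#'
#' @param base nominal [sim_config()].
#' @param rho pressure rate.
#' @param z rate of adaptation.
#' @param t_end run length.
#' @param record_every recording interval.
#' @param seed integer seed.
#' @return list with `series` (a `population_ts`), `survived` (logical),
#'   and `config`.
#' @export
pressure_ramp <- function(base, rho, z, t_end, record_every = 100,
                          seed = 1) {
  cfg <- pressure_config(base, rho, z)
  ts <- run_abm(cfg, t_end = t_end, record_every = record_every, seed = seed)
  list(series = ts, survived = ts$n[nrow(ts)] > 0, config = cfg)
}

#' Adaptation-rate versus pressure phase diagram
#'
#' Classifies every `(z, rho)` cell as SURVIVED or EXTINCT by the majority
#' outcome over `n_rep` pressure-ramp runs. The frontier between the two
#' regions is the critical transition where the pressure increases too fast
#' for adaptation to keep up.
#'
#' @param base nominal [sim_config()].
#' @param z_values rates of adaptation to scan.
#' @param rho_values pressure rates to scan.
#' @param t_end run length per cell.
#' @param n_rep replicates per cell (majority vote; odd values avoid ties,
#'   a tie counts as EXTINCT).
#' @param master_seed master seed.
#' @return object of class `"phase_diagram"`: data frame with columns `z`,
#'   `rho`, `survival_fraction`, `outcome`.
#' @export
phase_diagram <- function(base, z_values, rho_values, t_end, n_rep = 1,
                          master_seed = 1) {
  stopifnot(length(z_values) >= 1, length(rho_values) >= 1, n_rep >= 1)
  rows <- list()
  cell <- 0L
  for (z in z_values) {
    for (rho in rho_values) {
      cell <- cell + 1L
      surv <- logical(n_rep)
      for (r in seq_len(n_rep)) {
        seed <- replicate_seed(replicate_seed(master_seed, cell), r)
        surv[r] <- pressure_ramp(base, rho = rho, z = z, t_end = t_end,
                                 record_every = max(1, t_end),
                                 seed = seed)$survived
      }
      frac <- mean(surv)
      rows[[cell]] <- data.frame(z = z, rho = rho, survival_fraction = frac,
                                 outcome = if (frac > 0.5) "SURVIVED"
                                           else "EXTINCT")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d cells (%d z x %d rho), %d survived\n",
              nrow(x), length(unique(x$z)), length(unique(x$rho)),
              sum(x$outcome == "SURVIVED")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., fit = NULL) {
  n0 <- attr(x, "n_total")
  graphics::plot(x$t, 100 * x$n_pos / n0, type = "s", xlab = "t (days)",
                 ylab = "runs with positive population (%)",
                 ylim = c(0, 100), ...)
  if (!is.null(fit))
    graphics::lines(x$t, 100 * fit$fitted / n0, lty = 2)
  invisible(x)
}

#' @export
plot.distance_curve <- function(x, ...) {
  ycol <- if ("Q" %in% names(x)) "Q" else "Qprime"
  graphics::plot(x$t, x[[ycol]], type = "l", xlab = "t (days)",
                 ylab = if (ycol == "Q") "Q(t) (agents)" else "Q'(t)", ...)
  invisible(x)
}
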
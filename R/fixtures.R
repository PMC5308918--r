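#' Synthetic fixtures for the analysis layer
#'
#' Seed-deterministic generators of the synthetic inputs used to exercise
#' the analysis layer independently of the simulator:
#' \describe{
#'   \item{`histogram_pair`}{two discretized Gaussian-shaped [binned_pdf()]s
#'     with means `separation` apart (equal standard deviation `sd`),
#'     sampled with `size` draws each, or exact (`size = Inf`).}
#'   \item{`iid_series`}{iid `Normal(mean, sd)` series of length `size`.}
#'   \item{`ar1_series`}{AR(1) series `x_t = phi x_{t-1} + e_t` with unit
#'     innovation variance, length `size`.}
#'   \item{`survival_curve`}{an ensemble of `n_rep` replicates that each go
#'     extinct with per-step hazard `hazard`, recorded every
#'     `record_every` of `size` steps; the implied extinction rate is
#'     `-log(1 - hazard)` per step.}
#' }
#'
#' @param kind one of `"histogram_pair"`, `"iid_series"`, `"ar1_series"`,
#'   `"survival_curve"`.
#' @param seed integer seed.
#' @param size main size parameter (see above).
#' @param separation,sd,center histogram-pair shape parameters.
#' @param mean series mean (`iid_series`).
#' @param phi AR(1) coefficient.
#' @param hazard per-step extinction probability of one replicate.
#' @param n_rep replicates (`survival_curve`).
#' @param record_every recording interval (`survival_curve`).
#' @return kind-dependent: a list of two `binned_pdf`s, a numeric vector, or
#'   a [make_survival_curve()] object with attribute `lambda_true`.
#' @examples
#' fx <- make_fixture("histogram_pair", separation = 10, size = 500, seed = 1)
#' emd(fx$p_a, fx$p_b)
#' @export
make_fixture <- function(kind = c("histogram_pair", "iid_series",
                                  "ar1_series", "survival_curve"),
                         seed = 1, size = 1000, separation = 0, sd = 3,
                         center = 25, mean = 0, phi = 0.9, hazard = 0.01,
                         n_rep = 100, record_every = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    histogram_pair = {
      mk <- function(mu) {
        if (is.infinite(size)) {
          lo <- floor(mu - 6 * sd); hi <- ceiling(mu + 6 * sd)
          s <- lo:hi
          w <- stats::dnorm(s, mu, sd)
          binned_pdf(s, w)
        } else {
          pdf_from_values(round(stats::rnorm(size, mu, sd)))
        }
      }
      list(p_a = mk(center), p_b = mk(center + separation),
           separation = separation)
    },
    iid_series = mean + stats::rnorm(size, 0, sd),
    ar1_series = as.numeric(stats::arima.sim(list(ar = phi), n = size)),
    survival_curve = {
      stopifnot(hazard >= 0, hazard < 1)
      ext <- if (hazard > 0) stats::rgeom(n_rep, hazard) + 1 else
        rep(Inf, n_rep)
      times <- seq(0, size, by = record_every)
      n_pos <- vapply(times, function(t) sum(ext > t), numeric(1))
      cv <- make_survival_curve(times, n_pos, n_rep)
      attr(cv, "lambda_true") <- -log(1 - hazard)
      cv
    })
}

#' Write a fixture to disk
#'
#' Serializes a [make_fixture()] result as plain-text CSV next to a JSON
#' sidecar echoing the generation parameters.
#'
#' @param kind,seed,... passed to [make_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(kind, dir, seed = 1, ...) {
  fx <- make_fixture(kind, seed = seed, ...)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0("fixture_", kind))
  paths <- character(0)
  if (kind == "histogram_pair") {
    for (side in c("p_a", "p_b")) {
      p <- file.path(dir, paste0("fixture_", kind, "_", side, ".csv"))
      utils::write.csv(data.frame(n = fx[[side]]$support,
                                  weight = fx[[side]]$weights),
                       p, row.names = FALSE)
      paths <- c(paths, p)
    }
  } else if (kind == "survival_curve") {
    p <- paste0(base, ".csv")
    utils::write.csv(as.data.frame(fx), p, row.names = FALSE)
    paths <- p
  } else {
    p <- paste0(base, ".csv")
    utils::write.csv(data.frame(index = seq_along(fx), value = fx), p,
                     row.names = FALSE)
    paths <- p
  }
  meta <- paste0(base, ".json")
  jsonlite::write_json(c(list(kind = kind, seed = seed), list(...)), meta,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
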
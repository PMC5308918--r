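#' Write simulation output as tidy CSV
#'
#' One row per recorded step; when `replicate_id` is given it is added as a
#' column so single runs can be concatenated into long-format ensemble
#' files.
#'
#' @param series a `population_ts` from [run_abm()].
#' @param path output file.
#' @param replicate_id optional replicate label.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(series, path, replicate_id = NULL) {
  df <- as.data.frame(series)
  if (!is.null(replicate_id)) df$replicate_id <- replicate_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble as wide and long CSV
#'
#' @param ens an [ensemble_result()].
#' @param path_wide replicate-by-time matrix CSV (rows = replicates).
#' @param path_long optional long-format CSV with columns `replicate_id`,
#'   `t`, `n`.
#' @return invisibly, the paths written.
#' @export
write_ensemble_csv <- function(ens, path_wide, path_long = NULL) {
  stopifnot(inherits(ens, "ensemble_result"))
  wide <- as.data.frame(ens$n_matrix)
  names(wide) <- paste0("t", ens$times)
  wide <- cbind(replicate_id = seq_len(nrow(wide)), wide)
  utils::write.csv(wide, path_wide, row.names = FALSE)
  paths <- path_wide
  if (!is.null(path_long)) {
    long <- data.frame(
      replicate_id = rep(seq_len(nrow(ens$n_matrix)), times = ncol(ens$n_matrix)),
      t = rep(ens$times, each = nrow(ens$n_matrix)),
      n = as.vector(ens$n_matrix))
    utils::write.csv(long, path_long, row.names = FALSE)
    paths <- c(paths, path_long)
  }
  invisible(paths)
}

#' Write a histogram as two-column CSV
#'
#' @param p a [binned_pdf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(p, path) {
  check_pdf(p)
  utils::write.csv(data.frame(n = p$support, weight = p$weights), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a histogram written by [write_histogram_csv()]
#'
#' @param path CSV with columns `n` and `weight`.
#' @return a [binned_pdf()].
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  binned_pdf(df$n, df$weight)
}

#' Write adaptation curves as CSV
#'
#' Joins `Q(t)` and `Q'(t)` on the recording grid (`Qprime` is `NA` at the
#' first time).
#'
#' @param q a `distance_curve` from [adaptation_effect()].
#' @param qprime optional matching [adaptation_rate()] curve.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(q, path, qprime = NULL) {
  df <- data.frame(t = q$t, Q = q$Q)
  if (!is.null(qprime))
    df$Qprime <- qprime$Qprime[match(df$t, qprime$t)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transport plan as sparse triplet CSV
#'
#' @param plan a [transport_plan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "transport_plan"))
  utils::write.csv(as.data.frame(plan)[, c("from", "to", "flow")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a JSON run-metadata sidecar
#'
#' Records everything needed to replay a run or ensemble: the full
#' configuration, the master seed, per-replicate seeds and the package
#' version.
#'
#' @param path output file (conventionally `<output>.meta.json`).
#' @param cfg the [sim_config()] used.
#' @param master_seed master seed.
#' @param seeds optional per-replicate seeds.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_metadata_json <- function(path, cfg, master_seed = NULL, seeds = NULL,
                                extra = NULL) {
  meta <- list(package = "cpresim",
               version = as.character(utils::packageVersion("cpresim")),
               config = unclass(cfg), master_seed = master_seed,
               replicate_seeds = seeds)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Serialize a test result as a JSON record
#'
#' @param x an `abm_test`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_test_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "abm_test"))
  rec <- list(method = x$method, statistic = x$statistic,
              p_value = x$p_value, alpha = x$alpha, reject = x$reject)
  if (is.null(path))
    return(invisible(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
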
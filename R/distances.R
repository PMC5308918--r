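#' Align two binned pdfs on the union of their supports
#'
#' Zero-pads both weight vectors onto the sorted union support so that
#' bin-wise measures are well defined.
#'
#' @param p_a,p_b [binned_pdf()] objects.
#' @return list with `support`, `wa`, `wb`.
#' @keywords internal
align_pdfs <- function(p_a, p_b) {
  check_pdf(p_a, "p_a"); check_pdf(p_b, "p_b")
  support <- sort(unique(c(p_a$support, p_b$support)))
  wa <- numeric(length(support)); wb <- numeric(length(support))
  wa[match(p_a$support, support)] <- p_a$weights
  wb[match(p_b$support, support)] <- p_b$weights
  list(support = support, wa = wa, wb = wb)
}

#' Earth-mover's distance between two binned pdfs
#'
#' The minimal work needed to transform one pdf into the other, with ground
#' distance `d(j, k) = |j - k|` in agents (bin width 1). For distributions
#' of a single output variable the minimisation over all transport plans
#' reduces to a single sweep through consecutive support values, keeping
#' track of the cumulative mass that still has to be carried across each
#' gap:
#' `d_e = sum_i |cumsum(P_a - P_b)_i| * (s_{i+1} - s_i)`.
#'
#' Unlike overlap-based measures, the earth-mover's distance keeps growing
#' as two non-overlapping pdfs move apart, which is what makes it suitable
#' for quantifying adaptation effects once the adaptive and non-adaptive
#' output distributions have separated.
#'
#' @param p_a,p_b [binned_pdf()] objects (normalized).
#' @return non-negative scalar distance (in agents).
#' @examples
#' emd(binned_pdf(3, 1), binned_pdf(7, 1)) # all mass moved 4 agents
#' @export
emd <- function(p_a, p_b) {
  al <- align_pdfs(p_a, p_b)
  m <- length(al$support)
  if (m == 1) return(0)
  cum <- cumsum(al$wa - al$wb)
  sum(abs(cum[-m]) * diff(al$support))
}

#' Euclidean distance between two binned pdfs
#'
#' `sqrt(sum_j (P_a(j) - P_b(j))^2)` on the zero-padded union support. Like
#' the Jensen-Shannon divergence this saturates once the two pdfs no longer
#' overlap (at `sqrt(2)` for two disjoint point masses).
#'
#' @inheritParams emd
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(p_a, p_b) {
  al <- align_pdfs(p_a, p_b)
  sqrt(sum((al$wa - al$wb)^2))
}

#' Jensen-Shannon divergence between two binned pdfs
#'
#' `0.5 * sum_j [ P_a ln(2 P_a / (P_a + P_b)) + P_b ln(2 P_b / (P_a + P_b)) ]`
#' with the convention `0 ln 0 = 0`. Uses the natural logarithm, so the
#' value lies in `[0, ln 2]`, the maximum being attained for pdfs with
#' disjoint supports.
#'
#' @inheritParams emd
#' @return scalar in `[0, ln(2)]`; symmetric in its arguments.
#' @export
js_divergence <- function(p_a, p_b) {
  al <- align_pdfs(p_a, p_b)
  s <- al$wa + al$wb
  term <- function(w) {
    out <- numeric(length(w))
    pos <- w > 0
    out[pos] <- w[pos] * log(2 * w[pos] / s[pos])
    out
  }
  val <- 0.5 * sum(term(al$wa) + term(al$wb))
  min(max(val, 0), log(2))
}

#' Optimal transport plan between two binned pdfs
#'
#' An explicit flow matrix `g(j, k) >= 0` realizing the earth-mover's
#' distance: row sums reproduce `P_a`, column sums reproduce `P_b`, and the
#' total cost `sum g(j, k) |j - k|` equals [emd()]. For a one-dimensional
#' convex ground cost the monotone (north-west corner) coupling is optimal,
#' so the plan is built by greedily matching mass in support order.
#'
#' @inheritParams emd
#' @return an object of class `"transport_plan"`: data frame with columns
#'   `from`, `to`, `flow`, `dist`, plus attributes `support_a`, `support_b`
#'   and `cost`.
#' @export
transport_plan <- function(p_a, p_b) {
  check_pdf(p_a, "p_a"); check_pdf(p_b, "p_b")
  sa <- p_a$support; wa <- p_a$weights
  sb <- p_b$support; wb <- p_b$weights
  na <- length(sa); nb <- length(sb)
  i <- 1L; j <- 1L
  from <- numeric(0); to <- numeric(0); flow <- numeric(0)
  ra <- wa[1]; rb <- wb[1]
  tol <- 1e-15
  while (i <= na && j <= nb) {
    f <- min(ra, rb)
    if (f > 0) {
      from <- c(from, sa[i]); to <- c(to, sb[j]); flow <- c(flow, f)
    }
    ra <- ra - f; rb <- rb - f
    if (ra <= tol) { i <- i + 1L; if (i <= na) ra <- wa[i] }
    if (rb <= tol) { j <- j + 1L; if (j <= nb) rb <- wb[j] }
  }
  plan <- data.frame(from = from, to = to, flow = flow,
                     dist = abs(from - to))
  attr(plan, "support_a") <- sa
  attr(plan, "support_b") <- sb
  attr(plan, "cost") <- sum(plan$flow * plan$dist)
  class(plan) <- c("transport_plan", "data.frame")
  plan
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("<transport_plan> %d flows, cost %.6g\n", nrow(x),
              attr(x, "cost")))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Adaptation-effect curve Q(t)
#'
#' The earth-mover's distance between the time-dependent output pdfs of the
#' adaptive and the non-adaptive model, slice by slice:
#' `Q(t) = d_e(P_a(n, t), P_b(n, t))`. A growing `Q` means the two model
#' variants' output distributions keep drifting apart, i.e. adaptation has
#' a lasting effect on the output.
#'
#' @param h_a,h_b [time_dependent_histogram()] objects on identical time
#'   grids (conventionally `h_a` the adaptive, `h_b` the non-adaptive
#'   variant).
#' @param measure distance to apply per slice: `"emd"` (default),
#'   `"euclidean"` or `"js"`.
#' @return an object of class `"distance_curve"`: data frame with columns
#'   `t` and `Q`.
#' @export
adaptation_effect <- function(h_a, h_b, measure = c("emd", "euclidean", "js")) {
  stopifnot(inherits(h_a, "td_histogram"), inherits(h_b, "td_histogram"))
  measure <- match.arg(measure)
  if (length(h_a$times) != length(h_b$times) ||
      any(h_a$times != h_b$times))
    stop("time grids of the two histogram sets do not match")
  fn <- switch(measure, emd = emd, euclidean = euclidean_distance,
               js = js_divergence)
  q <- vapply(seq_along(h_a$times),
              function(i) fn(h_a$pdfs[[i]], h_b$pdfs[[i]]), numeric(1))
  out <- data.frame(t = h_a$times, Q = q)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Adaptation-rate curve Q'(t)
#'
#' First differences of the adaptation-effect curve on its (uniform)
#' recording grid: `Q'(t) = Q(t) - Q(t - dt)`. Summing `Q'` over the grid
#' telescopes back to `Q(t_end) - Q(t_first)` exactly.
#'
#' @param curve a `distance_curve` from [adaptation_effect()].
#' @return data frame of class `"distance_curve"` with columns `t` (the
#'   right end of each interval) and `Qprime`.
#' @export
adaptation_rate <- function(curve) {
  stopifnot(inherits(curve, "distance_curve"), nrow(curve) >= 2)
  dt <- diff(curve$t)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1))
    stop("recording grid is not uniform; Q' is defined on a uniform grid")
  out <- data.frame(t = curve$t[-1], Qprime = diff(curve$Q))
  class(out) <- c("distance_curve", "data.frame")
  out
}
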
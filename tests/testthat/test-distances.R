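test_that("earth-mover's distance on point masses and identical pdfs", {
  p3 <- binned_pdf(3, 1)
  p7 <- binned_pdf(7, 1)
  expect_equal(emd(p3, p3), 0)
  expect_equal(emd(p3, p7), 4)
  set.seed(1)
  p <- random_pdf()
  expect_equal(emd(p, p), 0)
})

test_that("sweep EMD equals the sorted-sample coupling on empirical data", {
  # independent oracle: for equal-size samples the 1-D optimal transport
  # cost is the mean absolute difference of the order statistics
  set.seed(2)
  for (i in 1:40) {
    a <- sample(0:30, 500, replace = TRUE, prob = runif(31))
    b <- sample(0:30, 500, replace = TRUE, prob = runif(31))
    oracle <- mean(abs(sort(a) - sort(b)))
    ta <- table(a); tb <- table(b)
    val <- emd(binned_pdf(as.numeric(names(ta)), as.numeric(ta)),
               binned_pdf(as.numeric(names(tb)), as.numeric(tb)))
    expect_lt(abs(val - oracle), 1e-9)
  }
})

test_that("emd behaves as a metric on random instances", {
  set.seed(3)
  for (i in 1:50) {
    p <- random_pdf(); q <- random_pdf(); r <- random_pdf()
    expect_lt(abs(emd(p, q) - emd(q, p)), 1e-9)
    expect_lte(emd(p, r), emd(p, q) + emd(q, r) + 1e-9)
    expect_gte(emd(p, q), 0)
  }
})

test_that("euclidean distance matches brute-force summation", {
  p <- binned_pdf(1, 1); q <- binned_pdf(9, 1)
  expect_equal(euclidean_distance(p, p), 0)
  expect_equal(euclidean_distance(p, q), sqrt(2))
  set.seed(4)
  for (i in 1:20) {
    a <- random_pdf(); b <- random_pdf()
    sup <- sort(unique(c(a$support, b$support)))
    wa <- wb <- numeric(length(sup))
    wa[match(a$support, sup)] <- a$weights
    wb[match(b$support, sup)] <- b$weights
    brute <- sqrt(sum((wa - wb)^2))
    expect_lt(abs(euclidean_distance(a, b) - brute), 1e-12)
  }
})

test_that("Jensen-Shannon divergence is symmetric and bounded by ln 2", {
  p <- binned_pdf(1, 1); q <- binned_pdf(9, 1)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(p, q), log(2))
  set.seed(5)
  for (i in 1:30) {
    a <- random_pdf(); b <- random_pdf()
    d1 <- js_divergence(a, b)
    expect_lt(abs(d1 - js_divergence(b, a)), 1e-12)
    expect_gte(d1, 0)
    expect_lte(d1, log(2))
  }
})

test_that("transport plans satisfy the marginal constraints at the sweep cost", {
  p3 <- binned_pdf(3, 1); p7 <- binned_pdf(7, 1)
  plan <- transport_plan(p3, p7)
  expect_equal(nrow(plan), 1)
  expect_equal(plan$flow, 1)
  expect_equal(attr(plan, "cost"), 4)

  p <- binned_pdf(1:3, c(1, 1, 2))
  self <- transport_plan(p, p)
  expect_true(all(self$from == self$to))
  expect_equal(attr(self, "cost"), 0)

  set.seed(6)
  for (i in 1:30) {
    a <- random_pdf(); b <- random_pdf()
    pl <- transport_plan(a, b)
    expect_true(all(pl$flow >= 0))
    rows <- tapply(pl$flow, pl$from, sum)
    cols <- tapply(pl$flow, pl$to, sum)
    expect_lt(max(abs(rows[as.character(a$support)] - a$weights)), 1e-10)
    expect_lt(max(abs(cols[as.character(b$support)] - b$weights)), 1e-10)
    expect_lt(abs(attr(pl, "cost") - emd(a, b)), 1e-10)
  }
})

test_that("distance measures separate regimes as pdfs stop overlapping", {
  # two equal-variance Gaussian-shaped histograms, growing mean separation:
  # emd grows like the separation while JS and Euclidean saturate
  seps <- c(0, 2, 5, 10, 20, 30, 40)
  vals <- t(sapply(seps, function(s) {
    fx <- gaussian_pair(s)
    c(emd = emd(fx$p_a, fx$p_b), eu = euclidean_distance(fx$p_a, fx$p_b),
      js = js_divergence(fx$p_a, fx$p_b))
  }))
  expect_true(all(diff(vals[, "emd"]) > 0))
  expect_equal(vals[seps >= 20, "emd"], seps[seps >= 20],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(abs(vals[nrow(vals), "js"] - log(2)), 1e-6)
  expect_lt(vals[nrow(vals), "eu"] - vals[nrow(vals) - 1, "eu"], 1e-6)
})

test_that("adaptation-effect curves track paired slices exactly", {
  # slices are point masses at c and c + v t: Q(t) = v t
  times <- seq(0, 50, 10)
  v <- 0.8; cc <- 30
  h_b <- list(times = times,
              pdfs = lapply(times, function(t) binned_pdf(cc, 1)))
  h_a <- list(times = times,
              pdfs = lapply(times, function(t) binned_pdf(cc + v * t, 1)))
  class(h_a) <- class(h_b) <- "td_histogram"
  q <- adaptation_effect(h_a, h_b)
  expect_equal(q$Q, v * times)

  same <- adaptation_effect(h_a, h_a)
  expect_true(all(same$Q == 0))

  qp <- adaptation_rate(q)
  expect_equal(qp$Qprime, rep(v * 10, length(times) - 1))
  # telescoping: cumulative Q' reconstructs Q exactly
  expect_equal(q$Q[1] + cumsum(qp$Qprime), q$Q[-1])

  h_bad <- h_a; h_bad$times <- times + 1
  expect_error(adaptation_effect(h_bad, h_b), "time grids")
  q_bad <- q[c(1, 2, 4), ]
  class(q_bad) <- c("distance_curve", "data.frame")
  expect_error(adaptation_rate(q_bad), "uniform")
})

test_that("unnormalized inputs are rejected by the distance layer", {
  p <- binned_pdf(1:3, c(1, 1, 1))
  broken <- p
  broken$weights <- broken$weights * 2
  expect_error(emd(broken, p), "not normalized")
  expect_error(js_divergence(p, broken), "not normalized")
})
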
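test_that("ensembles are reproducible with pairwise-distinct replicate seeds", {
  cfg <- tiny_config()
  ens <- run_ensemble(cfg, n_rep = 10, t_end = 100, record_every = 100,
                      master_seed = 1)
  expect_equal(dim(ens$n_matrix), c(10, 2))
  expect_equal(ens$times, c(0, 100))
  expect_true(all(ens$n_matrix >= 0))
  expect_equal(anyDuplicated(ens$seeds), 0)

  again <- run_ensemble(cfg, n_rep = 10, t_end = 100, record_every = 100,
                        master_seed = 1)
  expect_identical(ens$n_matrix, again$n_matrix)

  other <- run_ensemble(cfg, n_rep = 10, t_end = 100, record_every = 100,
                        master_seed = 2)
  expect_false(identical(ens$n_matrix, other$n_matrix))
})

test_that("extending an ensemble never perturbs earlier replicates", {
  cfg <- tiny_config()
  small <- run_ensemble(cfg, n_rep = 4, t_end = 50, record_every = 25,
                        master_seed = 3)
  big <- run_ensemble(cfg, n_rep = 8, t_end = 50, record_every = 25,
                      master_seed = 3)
  expect_identical(big$n_matrix[1:4, ], small$n_matrix)
})

test_that("binned pdfs are normalized with strictly increasing support", {
  p <- binned_pdf(c(3, 1, 2), c(2, 1, 1))
  expect_equal(p$support, c(1, 2, 3))
  expect_equal(sum(p$weights), 1)
  expect_error(binned_pdf(c(1, 1), c(1, 1)), "distinct")
  expect_error(binned_pdf(1:2, c(-1, 2)), "non-negative")
  expect_error(binned_pdf(1:2, c(0, 0)), "positive total")
  m <- pdf_moments(binned_pdf(c(0, 10), c(0.5, 0.5)))
  expect_equal(unname(m), c(5, 5))
})

test_that("ensemble histograms tally replicates exactly", {
  ens <- ensemble_result(times = c(0, 10), n_matrix = rbind(
    c(4, 5), c(4, 5), c(4, 5), c(4, 7)))
  h <- ensemble_histogram(ens, 10)
  expect_equal(h$support, c(5, 7))
  expect_equal(h$weights, c(0.75, 0.25))
  # integer tallies are recovered exactly
  expect_equal(h$weights * 4, c(3, 1))

  point <- ensemble_histogram(ens, 0)
  expect_equal(point$support, 4)
  expect_equal(point$weights, 1)

  expect_error(ensemble_histogram(ens, 99), "not recorded")
})

test_that("time-averaged histograms honour their window", {
  series <- data.frame(t = seq(0, 90, 10),
                       n = c(42, 42, 42, 42, 1, 2, 2, 3, 3, 3))
  const <- time_averaged_histogram(series[1:4, ], 0, 30)
  expect_equal(const$support, 42)
  expect_equal(const$weights, 1)

  one <- time_averaged_histogram(series, 38, 42)
  expect_equal(one$support, 1)

  # a union of two disjoint windows is the sample-size-weighted mixture
  h1 <- time_averaged_histogram(series, 0, 30)   # 4 steps
  h2 <- time_averaged_histogram(series, 40, 90)  # 6 steps
  hu <- time_averaged_histogram(series, 0, 90)   # all 10
  al1 <- hu$support
  mix <- sapply(al1, function(s) {
    0.4 * ifelse(s %in% h1$support, h1$weights[match(s, h1$support)], 0) +
    0.6 * ifelse(s %in% h2$support, h2$weights[match(s, h2$support)], 0)
  })
  expect_equal(hu$weights, unname(mix))

  expect_error(time_averaged_histogram(series, 91, 99), "no recorded steps")
})

test_that("histogram slices of a stationary synthetic process agree across times", {
  set.seed(101)
  # iid draws injected in place of the simulator
  m <- matrix(rpois(1000 * 2, lambda = 90), ncol = 2)
  ens <- ensemble_result(times = c(100, 200), n_matrix = m)
  h1 <- ensemble_histogram(ens, 100)
  h2 <- ensemble_histogram(ens, 200)
  expect_equal(sum(h1$weights), 1)
  expect_equal(sum(h2$weights), 1)
  ks <- suppressWarnings(stats::ks.test(m[, 1], m[, 2]))
  expect_gt(ks$p.value, 0.01)
})
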
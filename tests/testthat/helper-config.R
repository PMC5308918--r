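# Small configurations keep unit tests fast; the full 50x50 default grid is
# exercised only by the acceptance suite.
tiny_config <- function(...) {
  update_config(sim_config(grid_side = 8, n0 = 10), ...)
}

# A state with every agent at a prescribed energy, for closed-form
# demography checks.
state_with_energy <- function(cfg, n, energy, seed = 1) {
  st <- init_state(update_config(cfg, n0 = n), seed = seed)
  st$agents$energy <- rep(energy, n)
  st
}

# Discretized Gaussian pdf pair with exact (deterministic) weights.
gaussian_pair <- function(separation, sd = 3, center = 60) {
  make_fixture("histogram_pair", separation = separation, sd = sd,
               center = center, size = Inf)
}

random_pdf <- function(support = 0:30) {
  w <- stats::runif(length(support))
  keep <- w > 0.3
  if (!any(keep)) keep[1] <- TRUE
  binned_pdf(support[keep], w[keep])
}
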
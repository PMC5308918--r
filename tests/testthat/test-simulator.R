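test_that("initialization fills the grid and draws agents as specified", {
  cfg <- update_config(sim_config(grid_side = 10), n0 = 50)
  st <- init_state(cfg, seed = 1)
  expect_equal(nrow(st$agents), 50)
  expect_true(all(st$resource == cfg$K_cap))
  expect_true(all(st$agents$energy == cfg$e_init))
  expect_true(all(st$agents$x >= 0 & st$agents$x < 10))
  expect_true(all(st$agents$y >= 0 & st$agents$y < 10))
  expect_true(all(st$agents$w_harvest >= cfg$w_min &
                    st$agents$w_harvest <= cfg$w_max))

  pinned <- init_state(update_config(cfg, w_min = 10, w_max = 10), seed = 2)
  expect_true(all(pinned$agents$w_harvest == 10))
  expect_true(all(pinned$agents$w_move == 10))

  a <- init_state(cfg, seed = 99)
  b <- init_state(cfg, seed = 99)
  expect_identical(a, b)
})

test_that("resource update follows logistic growth then explicit diffusion", {
  cfg <- tiny_config()
  # uniform field at carrying capacity is a fixed point
  full <- matrix(cfg$K_cap, 8, 8)
  expect_equal(step_resource(full, cfg), full)

  # hand-evaluated single-point diffusion: r = 0, D = 0.1
  cfg0 <- update_config(cfg, r_growth = 0, D = 0.1)
  R <- matrix(0, 8, 8)
  R[4, 4] <- 1
  out <- step_resource(R, cfg0)
  expect_equal(out[4, 4], 0.6)
  expect_equal(out[3, 4], 0.1)
  expect_equal(out[5, 4], 0.1)
  expect_equal(out[4, 3], 0.1)
  expect_equal(out[4, 5], 0.1)
  expect_equal(sum(out), 1)

  # diffusion is conservative on a torus when growth is off
  set.seed(7)
  R <- matrix(runif(64), 8, 8)
  out <- step_resource(R, cfg0)
  for (i in 1:20) out <- step_resource(out, cfg0)
  expect_lt(abs(sum(out) - sum(R)), 1e-9 * sum(R))

  # growth pushes an empty-but-seeded field toward K and clips inside [0, K]
  st <- init_state(cfg, seed = 1)
  st$resource[] <- 0.5
  st2 <- step_resource(st, cfg)
  expect_s3_class(st2, "abm_state")
  expect_true(all(st2$resource >= 0 & st2$resource <= cfg$K_cap))
  expect_true(all(st2$resource > 0.5))
})

test_that("decision rule matches its closed form", {
  cfg <- tiny_config()
  st <- init_state(cfg, seed = 3)
  obs <- observe(st, 1, cfg)

  # w_harvest = 0 forces harvesting
  ag0 <- list(energy = obs$energy, w_harvest = 0, w_move = 5)
  set.seed(1)
  acts <- replicate(200, decide(ag0, obs, cfg)$action)
  expect_true(all(acts == "HARVEST"))

  # very large parameters force idleness (scores are positive here)
  sc <- satisfaction_scores(obs, cfg)
  expect_true(all(sc > 0 & sc < 1))
  agL <- list(energy = obs$energy, w_harvest = 500, w_move = 500)
  set.seed(2)
  acts <- replicate(200, decide(agL, obs, cfg)$action)
  expect_true(mean(acts == "IDLE") > 0.99)

  # Monte-Carlo frequency of harvesting equals exp(-w_harvest * A_h)
  ag <- list(energy = obs$energy, w_harvest = 4, w_move = 2)
  p_h <- exp(-ag$w_harvest * sc[["A_h"]])
  set.seed(4)
  n_draws <- 1e5
  acts <- vapply(seq_len(n_draws),
                 function(i) decide(ag, obs, cfg)$action, character(1))
  phat <- mean(acts == "HARVEST")
  expect_lt(abs(phat - p_h), 3 * sqrt(p_h * (1 - p_h) / n_draws))

  # conditional on not harvesting, moving has probability exp(-w_move * A_m)
  p_m <- exp(-ag$w_move * sc[["A_m"]])
  phat_m <- mean(acts == "MOVE") / (1 - phat)
  expect_lt(abs(phat_m - p_m), 4 * sqrt(p_m * (1 - p_m) / (n_draws * (1 - p_h))))
})

test_that("moves target the most resource-rich neighbour", {
  cfg <- tiny_config()
  st <- init_state(update_config(cfg, n0 = 1), seed = 5)
  x <- st$agents$x[1]; y <- st$agents$y[1]
  st$resource[] <- 0.2
  # east neighbour (x+1, same y) is the richest
  st$resource[(x + 1) %% 8 + 1, y + 1] <- 0.9
  obs <- observe(st, 1, cfg)
  ag <- list(energy = obs$energy, w_harvest = 500, w_move = 0)
  set.seed(6)
  for (i in 1:20) {
    d <- decide(ag, obs, cfg)
    expect_equal(d$action, "MOVE")
    expect_equal(d$direction, "E")
  }
})

test_that("action bookkeeping transfers energy and resource exactly", {
  cfg <- update_config(tiny_config(), harvest_fraction = 0.5,
                       energy_yield = 1, E_h = 0.05, E_m = 0.12, E_b = 0.02,
                       e_max = 10)
  st <- init_state(update_config(cfg, n0 = 1), seed = 7)
  st$agents$energy <- 4
  x <- st$agents$x[1]; y <- st$agents$y[1]
  st$resource[x + 1, y + 1] <- 1

  idle <- apply_action(st, 1, "IDLE", cfg)
  expect_equal(idle$agents$energy, 4 - 0.02)

  h <- apply_action(st, 1, "HARVEST", cfg)
  expect_equal(h$resource[x + 1, y + 1], 0.5)
  expect_equal(h$agents$energy, 4 + 0.5 - 0.05 - 0.02)

  # energy is clipped at e_max and at zero
  st$agents$energy <- 9.9
  h2 <- apply_action(st, 1, "HARVEST",
                     update_config(cfg, energy_yield = 10))
  expect_equal(h2$agents$energy, cfg$e_max)
  st$agents$energy <- 0.01
  m0 <- apply_action(st, 1, "MOVE", cfg, direction = "N")
  expect_equal(m0$agents$energy, 0)
})

test_that("moving east at the boundary wraps on a torus", {
  cfg <- tiny_config()
  st <- init_state(update_config(cfg, n0 = 1), seed = 8)
  st$agents$x <- 7L; st$agents$y <- 3L
  mv <- apply_action(st, 1, "MOVE", cfg, direction = "E")
  expect_equal(mv$agents$x, 0L)
  expect_equal(mv$agents$y, 3L)
})

test_that("death risk matches exp(-energy/death_scale) and zero energy is fatal", {
  cfg <- update_config(sim_config(grid_side = 30), rep_prob_max = 0)
  st <- state_with_energy(cfg, 5000, 0)
  set.seed(9)
  expect_equal(nrow(demography(st, cfg)$agents), 0)

  for (e in c(1, 3)) {
    st <- state_with_energy(cfg, 10000, e)
    set.seed(e)
    surv <- nrow(demography(st, cfg)$agents)
    p <- exp(-e / cfg$death_scale)
    expect_lt(abs((1 - surv / 10000) - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("reproduction splits energy and respects rep_prob_max = 0", {
  cfg <- update_config(sim_config(grid_side = 30), rep_prob_max = 0)
  st <- state_with_energy(cfg, 500, cfg$e_max)
  set.seed(10)
  out <- demography(st, cfg)
  expect_lte(nrow(out$agents), 500)

  cfg2 <- update_config(cfg, rep_prob_max = 1, rep_threshold = 1,
                        death_scale = 1e-6)
  # death_scale tiny => p_death ~ 0 at high energy; births near-certain
  st <- state_with_energy(cfg2, 200, 8)
  set.seed(11)
  out <- demography(st, cfg2)
  born <- nrow(out$agents) - 200
  expect_gt(born, 150)
  kids <- utils::tail(out$agents, born)
  expect_true(all(kids$energy == 4))
  # parents' energy halved, offspring placed on the parent's site
  expect_true(all(out$agents$energy[seq_len(200)] %in% c(4, 8)))
})

test_that("offspring parameters are inherited with mutation or redrawn", {
  cfg <- tiny_config()
  parent <- list(w_harvest = 9, w_move = 11)

  # adaptive, z = 0: exact copy
  set.seed(12)
  w <- inherit_w(parent, update_config(cfg, adaptive = TRUE, z = 0))
  expect_equal(unname(w), c(9, 11))

  # adaptive: deviation scale is mutation_scale * z
  draw <- function(z, n = 10000) {
    c2 <- update_config(cfg, adaptive = TRUE, z = z, w_min = 0, w_max = 20)
    vapply(seq_len(n), function(i) inherit_w(parent, c2)[["w_harvest"]],
           numeric(1))
  }
  set.seed(13)
  s1 <- sd(draw(1) - 9)
  s5 <- sd(draw(5) - 9)
  expect_lt(abs(s1 - 0.1), 0.01)
  expect_lt(abs(s5 / s1 - 5), 0.5)

  # non-adaptive: redrawn from the initial uniform, parent ignored
  c3 <- update_config(cfg, adaptive = FALSE, w_min = 2, w_max = 6)
  set.seed(14)
  ws <- vapply(seq_len(10000),
               function(i) inherit_w(list(w_harvest = 100, w_move = 100),
                                     c3)[["w_harvest"]], numeric(1))
  expect_true(all(ws >= 2 & ws <= 6))
  ks <- suppressWarnings(stats::ks.test(ws, "punif", 2, 6))
  expect_gt(ks$p.value, 0.001)
})

test_that("full steps are deterministic under a seed and absorb extinction", {
  cfg <- tiny_config()
  a <- run_abm(cfg, t_end = 60, record_every = 10, seed = 42)
  b <- run_abm(cfg, t_end = 60, record_every = 10, seed = 42)
  expect_identical(a, b)

  # extinct state: agents stay absent, resource relaxes toward K
  cfg0 <- update_config(cfg, n0 = 1)
  st <- init_state(cfg0, seed = 15)
  st$agents <- st$agents[0, ]
  st$resource[] <- 0.3
  set.seed(16)
  st2 <- step_model(st, cfg0, n_steps = 200)
  expect_equal(nrow(st2$agents), 0)
  expect_true(all(st2$resource > 0.99 * cfg0$K_cap))
  expect_equal(st2$t, 200)
})

test_that("the pressure ramp lowers D by rho per step down to D_min", {
  cfg <- update_config(tiny_config(), rho = 1e-3, D = 0.1, D_min = 0.05)
  ts <- run_abm(cfg, t_end = 80, record_every = 10, seed = 17)
  # D(t) = max(D_min, D0 - rho * t); the floor is reached at step 50
  expect_equal(ts$D, pmax(0.05, 0.1 - 1e-3 * ts$t))
  expect_equal(ts$D[ts$t >= 50], rep(0.05, sum(ts$t >= 50)))
})

test_that("run records bookkeeping matches its contract", {
  cfg <- tiny_config()
  ts <- run_abm(cfg, t_end = 100, record_every = 10, seed = 18)
  expect_equal(ts$t, seq(0, 100, by = 10))
  expect_equal(ncol(ts), 6)

  # an extinct run keeps recording n = 0, with missing mean parameters
  cfgdie <- update_config(cfg, E_b = 5, n0 = 5) # basal cost kills in 2 steps
  tsd <- run_abm(cfgdie, t_end = 50, record_every = 5, seed = 19)
  expect_true(any(tsd$n == 0))
  ext <- which(tsd$n == 0)
  expect_true(all(diff(ext) == 1)) # extinction absorbing on the record grid
  expect_true(all(is.na(tsd$mean_w_harvest[ext])))
  expect_true(all(!is.na(tsd$mean_w_harvest[tsd$n > 0])))
})

test_that("agent energy stays within [0, e_max] along a run", {
  cfg <- tiny_config()
  st <- init_state(cfg, seed = 20)
  set.seed(21)
  for (k in 1:30) {
    st <- step_model(st, cfg, n_steps = 1)
    if (nrow(st$agents) > 0) {
      expect_true(all(st$agents$energy >= 0))
      expect_true(all(st$agents$energy <= cfg$e_max))
    }
    expect_true(all(st$resource >= 0 & st$resource <= cfg$K_cap))
  }
})
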
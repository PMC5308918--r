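#' Initialize the model state
#'
#' Fills every site with resource at carrying capacity and places `n0`
#' agents uniformly at random, each with energy `e_init` and decision
#' parameters drawn independently from `Uniform(w_min, w_max)` (pin initial
#' values by setting `w_min == w_max`, as in the pressure-ramp protocol).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; when given, `set.seed(seed)` is called
#'   so the initial state is reproducible.
#' @return an object of class `"abm_state"`: a list with elements `t`
#'   (time-step), `D` (current diffusion coefficient), `resource`
#'   (`grid_side` x `grid_side` matrix), and `agents` (data frame with
#'   columns `id`, `x`, `y`, `energy`, `w_harvest`, `w_move`; coordinates
#'   are 0-based).
#' @examples
#' st <- init_state(sim_config(grid_side = 10, n0 = 5), seed = 1)
#' nrow(st$agents)
#' @export
init_state <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  st <- cpp_init_state(unclass(cfg))
  as_abm_state(st)
}

as_abm_state <- function(st) {
  st$agents <- as.data.frame(st$agents)
  class(st) <- "abm_state"
  st
}

#' @export
print.abm_state <- function(x, ...) {
  cat(sprintf("<abm_state> t=%d, n=%d agents, grid %dx%d, D=%g\n",
              x$t, nrow(x$agents), nrow(x$resource), ncol(x$resource), x$D))
  cat(sprintf("  total resource %.3f; mean energy %s\n", sum(x$resource),
              if (nrow(x$agents) > 0)
                sprintf("%.3f", mean(x$agents$energy)) else "NA"))
  invisible(x)
}

#' Resource growth and diffusion step
#'
#' Applies one update of the resource field: logistic growth
#' `R + r_growth * R * (1 - R / K_cap)` on every site, followed by explicit
#' diffusion `+ D * sum(R_nb - R_site)` over the four von Neumann
#' neighbours, with the result clipped to `[0, K_cap]`. On a torus with
#' `r_growth = 0` the scheme conserves total resource exactly (up to
#' floating-point accumulation).
#'
#' @param resource square numeric matrix of site resource densities, or an
#'   `abm_state` (in which case the updated state is returned).
#' @param cfg a [sim_config()]; `D` may be overridden via `D`.
#' @param D diffusion coefficient to use (defaults to the state's current
#'   `D`, or `cfg$D` for a bare matrix).
#' @return a matrix (or updated `abm_state`) of the same shape.
#' @export
step_resource <- function(resource, cfg, D = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(resource, "abm_state")) {
    st <- resource
    dd <- if (is.null(D)) st$D else D
    st$resource <- cpp_step_resource(st$resource, cfg$torus, cfg$r_growth,
                                     cfg$K_cap, dd)
    return(st)
  }
  stopifnot(is.matrix(resource), nrow(resource) == ncol(resource))
  dd <- if (is.null(D)) cfg$D else D
  cpp_step_resource(resource, cfg$torus, cfg$r_growth, cfg$K_cap, dd)
}

#' Local observation of an agent
#'
#' Assembles what an agent perceives: the resource on its own site, the
#' resource on its four von Neumann neighbours, and the agent counts on all
#' five sites (own count excludes the agent itself).
#'
#' @param state an `abm_state`.
#' @param agent row index (1-based) into `state$agents`.
#' @param cfg a [sim_config()].
#' @return a list with `energy`, `R_site`, `R_nb` (length 4, order N, E, S,
#'   W), `nb_ok` (valid-neighbour flags, all `TRUE` on a torus),
#'   `count_site` (other agents on the own site) and `count_nb`.
#' @export
observe <- function(state, agent, cfg) {
  stopifnot(inherits(state, "abm_state"), inherits(cfg, "sim_config"))
  ag <- state$agents
  stopifnot(agent >= 1, agent <= nrow(ag))
  L <- cfg$grid_side
  x <- ag$x[agent]; y <- ag$y[agent]
  dx <- c(0L, 1L, 0L, -1L); dy <- c(-1L, 0L, 1L, 0L)
  R_nb <- numeric(4); cnt_nb <- numeric(4); ok <- logical(4)
  for (d in 1:4) {
    nx <- x + dx[d]; ny <- y + dy[d]
    if (cfg$torus) {
      nx <- nx %% L; ny <- ny %% L
    } else if (nx < 0 || nx >= L || ny < 0 || ny >= L) {
      next
    }
    ok[d] <- TRUE
    R_nb[d] <- state$resource[nx + 1, ny + 1]
    cnt_nb[d] <- sum(ag$x == nx & ag$y == ny)
  }
  list(energy = ag$energy[agent],
       R_site = state$resource[x + 1, y + 1],
       R_nb = R_nb, nb_ok = ok,
       count_site = sum(ag$x == x & ag$y == y) - 1,
       count_nb = cnt_nb)
}

#' Satisfaction scores of an agent
#'
#' The decision of an agent is driven by two satisfaction scores in
#' \[0, 1\], each an equal-weight average of normalized hunger, food
#' availability and crowding terms:
#' `A_h = mean(energy/e_max, 1 - R_site/K_cap, crowd_site)` and
#' `A_m = mean(energy/e_max, R_site/K_cap, 1 - max_nb R/K_cap, crowd_nb)`,
#' where a crowding term is `min(1, count / crowd_sat)` and `crowd_nb`
#' averages the four neighbour terms. A fully satisfied agent (score 1) has
#' no reason to act.
#'
#' @param obs an observation from [observe()] (or a hand-built list with the
#'   same fields).
#' @param cfg a [sim_config()].
#' @return named numeric vector `c(A_h=, A_m=)`.
#' @export
satisfaction_scores <- function(obs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cpp_satisfaction(obs$energy, obs$R_site, as.numeric(obs$R_nb),
                   as.logical(obs$nb_ok), obs$count_site,
                   as.numeric(obs$count_nb), unclass(cfg))
}

#' Stochastic action choice of an agent
#'
#' Draws the agent's action for this time-step. With satisfaction scores
#' `A_h`, `A_m` (see [satisfaction_scores()]), the agent harvests with
#' probability `exp(-w_harvest * A_h)`; failing that it moves with
#' probability `exp(-w_move * A_m)` toward the neighbouring site with the
#' most resource (ties broken uniformly at random); otherwise it stays idle.
#' A `w` value of 0 therefore forces the corresponding action, and large
#' values suppress it.
#'
#' @param agent one-row data frame (or list) with `energy`, `w_harvest`,
#'   `w_move`.
#' @param obs observation list as returned by [observe()].
#' @param cfg a [sim_config()].
#' @return a list with `action` (one of `"HARVEST"`, `"MOVE"`, `"IDLE"`) and
#'   `direction` (`"N"`, `"E"`, `"S"`, `"W"`, or `NA` unless moving).
#' @export
decide <- function(agent, obs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  res <- cpp_decide(agent$energy, agent$w_harvest, agent$w_move, obs$R_site,
                    as.numeric(obs$R_nb), as.logical(obs$nb_ok),
                    obs$count_site, as.numeric(obs$count_nb), unclass(cfg))
  acts <- c("HARVEST", "MOVE", "IDLE")
  dirs <- c("N", "E", "S", "W")
  list(action = acts[res[["action"]] + 1L],
       direction = if (res[["action"]] == 1L) dirs[res[["dir"]] + 1L]
                   else NA_character_)
}

#' Apply an action to the model state
#'
#' Energy bookkeeping of a single agent action. HARVEST removes
#' `harvest_fraction * R` from the agent's site and credits
#' `energy_yield * harvest_fraction * R - E_h`; MOVE shifts the agent one
#' site (wrapping on a torus) at cost `E_m`; IDLE transfers nothing. In all
#' cases the basal cost `E_b` is paid and energy is clipped to
#' `[0, e_max]`.
#'
#' @param state an `abm_state`.
#' @param agent row index (1-based) of the acting agent.
#' @param action `"HARVEST"`, `"MOVE"` or `"IDLE"`.
#' @param direction `"N"`, `"E"`, `"S"` or `"W"` (MOVE only).
#' @param cfg a [sim_config()].
#' @return the updated `abm_state`.
#' @export
apply_action <- function(state, agent, action, cfg, direction = NA) {
  stopifnot(inherits(state, "abm_state"), inherits(cfg, "sim_config"))
  code <- match(action, c("HARVEST", "MOVE", "IDLE")) - 1L
  if (is.na(code)) stop("unknown action: ", action)
  dir <- 0L
  if (code == 1L) {
    dir <- match(direction, c("N", "E", "S", "W")) - 1L
    if (is.na(dir)) stop("MOVE requires direction N, E, S or W")
  }
  as_abm_state(cpp_apply_action(unclass_state(state), agent, code, dir,
                                unclass(cfg)))
}

unclass_state <- function(state) {
  st <- unclass(state)
  st$agents <- as.list(st$agents)
  st
}

#' Death and reproduction
#'
#' End-of-step demography. Each agent dies with probability
#' `exp(-energy / death_scale)` (certain death at zero energy); each
#' survivor reproduces with probability
#' `rep_prob_max * plogis((energy - rep_threshold) / (0.1 * e_max))`.
#' Offspring are placed on the parent's site, the parent's energy is split
#' equally with the offspring, and offspring decision parameters are set by
#' [inherit_w()].
#'
#' @param state an `abm_state`.
#' @param cfg a [sim_config()].
#' @return the updated `abm_state`.
#' @export
demography <- function(state, cfg) {
  stopifnot(inherits(state, "abm_state"), inherits(cfg, "sim_config"))
  as_abm_state(cpp_demography(unclass_state(state), unclass(cfg)))
}

#' Per-energy vital rates
#'
#' The closed-form per-step death and reproduction probabilities as
#' functions of agent energy, as used by [demography()].
#'
#' @param energy numeric vector of energies.
#' @param cfg a [sim_config()].
#' @return data frame with columns `energy`, `p_death`, `p_rep`.
#' @export
vital_rates <- function(energy, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- cpp_vital_rates(as.numeric(energy), unclass(cfg))
  n <- length(energy)
  data.frame(energy = energy, p_death = v[seq_len(n)],
             p_rep = v[n + seq_len(n)])
}

#' Offspring decision parameters
#'
#' In the adaptive variant the offspring inherits the parent's `w_harvest`
#' and `w_move` plus independent `Normal(0, mutation_scale * z)` deviations,
#' clipped at 0. In the non-adaptive variant both values are redrawn from
#' the initial `Uniform(w_min, w_max)`, ignoring the parent, so the
#' population-level distribution of decision parameters cannot evolve.
#'
#' @param parent list or one-row data frame with `w_harvest` and `w_move`.
#' @param cfg a [sim_config()].
#' @return named numeric vector `c(w_harvest=, w_move=)`.
#' @export
inherit_w <- function(parent, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cpp_inherit(parent$w_harvest, parent$w_move, unclass(cfg))
}

#' Advance the model
#'
#' Runs full time-steps: resource growth/diffusion over all sites, then all
#' agents in freshly randomized order (observe, decide, act), then
#' demography, then (when `rho > 0`) the pressure ramp
#' `D <- max(D_min, D - rho)`. The extinct state is absorbing: with no
#' agents the resource simply relaxes back toward `K_cap`.
#'
#' @param state an `abm_state`.
#' @param cfg a [sim_config()].
#' @param n_steps number of steps to advance (default 1).
#' @return the updated `abm_state`.
#' @export
step_model <- function(state, cfg, n_steps = 1) {
  stopifnot(inherits(state, "abm_state"), inherits(cfg, "sim_config"),
            n_steps >= 1)
  out <- cpp_advance(unclass_state(state), unclass(cfg), as.integer(n_steps),
                     .Machine$integer.max)
  as_abm_state(out$state)
}

#' Run the model and record a population time series
#'
#' Initializes a state (unless one is supplied) and advances it to `t_end`,
#' recording at `t = 0` and every `record_every` steps. Extinct runs keep
#' recording `n = 0` until `t_end` so that survival curves remain well
#' defined; the mean decision-parameter columns are `NA` whenever the
#' population is extinct.
#'
#' @param cfg a [sim_config()].
#' @param t_end final time-step (>= 1).
#' @param record_every recording interval in steps (>= 1).
#' @param seed optional integer seed for full reproducibility.
#' @param state optional starting `abm_state`; by default a fresh
#'   [init_state()] is drawn.
#' @param keep_state if `TRUE`, attach the final state as attribute
#'   `"final_state"`.
#' @return a data frame of class `"population_ts"` with columns `t`, `n`,
#'   `mean_w_harvest`, `mean_w_move`, `total_resource`, `D`.
#' @examples
#' ts <- run_abm(sim_config(grid_side = 10, n0 = 20), t_end = 50,
#'               record_every = 10, seed = 1)
#' ts$n
#' @export
run_abm <- function(cfg, t_end, record_every = 1, seed = NULL, state = NULL,
                    keep_state = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), t_end >= 1, record_every >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- as_abm_state(cpp_init_state(unclass(cfg)))
  st0 <- state
  first <- data.frame(t = st0$t, n = nrow(st0$agents),
                      mean_w_harvest = if (nrow(st0$agents) > 0)
                        mean(st0$agents$w_harvest) else NA_real_,
                      mean_w_move = if (nrow(st0$agents) > 0)
                        mean(st0$agents$w_move) else NA_real_,
                      total_resource = sum(st0$resource), D = st0$D)
  out <- cpp_advance(unclass_state(state), unclass(cfg),
                     as.integer(t_end - st0$t), as.integer(record_every))
  rec <- as.data.frame(out$records)
  ts <- rbind(first, rec)
  ts$t <- as.integer(ts$t)
  ts$n <- as.integer(ts$n)
  class(ts) <- c("population_ts", "data.frame")
  if (keep_state) attr(ts, "final_state") <- as_abm_state(out$state)
  ts
}

#' @export
print.population_ts <- function(x, ...) {
  cat(sprintf("<population_ts> %d records, t in [%d, %d]\n", nrow(x),
              min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
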
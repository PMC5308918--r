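#' Simulation configuration
#'
#' Builds the full parameter set of the common-pool resource agent-based
#' model. Agents live on a square lattice of sites on which a resource grows
#' logistically and diffuses between neighbouring sites. Each time-step every
#' agent decides stochastically whether to harvest its site, move to a
#' von Neumann neighbour, or stay inactive; harvesting, moving and basal
#' maintenance all cost energy, and at the end of the step agents die or
#' reproduce according to their internal energy.
#'
#' Two decision parameters, `w_harvest` and `w_move`, scale how readily an
#' agent acts: the probability of harvesting is `exp(-w_harvest * A_h)` where
#' `A_h` is a satisfaction score in \[0,1\] (an agent fully satisfied with its
#' energy, food and crowding situation does not bother to act), so `w = 0`
#' means the action is taken with probability 1 and larger values suppress
#' it. In the adaptive model variant offspring inherit their parent's `w`
#' values plus a Normal deviation of standard deviation
#' `mutation_scale * z`, so natural selection can shift the population
#' distribution of decision parameters; in the non-adaptive variant newborn
#' `w` values are redrawn from the initial `Uniform(w_min, w_max)`, freezing
#' that distribution in place.
#'
#' @param grid_side sites per edge of the square grid (>= 3); each site is
#'   1 km^2.
#' @param torus wrap the grid edges (default `TRUE`).
#' @param r_growth logistic resource regrowth rate, per day.
#' @param K_cap resource carrying capacity per site.
#' @param D resource diffusion coefficient, km^2/day. The explicit scheme is
#'   stable for `D <= 0.25`.
#' @param E_h,E_m,E_b energy costs (J) of harvesting, moving, and basal
#'   maintenance per time-step.
#' @param harvest_fraction fraction of the site's resource removed per
#'   harvest, in (0, 1].
#' @param energy_yield J gained per unit of resource harvested.
#' @param e_init initial agent energy, J.
#' @param e_max energy ceiling, J; also normalises energy in the decision and
#'   reproduction functions.
#' @param death_scale energy scale of mortality, J: per-step death
#'   probability is `exp(-energy / death_scale)`.
#' @param rep_threshold energy (J) at which the reproduction probability
#'   reaches half its maximum.
#' @param rep_prob_max maximum per-step reproduction probability.
#' @param w_min,w_max bounds of the initial uniform distribution of the
#'   agent decision parameters.
#' @param z inheritance deviation parameter (rate of adaptation): offspring
#'   `w` values deviate from the parent by `Normal(0, mutation_scale * z)`.
#' @param mutation_scale base width of the inheritance deviation.
#' @param crowd_sat agent count at which a site is considered fully crowded.
#' @param adaptive logical; inherit (`TRUE`) or redraw (`FALSE`) offspring
#'   decision parameters.
#' @param n0 initial number of agents.
#' @param rho pressure rate: decrease of `D` per time-step (applied when
#'   positive), so `D(t) = max(D_min, D - rho * t)`.
#' @param D_min floor for `D` under pressure.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [run_abm()], [run_ensemble()], [init_state()]
#' @examples
#' cfg <- sim_config(grid_side = 10, n0 = 20)
#' cfg$D
#' @export
sim_config <- function(grid_side = 50,
                       torus = TRUE,
                       r_growth = 0.1,
                       K_cap = 1,
                       D = 0.1,
                       E_h = 0.2,
                       E_m = 0.2,
                       E_b = 0.15,
                       harvest_fraction = 0.5,
                       energy_yield = 3.7,
                       e_init = 5,
                       e_max = 10,
                       death_scale = 1,
                       rep_threshold = 6,
                       rep_prob_max = 0.05,
                       w_min = 5,
                       w_max = 15,
                       z = 1,
                       mutation_scale = 0.1,
                       crowd_sat = 5,
                       adaptive = TRUE,
                       n0 = 100,
                       rho = 0,
                       D_min = 0.05) {
  cfg <- list(grid_side = as.integer(grid_side), torus = isTRUE(torus),
              r_growth = as.numeric(r_growth), K_cap = as.numeric(K_cap),
              D = as.numeric(D), E_h = as.numeric(E_h), E_m = as.numeric(E_m),
              E_b = as.numeric(E_b),
              harvest_fraction = as.numeric(harvest_fraction),
              energy_yield = as.numeric(energy_yield),
              e_init = as.numeric(e_init), e_max = as.numeric(e_max),
              death_scale = as.numeric(death_scale),
              rep_threshold = as.numeric(rep_threshold),
              rep_prob_max = as.numeric(rep_prob_max),
              w_min = as.numeric(w_min), w_max = as.numeric(w_max),
              z = as.numeric(z), mutation_scale = as.numeric(mutation_scale),
              crowd_sat = as.numeric(crowd_sat), adaptive = isTRUE(adaptive),
              n0 = as.integer(n0), rho = as.numeric(rho),
              D_min = as.numeric(D_min))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a [sim_config()] and fails with a
#' message naming the violated constraint.
#'
#' @param cfg a `sim_config` object (or a bare named list with the same
#'   fields).
#' @return `cfg`, invisibly classed as `"sim_config"`, if valid.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  req <- c("grid_side", "torus", "r_growth", "K_cap", "D", "E_h", "E_m",
           "E_b", "harvest_fraction", "energy_yield", "e_init", "e_max",
           "death_scale", "rep_threshold", "rep_prob_max", "w_min", "w_max",
           "z", "mutation_scale", "crowd_sat", "adaptive", "n0", "rho",
           "D_min")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0)
    fail(paste("missing fields:", paste(missing, collapse = ", ")))
  num <- cfg[setdiff(req, c("torus", "adaptive"))]
  if (any(!vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1))))
    fail("all numeric fields must be finite scalars")
  if (cfg$grid_side < 3) fail("grid_side must be >= 3")
  if (cfg$r_growth < 0) fail("r_growth must be >= 0")
  if (cfg$K_cap <= 0) fail("K_cap must be > 0")
  if (cfg$D < 0 || cfg$D > 0.25)
    fail("D must lie in [0, 0.25] (explicit-diffusion stability)")
  for (f in c("E_h", "E_m", "E_b", "e_init", "e_max"))
    if (cfg[[f]] < 0) fail(paste(f, "must be >= 0"))
  if (cfg$harvest_fraction <= 0 || cfg$harvest_fraction > 1)
    fail("harvest_fraction must lie in (0, 1]")
  if (cfg$energy_yield < 0) fail("energy_yield must be >= 0")
  if (cfg$e_init > cfg$e_max) fail("e_init must not exceed e_max")
  if (cfg$death_scale <= 0) fail("death_scale must be > 0")
  if (cfg$rep_prob_max < 0 || cfg$rep_prob_max > 1)
    fail("rep_prob_max must lie in [0, 1]")
  if (cfg$w_min < 0) fail("w_min must be >= 0")
  if (cfg$w_min > cfg$w_max) fail("w_min must not exceed w_max")
  if (cfg$z < 0) fail("z must be >= 0")
  if (cfg$mutation_scale < 0) fail("mutation_scale must be >= 0")
  if (cfg$crowd_sat <= 0) fail("crowd_sat must be > 0")
  if (cfg$n0 < 1) fail("n0 must be >= 1")
  if (cfg$rho < 0) fail("rho must be >= 0")
  if (cfg$D_min > cfg$D) fail("D_min must not exceed D")
  class(cfg) <- "sim_config"
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", if (x$adaptive) "adaptive" else "non-adaptive",
      "variant\n")
  cat(sprintf("  grid %dx%d (%s), r_growth=%g, K_cap=%g, D=%g\n",
              x$grid_side, x$grid_side, if (x$torus) "torus" else "bounded",
              x$r_growth, x$K_cap, x$D))
  cat(sprintf("  costs E_h=%g E_m=%g E_b=%g; yield=%g x fraction=%g\n",
              x$E_h, x$E_m, x$E_b, x$energy_yield, x$harvest_fraction))
  cat(sprintf("  energy: init=%g max=%g death_scale=%g rep@%g (max p=%g)\n",
              x$e_init, x$e_max, x$death_scale, x$rep_threshold,
              x$rep_prob_max))
  cat(sprintf("  w ~ U(%g, %g), z=%g, mutation_scale=%g, n0=%d\n",
              x$w_min, x$w_max, x$z, x$mutation_scale, x$n0))
  if (x$rho > 0)
    cat(sprintf("  pressure ramp: rho=%g down to D_min=%g\n", x$rho, x$D_min))
  invisible(x)
}

#' Modify a configuration
#'
#' Returns a copy of `cfg` with the named fields replaced, re-validated.
#'
#' @param cfg a [sim_config()].
#' @param ... named fields to override.
#' @return a new `sim_config`.
#' @examples
#' cfg <- update_config(sim_config(), E_h = 0.07, adaptive = FALSE)
#' @export
update_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$grid_side <- as.integer(cfg$grid_side)
  cfg$n0 <- as.integer(cfg$n0)
  out <- validate_sim_config(unclass(cfg))
  out
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat key-value YAML mirroring the
#' [sim_config()] field names; any subset of fields may be given and the rest
#' take their defaults.
#'
#' @param path file path.
#' @param cfg a [sim_config()] (for writing).
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a flat key-value mapping")
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
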
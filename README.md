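# cpresim

Agent-based simulation and resilience analysis of a common-pool resource
system.

## What this is for

Ecological and social-ecological modellers who want to quantify what *agent
adaptation* does to a system under pressure face two practical problems:
the output of an agent-based model (ABM) is a stochastic, time-dependent
distribution rather than a number, and adaptation moves that distribution
on time scales far longer than the obvious burn-in. `cpresim` packages a
complete workbench for this question around a concrete test case:

* a fast (C++ core) discrete-time ABM of agents harvesting a renewable,
  diffusing resource on a square lattice, where each agent's readiness to
  harvest or move is governed by two heritable parameters
  (`w_harvest`, `w_move`) — with **adaptation on** (offspring inherit the
  parent's parameters with a small mutation, so natural selection acts) or
  **off** (offspring parameters are redrawn from the initial distribution,
  freezing it);
* replicate ensembles and the two kinds of output histograms of the
  population size `n`: time-dependent (across replicates at fixed `t`) and
  time-averaged (across the steps of one long run);
* distance measures between output pdfs, centred on the earth-mover's
  distance

  `d_e(P_a, P_b) = min_g sum_{j,k} g(j,k) |j - k|`,

  minimized over non-negative flows `g` with marginals `P_a` and `P_b` and
  computed exactly by a cumulative-mass sweep. Unlike the Euclidean
  distance or the Jensen-Shannon divergence (bounded by `ln 2`), `d_e`
  keeps growing as two non-overlapping pdfs separate — which is what makes
  the adaptation-effect curve `Q(t) = d_e(P_a(n,t), P_b(n,t))` and its
  rate `Q'(t) = Q(t) - Q(t - dt)` informative on long horizons;
* stationarity diagnostics (Mann-Kendall + runs test on window means) and
  an ergodicity test (thinned single-run sample vs. ensemble sample,
  two-sample Kolmogorov-Smirnov) — ongoing adaptation shows up as a
  failure of ergodicity;
* survival analysis under pressure: survival curves over replicates, the
  exponential extinction fit `N_pos(t) = N_pos,0 * exp(-lambda * t)`
  (least squares in count space, `lambda >= 0`), harvest-cost sweeps,
  pressure ramps `D(t) = max(D_min, D_0 - rho t)` on the resource
  diffusion coefficient, and `z`-vs-`rho` phase diagrams of survival.

## Worked example

```r
library(cpresim)

cfg <- sim_config()          # calibrated 50x50 default, adaptive variant
cfg
#> <sim_config> adaptive variant
#>   grid 50x50 (torus), r_growth=0.1, K_cap=1, D=0.1
#>   costs E_h=0.2 E_m=0.2 E_b=0.15; yield=3.7 x fraction=0.5
#>   energy: init=5 max=10 death_scale=1 rep@6 (max p=0.05)
#>   w ~ U(5, 15), z=1, mutation_scale=0.1, n0=100

# adaptive vs non-adaptive ensembles, Q(t) between their histograms
cmp <- compare_adaptation(cfg, n_rep = 20, t_end = 3000,
                          record_every = 500, master_seed = 1)
round(cmp$Q$Q, 1)
#> [1]   0.0 519.5 567.0 600.7 608.1 616.1 611.1

# ergodicity: the adaptive variant keeps drifting, the frozen one does not
ens <- run_ensemble(update_config(cfg, adaptive = FALSE), n_rep = 100,
                    t_end = 4000, record_every = 4000, master_seed = 2)
long <- run_abm(update_config(cfg, adaptive = FALSE), t_end = 20000,
                record_every = 25, seed = 3)
ergodicity_test(long$n[long$t >= 4000], ens$n_matrix[, 2])
#> <abm_test> ergodicity (two-sample Kolmogorov-Smirnov)
#>   statistic = 0.31, p = 0.08845, alpha = 0.05 -> do not reject

# extinction rate past the tipping point, with and without adaptation
sc <- survival_curve(run_ensemble(update_config(cfg, adaptive = FALSE,
                                                E_h = 0.3),
                                  n_rep = 25, t_end = 4000,
                                  record_every = 200, master_seed = 4))
fit_extinction(sc)
#> <extinction_fit> lambda = 0.000267076 per step, MSE = 18.38 (N0 = 25)
```

`Q(t)` climbs steeply in the first thousand steps while selection sorts
the initial spread of decision parameters (the adaptive population grows
several-fold past the frozen variant), then keeps drifting slowly; the
ergodicity test retains the null for the frozen variant (its time sample
and ensemble sample agree in distribution, whereas the adaptive variant
rejects decisively); and at `E_h = 0.3` the non-adaptive population decays
with a fitted extinction rate of about 2.7e-4 per day, while the same
ensemble with adaptation enabled yields `lambda = 0` (its survival curve
goes flat after the first few hundred steps).

A thin command-line wrapper over the same functions ships at
`inst/cli/cpresim.R` with subcommands `run`, `ensemble`, `compare`,
`tests`, `sweep-eh`, `phase` and `fixtures`; every command writes CSV plus
a JSON metadata sidecar (config echo and all seeds) sufficient to replay
it. See `?cpresim_cli`.

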
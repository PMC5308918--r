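---
title: "Measuring adaptation and resilience in a common-pool resource model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adaptation and resilience in a common-pool resource model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpresim)
```

## The question

Populations of autonomous agents that compete for a shared, renewable
resource can absorb a certain amount of outside pressure before they
collapse. When the agents' behavioural rules can change — here through
natural selection on heritable decision parameters — the boundary of the
safe region itself moves over time. `cpresim` provides (i) a stochastic
agent-based simulator of such a system with adaptation that can be switched
off, and (ii) the analysis layer needed to quantify what adaptation does:
distributional distance measures between model variants, stationarity and
ergodicity diagnostics, extinction-rate fits, and pressure-ramp experiments.

The central model output throughout is the population size $n$, and the
central objects are its *time-dependent* histograms $P(n, t)$ (across
replicate runs at fixed $t$) and *time-averaged* histograms (across the
recorded steps of one long run).

## The simulator

Agents live on a `grid_side` x `grid_side` torus of 1 km^2 sites. Each site
carries a resource density $R \in [0, K]$ updated every step by logistic
growth $R \mathrel{+}= r\,R(1 - R/K)$ followed by explicit diffusion
$R \mathrel{+}= D \sum_{\mathrm{nb}} (R_{\mathrm{nb}} - R)$ over the four
von Neumann neighbours (stable for $D \le 0.25$; results clipped to
$[0, K]$).

Each time-step every agent, in freshly randomized order, observes its own
energy, the resource on its site and its four neighbours, and the agent
counts on those sites, and then chooses stochastically between harvesting,
moving, and staying idle:

* Two *satisfaction scores* in $[0,1]$ summarize how little reason the
  agent has to act. The harvest score averages satiation ($e/e_{\max}$),
  the lack of food on the spot ($1 - R/K$), and crowding
  ($\min(1, c/c_{\mathrm{sat}})$); the move score averages satiation, food
  on the spot, the lack of better food next door
  ($1 - \max_{\mathrm{nb}} R/K$), and neighbour crowding.
* The agent harvests with probability $\exp(-w_{\mathrm{harvest}} A_h)$;
  failing that, it moves with probability $\exp(-w_{\mathrm{move}} A_m)$
  toward the richest neighbouring site (ties uniform); otherwise it idles.
  A parameter value of 0 forces the action; large values suppress it.

Harvesting removes a fraction `harvest_fraction` of the site's resource and
converts it to energy at rate `energy_yield`, minus the cost $E_h$; moving
costs $E_m$; every agent pays the basal cost $E_b$ every step; energy is
clipped to $[0, e_{\max}]$. At the end of the step each agent dies with
probability $\exp(-e/\mathrm{death\_scale})$ (certain at $e = 0$) and each
survivor reproduces with probability
$p_{\max} \cdot \mathrm{logistic}((e - e_{\mathrm{thr}})/(0.1\,e_{\max}))$,
splitting its energy equally with the offspring.

The two decision parameters are the adaptive substrate. Initial agents draw
them from $U(w_{\min}, w_{\max})$. In the **adaptive** variant offspring
inherit the parent's values plus independent
$\mathcal{N}(0, \mathrm{mutation\_scale} \cdot z)$ deviations (clipped at
0), so selection can shift the population distribution; $z$ is the *rate of
adaptation*. In the **non-adaptive** variant offspring values are redrawn
from the initial uniform, which freezes the distribution and disables
selection. Extinction is absorbing, and runs always continue to their
configured end so survival curves are well defined.

All functional forms above (the exponential decision function, the
equal-weight satisfaction scores, exponential mortality, logistic
reproduction) are deliberately minimal monotone choices, each implemented
as a single function in the C++ core so that alternative forms can be
substituted in one place.

## Default parameterization

The defaults in `sim_config()` were fixed once, as a package-level design
choice, to place the non-adaptive variant in a biologically sensible
regime: a population of order $10^2$ agents on the 50 x 50 grid that
stabilizes after a transient of roughly a thousand steps and persists for
at least tens of thousands of steps, with the across-replicate mean
settling near 90-100 agents at $t = 1000$. The calibration knobs were the
initial population, initial energy, basal cost and energy yield
(`n0 = 100`, `e_init = 5`, `E_b = 0.15`, `energy_yield = 3.7`); regrowth
was set to `r_growth = 0.1` after observing that faster regrowth leaves the
~90-agent regime barely regulated (the grid sits at carrying capacity and
the population performs a near-critical random walk with frequent chance
extinctions), while slower regrowth cannot support the initial transient.

The initial decision-parameter range is $U(5, 15)$, centred on the value 10
used to pin agents in the pressure-ramp protocol. Adaptation then has two
phases: selection first sorts the standing variation within the initial
range (roughly the first thousand steps, during which the adaptive
population grows well past the frozen variant), and afterwards a
mutation-limited drift of the parameter distribution continues over $10^4$
or more steps — the long-time-scale signal the ergodicity diagnostic is
designed to detect. A much wider initial range (for example $U(0, 20)$)
would make the sorting phase overwhelm everything and leave no long-run
drift, which is why the narrower range was chosen. With
`mutation_scale = 0.1`, $z$ multiplies a per-generation deviation of 0.1
on parameters of order 10.

```{r defaults}
sim_config()
```

## What the analysis layer computes

**Histograms and distances.** `run_ensemble()` produces the
replicate-by-time matrix of $n$; `ensemble_histogram()` and
`time_averaged_histogram()` give the two kinds of output pdfs as
`binned_pdf` objects (integer bins of width one agent). Three distances
compare pdfs on the zero-padded union of their supports: the earth-mover's
distance `emd()` (1-D optimal transport with ground distance $|j - k|$ in
agents, computed by the exact cumulative-mass sweep over consecutive
support values), the Euclidean distance, and the Jensen-Shannon divergence
(natural logarithm, so its ceiling is $\ln 2$). Only the earth-mover's
distance keeps growing once two pdfs no longer overlap, which is why it is
the default measure of adaptation effects; `transport_plan()` exposes an
explicit optimal flow matrix for inspection. The adaptation-effect curve
$Q(t)$ is the slice-wise earth-mover's distance between the adaptive and
non-adaptive time-dependent histograms, and the adaptation rate $Q'(t)$ is
its first difference on the recording grid, computed without smoothing so
that $\sum Q'$ telescopes exactly.

**Stationarity and ergodicity.** Raw step-to-step output fluctuates too
much for a direct test, so `stationarity_test()` averages the series over
non-overlapping windows and applies two complementary tests to the window
means — a Mann-Kendall trend test and a runs test about the median — each
at level $\alpha/2$ (Bonferroni). `ergodicity_test()` compares a
single-run sample (thinned by the estimated autocorrelation time, since
consecutive recorded steps are strongly dependent and the paper-level
protocol is silent on this) against an across-replicate sample at a fixed
time with a two-sample Kolmogorov-Smirnov test; the model is called ergodic
when the null of identical distributions is *not* rejected. Both tests are
named strategies behind one interface, so an alternative instantiation of
"trend test" or "runs statistic" can be swapped in without touching
callers. `run_diagnostics()` chains them in their natural order: the
stationarity scan picks the burn-in that anchors the ergodicity comparison.

**Resilience.** `survival_curve()` counts replicates with a positive
population over time and `fit_extinction()` fits
$N_{\mathrm{pos}}(t) = N_{\mathrm{pos},0} e^{-\lambda t}$ by least squares
in count space, with $N_{\mathrm{pos},0}$ fixed at the known replicate
total and $\lambda \ge 0$ constrained. Count space is used rather than a
log-linear regression because survival curves legitimately reach zero;
the one-dimensional objective is minimized by golden-section search with
the exact boundary fit $\lambda = 0$ returned whenever it is at least as
good, so flat curves yield exactly zero. `sweep_harvest_cost()`,
`pressure_ramp()` and `phase_diagram()` orchestrate the standard
experiments over $E_h$, $\rho$ and $z$.

## Behaviour of the calibrated model

Three robust regimes, all exercised by the test suite at desk scale
(stated sizes):

* **Adaptation raises the long-run population.** Selection drives
  $w_{\mathrm{harvest}}$ down (agents harvest more readily) over thousands
  of steps; the adaptive long-run mean of $n$ exceeds the non-adaptive one
  by a factor of several (checked with 6 replicates per variant over
  10,000 steps). Consequently the adaptive variant fails the ergodicity
  test over a 20,000-step horizon with burn-in 4,000 and a 120-replicate
  ensemble, while the non-adaptive variant passes it under the identical
  protocol. The burn-in of 4,000 steps is chosen to sit safely past the
  calibrated model's slow initial climb (the across-replicate mean keeps
  creeping for a few thousand steps after the visible ~1,000-step
  transient).
* **Adaptation rescues populations near the tipping point.** With the
  default economy the non-adaptive population collapses once the harvest
  cost is raised past $E_h \approx 0.25$; at $E_h = 0.30$ its survival
  curve decays steadily ($\lambda > 0$ over 30 replicates and 4,000 steps)
  while adaptive extinctions, when they occur at all, are confined to the
  early steps and the late survival curve is flat.
* **Resilience depends on the rate of adaptation.** Under the pressure-ramp
  protocol (all agents pinned at $w = 10$, move cost 0.1, diffusion lowered
  from 0.1 to 0.05 at rate $\rho = 5\times10^{-5}$ per step), populations
  with $z = 1$ reliably collapse, while a substantial fraction with
  $z = 5$ adapt their movement behaviour quickly enough to survive
  (checked with 20 replicates per $z$ over 10,000 steps).

## Known limitations

* The exact functional forms and default constants of the original
  simulation model behind this class of systems are not public; everything
  here is a reconstruction honouring the documented qualitative
  constraints. Numeric outputs (population levels, extinction rates,
  tipping locations) should be read as properties of *this*
  parameterization, not as re-measurements of any published run.
* In this reconstruction the harvest cost acts purely through the energy
  budget — the decision rules do not sense it — so extinction under
  harvest-cost pressure appears at *high* $E_h$ (starvation), and on the
  low range $E_h \in [0, 0.1]$ no extinctions occur at all
  ($\lambda \equiv 0$ for both variants). A destabilizing
  cheap-harvest/overshoot regime, in which lowering $E_h$ hastens
  collapse, was searched for extensively (fast reproduction, sharp
  mortality, slow regrowth, weakened satiation) and does not arise under
  these functional forms: the satiation and food-availability terms act as
  immediate negative feedback that damps boom-bust cycles, and removing
  that feedback produces all-or-nothing collapse rather than a graded
  cliff. The monotone-in-$E_h$ checks on the low range therefore hold
  degenerately, and the meaningful adaptation-rescue contrast is tested at
  the reconstruction's actual tipping point instead.
* The synthetic-data generators used to validate the analysis layer (iid
  and AR(1) series, Gaussian-shaped histogram pairs, geometric-hazard
  survival curves) emulate the *statistical* structure the tests must
  detect — drift, dependence, distributional separation, exponential
  extinction — but none of the spatial mechanics of the simulator. Tests
  passing on them validate the measurement instruments, not the ecology.
* Resource observation is noise-free; a perception-noise hook would be the
  natural first extension. There are no direct agent-agent interactions
  (trade, imitation), no continuous-time dynamics, and only the scalar
  output $n$ is analysed.

## Numerical notes

* One master seed drives everything; per-replicate seeds are spawned by a
  counter-based mix (`replicate_seed()`), so enlarging an ensemble never
  changes existing replicates, and identical configurations with identical
  seeds produce bit-identical trajectories (the C++ core draws exclusively
  from R's RNG stream).
* The earth-mover's sweep is exact for one-dimensional histograms; it is
  verified in the test suite against an independent linear-programming
  transport solver on hundreds of random instances, and
  `transport_plan()`'s greedy monotone coupling reproduces the same cost.
* Degenerate inputs are handled by convention where the underlying
  statistic is undefined: constant series have autocorrelation time 1, a
  Kolmogorov-Smirnov comparison of two identical constant samples returns
  p = 1 (ergodic), and zero-width mutation (`z = 0`) copies parental
  parameters exactly.
* Ties in the "richest neighbour" move target are broken uniformly at
  random; the agent update order is reshuffled every step to avoid
  positional bias.
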
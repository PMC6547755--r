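---
title: "Exclusion dynamics in optional public goods games: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exclusion dynamics in optional public goods games: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggexclusion)
```

## The model

`pggexclusion` studies how *social exclusion* promotes cooperation in the
optional public goods game (PGG).  Four strategies compete:

* **Cooperators (C)** invest one unit into the common pot;
* **Defectors (D)** invest nothing but share the pot;
* **Loners (L)** sit the game out for a fixed payoff `sigma`;
* **Excluders (E)** invest like cooperators and, in addition, try to expel
  each defector in their group, succeeding per attempt with probability
  `beta` at unit cost `cE`.

In an `N`-member group with `k` loners and `j` defectors of which `s`
survive exclusion, the pot of the `N - k - j` contributors is multiplied by
the amplification factor `r` (`1 < r < N`) and shared equally among the
non-excluded participants, so each receives `r (N - k - j) / (N - k - j + s)`.
An expelled defector receives nothing from that game.  A player whose
co-members are all loners cannot play and falls back to `sigma`.

Two exclusion mechanisms are compared:

* **synchronous** — every excluder attempts every defector simultaneously
  and pays `cE` for each defector it attempts;
* **asynchronous (sequential)** — excluders act in a uniformly random
  order and stop attempting a defector as soon as some excluder has
  expelled it.  An excluder among `l + 1` then pays, per defector, the
  expected cost
  `cR = (1 - (1 - beta)^(l + 1)) / ((l + 1) beta) * cE <= cE`.

Sequential exclusion is cheaper whenever `beta > 0`, and the two
mechanisms coincide as `beta -> 0`; `cR` at `beta = 0` is defined by that
continuous limit.  The package's central question is how much this cost
saving helps cooperation.

The unit cost is tied to the success probability by a cost function,
by default `cE(beta) = 0.2 * 10^beta` (increasing and convex: reliable
exclusion is disproportionately expensive).  The convexity assumption is
documented but not enforced, so alternative cost models can be explored.

## Well-mixed populations: an exact Markov chain

For a population of `M` individuals with counts `(X, Y, Z, W)` of the four
strategies, groups of `N` are sampled without replacement, which makes the
expected payoff of each strategy an exact hypergeometric expectation over
the co-member composition `(l, k, j)` and a binomial expectation over
defector survival (`payoff_C()`, `payoff_D()`, `payoff_L()`, `payoff_E()`).
Only the excluder payoff differs between mechanisms, through `cE` versus
`cR`.  When a strategy is absent its payoff is defined as the count-weighted
average payoff of the strategies present (`degenerate_payoff()`); the
average is over individuals, the natural reading of a population average.
All combinatorial weights are evaluated in log space (`lchoose`), so
population sizes of 100 and beyond are handled without overflow.

Strategies then flow towards better-paying alternatives at the *transfer
rate* `epsilon + kappa * max(pi_s2 - pi_s1, 0)`.  The perturbation rate
`epsilon > 0` keeps every switch possible, so the count process
`(X, Y, Z, W)` is an irreducible continuous-time Markov chain on
`choose(M + 3, 3)` states.  How the pairwise transfer rate aggregates into
a state-level transition rate admits two readings, and the package
implements both (`pgg_params(aggregation = )`):

* **`"type"` (default)** — the transfer rate is a macroscopic intensity
  between strategy *types*: whenever strategy `s1` is present, one of its
  carriers switches to `s2` at rate `epsilon + kappa (Delta pi)+`,
  independent of how many carriers there are.  This is the reading under
  which the transfer rate is a population-level quantity distinct from any
  individual-level imitation probability.  It is the default because it
  keeps the cooperative-probability gain of sequential exclusion small
  (grid maximum near 0.1) when exclusion is unreliable (`beta <= 0.3`)
  while letting it grow large only at small `r` and large `beta` — the
  regime structure the model is known for — whereas the count-proportional
  alternative concentrates markedly more stationary mass in transition
  regions and roughly doubles that weak-exclusion maximum.  At
  `kappa = 0` all allowed
  moves have the symmetric rate `epsilon` and the stationary law is
  uniform over all states — a closed form the tests verify.
* **`"count"`** — the state rate is `count(s1)` times the per-capita rate:
  individuals switch independently (the density-dependent reading common
  in chemical-kinetics-style count chains).  At `kappa = 0` individuals
  decouple into independent symmetric 4-state chains and the stationary
  law is `Multinomial(M, 1/4, 1/4, 1/4, 1/4)`; the tests verify this to
  1e-8 total variation.  This mode is retained for comparison studies.

### Solving for the stationary distribution

`stationary_distribution()` solves `p'Q = 0`, `sum(p) = 1` with a sparse LU
factorisation.  The default route pins the unnormalised mass of one
reference state to 1 and solves the remaining `n - 1` equations, which
preserves the generator's sparsity; residuals are around 1e-15 at
`M = 20` (1771 states).  Replacing one equation by the normalisation
constraint — the textbook alternative — densifies a factor and is kept
only as a fallback, with power iteration on the uniformized chain as a
second fallback.  A solve is rejected if `max |p'Q|` exceeds 1e-10
(1e-8 for the fallbacks), and failures name the offending parameter set.

### Stochastic stability, operationally

A state is *stochastically stable* if it retains probability in the limit
distribution as the perturbation vanishes.  The package operationalizes
this definition rather than computing the exact `epsilon -> 0` limit by
tree surgery: `stable_states()` re-solves the chain along a decreasing
`epsilon` schedule (default `1e-2, 1e-3, 1e-4`) and keeps the states whose
stationary probability stays above a threshold (default `1e-3`)
throughout; class masses at the smallest `epsilon` are reported as the
limit probabilities.  Reported masses always record their `epsilon`.
Two practical notes:

* In sharply selected regimes (for instance large `r`, small `sigma`,
  where the all-defector state dominates) the mass concentrates slowly;
  transition-ridge states can stay above the threshold until
  `epsilon <= 1e-5`.  The schedule is an explicit argument so such runs
  can push lower.
* If the surviving mass fails to grow monotonically along the schedule a
  warning is issued and the smallest-`epsilon` result returned.

The interesting aggregate is the mass on four state classes: `AllD`
(`(0, M, 0, 0)`), `AllL` (the three states payoff-equivalent to an
all-loner population: `(0, 0, M, 0)`, `(0, 1, M - 1, 0)`,
`(0, 0, M - 1, 1)`), `CplusE` (all `(i, 0, 0, M - i)` compositions of
cooperators and excluders — the cooperative class), and `Other`.
`coop_probability_difference()` reports the asynchronous-minus-synchronous
`CplusE` mass: the probability gain of sequential exclusion.

The well-mixed defaults mirror the study conditions: `M = 20`, `N = 5`,
`kappa = 1`, `sigma = 0.1`, reporting `epsilon = 1e-3`.

## Structured populations: lattice Monte Carlo

`run_simulation()` places the four strategies uniformly at random on an
`L x L` square lattice (default 100) with periodic boundaries.  Every cell
plays a five-member game in each of the five von Neumann groups it belongs
to, accumulating payoff over those five games; loners collect `sigma` per
game.  One Monte Carlo step is `L^2` elementary updates; an update picks a
random cell `i` and a random neighbour `j`, evaluates both cumulative
payoffs, and lets `j` adopt `i`'s strategy with the Fermi probability
`1 / (1 + exp((pi_j - pi_i) / tau))`, `tau = 0.1` by default.  Runs last
10,000 steps by default and report frequencies averaged over the final
1,000; sweeps average 20 independent replicates.  Replicate seeds derive
from the master seed as `seed + 7919 (replicate - 1)` and are logged with
the results.

Group games realize exclusion stochastically at every payoff evaluation
(`payoff_mode = "stochastic"`, the canonical mode): each synchronous
excluder attempts, and pays for, every defector in the group; asynchronous
excluders are freshly ordered at random per group and stop paying for
expelled defectors.  The two players of an imitation event draw
independent realizations.  An `"expected"` mode replaces exclusion
outcomes by their exact means (binomial survival sums, `cR` costs) for
variance-reduction studies; it is not the canonical protocol.  The
realized costs are tested against the analytic expectations: synchronous
costs equal `cE` per defector exactly, and mean sequential costs match
`cR` to Monte Carlo error.

The update scheme is asynchronous random sequential updating — the only
scheme consistent with repeatedly selecting a random individual — and a
fixed round budget is used rather than a convergence test, with an
optional early-stop left off by default so trajectories remain strictly
reproducible from their seed.

## Parameter sweeps and problem sizes

`wellmixed_sweep()`, `lattice_sweep()`, `max_probability_difference()`,
`detect_peak()` and `emergence_interval()` drive the result surfaces: class
masses over `(r, sigma)` grids, frequency-versus-`r` curves, the maximal
cooperative-probability gain, defector peak locations, and the contiguous
`r` interval where defection persists (mean frequency above 0.05 by
default).  Peak ties break towards the smaller parameter value; monotone
series return their endpoint with a warning.

Default grids are `r` in `[1.5, 4.5]` in steps of 0.2 and `sigma` in
`[0, 1]` in steps of 0.1 for the grid surfaces; all grids are arguments.
The package's own verification runs use deliberately reduced sizes chosen
to keep the full suite re-runnable on a single CPU in well under half an
hour: lattice sweeps on `L = 50` with 5,000 rounds, a 500-round window and
5 replicates; the well-mixed grids at the sizes above.  The full-size
protocol (`L = 100`, 10,000+ rounds, 20 replicates) is available by
passing the corresponding parameters.

## What the scaled runs do and do not show

Sampling the generator's own defaults reproduces, and the tests assert,
the model's qualitative structure:

* the cooperative transition happens at smaller `r` under asynchronous
  than synchronous exclusion, on both dynamics;
* defectors persist only on an interior `r` interval on the lattice, with
  the weak-exclusion (`beta = 0.1`) defector peak at `r = 3.5`;
* below the interval the population fixes on loners, above it on
  cooperator-excluder mixtures;
* the well-mixed cooperative-probability gain of asynchronous exclusion
  stays near or below 0.1 whenever `beta <= 0.3` (its grid maximum there
  computes to about 0.11 at `beta = 0.3`, against gains of about 0.3 at
  `beta = 0.8`) and grows with `beta`, with its maximum at small `r` and
  small `sigma`.

Two caveats matter when extrapolating from the reduced sizes.  First,
the defector coexistence phase at strong exclusion (`beta = 0.8`) lives on
cyclic dominance (E displaces D, D exploits C, C/E drift neutrally, L
invades D), and cyclic coexistence is fragile on small lattices: on
`L = 50` grids most replicates collapse to a single absorbing phase within
a few thousand rounds, so window-averaged defector frequencies there
underestimate the coexistence amplitudes seen on `L = 100` grids, where
the same parameter points sustain mixed C + D + L states.  Quantitative
peak heights in that regime should therefore be read from full-size runs.
Second, the stochastic payoff mode means two evaluations of the same cell
differ; this is the intended model of noisy exclusion, but it adds
evaluation noise on top of the Fermi noise, and regime boundaries can
shift by a few tenths in `r` relative to accountings that share one
exclusion realization per round.

## Numerical choices

* Hypergeometric/binomial weights in log space; weights at impossible
  compositions are exactly zero (`lchoose0` guards the support, avoiding
  R's analytic continuation of `choose` at negative arguments).
* `cR(beta = 0)` is the continuous limit `cE`; the formula as printed is
  0/0 there.
* Stationary solves: reduced sparse LU, residual tolerance 1e-10;
  fallbacks as above.
* States are ordered lexicographically by `(X, Y, Z)` with `W` implied;
  every state-indexed output uses this order.
* Lattice RNG: R's generator, one seeded stream per replicate, so every
  trajectory is bit-for-bit reproducible from the master seed.
* Degenerate groups: a pot with no contributors pays zero; a group with at
  most one participant pays that participant `sigma`, inheriting the
  well-mixed all-loner rule.

## Limitations

* Only square lattices with von Neumann neighbourhoods; heterogeneous
  networks are out of scope.
* Stochastic stability is operational (small fixed `epsilon`), not an
  exact vanishing-perturbation computation.
* The nested payoff sums are evaluated as written; no closed-form
  simplification or infinite-population replicator limit is provided.
* Single-process execution; the compiled lattice kernel is serial.
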
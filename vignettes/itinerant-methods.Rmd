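---
title: "Attractor itinerancy in bistable rate networks with synaptic depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor itinerancy in bistable rate networks with synaptic depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itinerant)
library(dplyr)
```

## The model

`itinerant` simulates networks of N neural populations, each described by a
normalized mean firing rate $r_i \in [0,1]$, a synaptic activation
$s_i \in [0,1]$, and a short-term depression factor $d_i \in [0,1]$
($d_i = 0$ is a fully depressed synapse).  In dimensionless form — time in
units of the rate time constant $\tau_r$, inputs scaled by the input-output
slope — the dynamics are

$$
\dot r_i = -r_i + f\Big(\textstyle\sum_j w_{ij} s_j - \theta_i + I_i(t)\Big),
\qquad
\dot s_i = \alpha\big(-s_i + b\, r_i d_i (1 - s_i)\big),
\qquad
\dot d_i = \beta\big(1 - d_i - a\, r_i d_i\big),
$$

with the logistic transfer $f(x) = (1+e^{-x})^{-1}$.  The parameters and
their defaults (`dim_params()`):

| parameter | meaning | default | origin |
|---|---|---|---|
| `a` | depression strength $p_0 r^{\max}\tau_d$ | 6.25 | $\tau_d = 250$ ms, $p_0 = 0.5$, $r^{\max} = 50$ Hz |
| `b` | synaptic amplitude $\rho p_0 r^{\max}\tau_s$ | 1.25 | $\tau_s = 50$ ms, $\rho = 1$ |
| `alpha` | $\tau_r/\tau_s$ | 0.2 | $\tau_r = 10$ ms |
| `beta` | $\tau_r/\tau_d$ | 0.04 | |
| `theta` | activation threshold | 5 | |
| `w_self` | self-coupling $w_{ii}$ | 40 | strong enough for bistability |

Only the dimensionless combinations are identifiable; $r^{\max}$ and the
slope scale $\Delta$ never appear separately in any analysis, so
`nondimensionalize()` is provided for completeness but all computations run
in dimensionless form.  $\rho = 1$ is forced by `b = 1.25` given the other
constants.  The slow-depression regime of interest has $a > b$ and
$\beta < \alpha$ (`is_slow_depression()`).

The no-depression control is implemented as $a = 0$ with $d$ pinned at 1
(equivalently $\tau_d \to 0$), not as $\beta \to \infty$, which would make
the system needlessly stiff.  With depression disabled the state space is
$(r, s)$ only; Jacobians shrink accordingly.

At a steady rate the synapse and depression variables take the closed forms
$s(r) = br/(1 + (a+b)r)$ and $d(r) = 1/(1+ar)$, so fixed points satisfy the
N-dimensional system $g(r_i) = \sum_j w_{ij}\, s(r_j) + I_i - \theta_i$ with
$g = f^{-1}$ the logit.

## Fixed-point enumeration and classification

`find_fixed_points()` solves the fixed-point system by damped Newton
iteration **in logit coordinates** $x_i = g(r_i)$.  This choice matters:
without depression the active state of a strongly self-excited unit sits at
$r \approx 1 - 3\times 10^{-8}$, hopeless for a solver working in $r$, but
at a comfortable $x \approx 17$ in logit space.  Newton starts are all
$3^N$ combinations of each unit's isolated single-unit roots, which
enumerates the complete catalog when cross-couplings are weak (the regime
of interest); above `max_seeds` combinations, a seeded random subset with
logit-space jitter is used, so catalogs of strongly coupled networks are
sampled rather than exhaustive.  Any attractor discovered later by settling
(during frequency estimation or a stimulus train) is polished by Newton and
appended to the catalog with a message, so downstream statistics do not
depend on the initial enumeration being complete.

Stability comes from the blocked Jacobian at a root, whose per-unit
$3\times 3$ blocks couple across units only through the
$w_{ij}\, r_i(1-r_i)$ rate-synapse entry (`fp_jacobian()`).  A fixed point
is a saddle of degree $k$ when $k$ eigenvalues have positive real part;
imaginary parts (spiral approach) do not affect stability.  Real parts
within `1e-8` of zero are flagged marginal and never counted stable.  The
package also provides `rhs_jacobian()`, the exact Jacobian of the flow at
*any* state; at a fixed point the two coincide, and the test suite verifies
both against central finite differences.  For N uncoupled bistable units
the catalog reproduces the combinatorial law $n_k = \binom{N}{k} 2^{N-k}$,
$\sum_k n_k = 3^N$, which the tests assert for $N \le 3$.

## Settling, matching, and the slow spiral at the active state

Much of the package reduces to one primitive: relax the network and decide
which attractor it reached.  A numerical fact shapes all the defaults here.
At the standard parameters the active (ON) fixed point of a single unit has
a complex eigenvalue pair with real part $\approx -0.012$: trajectories
approach it as a very slow spiral, and the max-norm of the right-hand side
decays by only $e^{-12}$ per 1000 time units.  Demanding a residual of
$10^{-9}$ within 1000 time units — superficially a natural choice — would
therefore label almost every run that ends in an ON state "unsettled".  The
package instead uses:

* `settle_tol = 1e-6` on the max-norm of the right-hand side, detected by
  the solver's root-finding (`lsodar`) so integration stops at the crossing;
* `max_settle_time = 2000` as the default cutoff;
* `match_tol = 1e-3` (max-norm on $r$) for assigning a settled state to a
  catalog entry — at residual $10^{-6}$ the distance to the fixed point
  along the slow mode is at most $\sim 10^{-4}$, comfortably inside it.

A dedicated robustness test integrates a battery of one- and two-unit cases
at the default and at tenfold tighter integrator tolerances and asserts the
binarized outcomes never change.

Stimulus discontinuities are never stepped across: `simulate_network()`
splits the integration exactly at every pulse onset and offset (windows are
half-open $[t_0, t_0 + \tau_{dur})$).  States are clipped to $[0,1]$ only
in reported tables, never inside the integration loop.

Grid experiments (basin maps, response maps, frequency estimation) stack
many independent copies of the network into one block ODE system and
integrate them together with the explicit Adams method, pruning converged
rows chunk by chunk.  The stacked system is non-stiff (all local rates are
$O(1)$ or slower), and avoiding the implicit path matters because a stiff
solver would factor a dense Jacobian across all stacked states.  This is a
performance choice only; per-trajectory results are identical to
single-network integration within integrator tolerance.

## Basins, response maps, and itinerancy statistics

**Basin maps** (`map_basins()`, N = 2) assign each point of a regular grid
over the $(r_1, r_2)$ rate plane to the attractor reached after lifting the
synapse and depression variables to their conditional steady values
$s(r), d(r)$ — the single biggest convention in the module, since a grid
point underdetermines the full state.  The default resolution is 101×101;
areas are normalized over labeled cells, and a doubling-stability test
bounds discretization error at 2% in the regular-basin (no-depression)
cases.  Connectivity of basins is assessed with 8-neighbor adjacency so
that diagonal bands count as one region.

**Response maps** scan pulse duration × amplitude.  The single-pulse map
records the final binarized pattern from a fixed initial attractor; the
two-pulse map counts binarized changes across the settled states (initial,
after pulse 1, after pulse 2).  Cells with 2 changes mark maximal history
dependence: the same stimulus switches the unit ON from OFF and then OFF
from ON.  With depression disabled this category is empty — the negative
control asserted by the acceptance suite.  At the standard parameters the
repeated-switching region for 60-unit pulses is a narrow amplitude band
near $I_{app} \approx 0.84$ (width below 0.04), so the acceptance check
locates the band by scanning amplitudes at 0.01 steps before running the
exact two-pulse protocol inside it.

**Reachable states** (`count_reachable_states()`) start every run from the
same settled attractor (default pattern `01001` in five-unit circuits) and
count distinct settled binary patterns over the grid; unsettled cells are
excluded and reported.

**Stimulus trains** (`run_train()`) repeatedly apply one pulse and relax
for the inter-stimulus interval $\tau_{isi} = 1000$.  Settled states are
matched to the catalog; since the settled-to-settled map is deterministic,
the visited sequence is eventually periodic and the record closes at the
first repeated index, reporting the cycle.  The sequence length $\ell$
counts **distinct states including the initial one** — the convention is
stated explicitly because the off-by-one alternative is equally natural.
`sequence_stats()` aggregates $\langle\ell\rangle$ (mean over starting
attractors) and $\ell_{\max}$ per network over a seeded ensemble.  For
strongly coupled ensembles the per-network catalog is first augmented by
settling random initial conditions (`n_freq_samples`), which in practice
discovers far more stable states than Newton seeding alone; when the
stable count exceeds `max_starts`, the most frequently occurring attractors
are used as starts.  Targeted subsets (`target_fraction`) are drawn once
per network and reused for every pulse; exponential amplitude protocols
redraw per pulse and per targeted unit from the configured mean.

## What the generators emulate, and what they do not

`random_network()` draws cross-couplings i.i.d. Gaussian (mean `mu`, spread
`sigma`, optionally $\sigma = N^{-1/2}$ for size scaling) and overwrites the
diagonal with `w_self`, treating self- and cross-coupling as separate
parameters; draws are untruncated and moments refer to off-diagonal entries
only.  The study conditions used throughout the tests are the ones the
analyses define: weakly coupled five-unit circuits
($\mu = 0$, $\sigma = 0.1$), strongly coupled ten-unit circuits
($\mu = -0.2$, $\sigma = 1$) under trains with $\tau_{dur} = 20$, and the
$\sigma = N^{-1/2}$ scaling family.  These ensembles are statistical
stand-ins: the specific random matrices behind published example figures
are not recoverable, so ensemble-level *orderings* (depression lengthens
sequences; depression enlarges the reachable repertoire) are the tested
claims, not exact curve values.  Synthetic networks here have no sparse
topology, no sign-constrained (Dale's law) columns, and identical unit
parameters — passing tests say nothing about those features of biological
circuits.

Long transients are probed by `settling_fraction()`: random initial rate
vectors are relaxed for at most 500 time units (five seconds at
$\tau_r = 10$ ms) and counted unsettled if the right-hand side max-norm
still exceeds `1e-3`.  That looser threshold is deliberate: the question is
whether the trajectory is still wandering between states, not whether the
linear tail of the slow spiral has decayed; a threshold tied to
`settle_tol` would label essentially every run unsettled at every size and
erase the size dependence the diagnostic exists to show.  With
$\sigma = 0.1$ the unsettled fraction grows markedly from N = 5 to N = 20,
the scaled-down signature of the transient-dominated large-N regime (the
full N = 100 regime is out of scope).

## Problem sizes and runtime

The test and acceptance workloads are sized for a single CPU: ensembles of
20 networks, trains of 12 pulses capped at 8 starting attractors with 120
settling samples per catalog, response-map grids of 51×41, basin grids of
61×61, and 100 initial conditions per settling-fraction point.  All
randomness flows from explicit integer seeds (per-network substreams are
`seed + index`), so every table in the package reproduces bit-for-bit.

## Known limitations

* Catalog completeness is guaranteed only in the weak-coupling regime where
  single-unit root combinations enumerate all seeds; elsewhere the catalog
  is a (well-behaved, self-extending) sample, and rare attractors with tiny
  basins can be missed.
* Basin geometry is computed for N = 2 only; for larger N, occurrence
  frequencies under uniform sampling stand in for basin volumes.
* The model is deterministic: noise-driven transitions, facilitation, and
  adaptation currents are not modeled.
* `run_train()` flags, but does not exclude, pulses whose inter-stimulus
  relaxation did not reach the settling tolerance; in strongly coupled
  ten-unit circuits with depression this is common and reflects genuinely
  long transients, so sequence statistics there should be read as counts of
  distinct visited rate vectors rather than of certified fixed points.
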
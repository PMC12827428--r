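---
title: "Connectivity indices and metapopulation persistence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity indices and metapopulation persistence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverdci)
```

## The question the package answers

The Dendritic Connectivity Index summarizes a fragmented river network in
one number built only from reach lengths and barrier passabilities. It is
widely used to rank watersheds and to prioritize barrier removal, but it
is a purely structural quantity. `riverdci` pairs it with a mechanistic
patch-occupancy model on the *same* network so that, over ensembles of
randomized networks, the rank agreement between index and demography can
be measured rather than assumed.

## Network representation

A network is a rooted metric tree: reach 1 is the river mouth, ids are
breadth-first from the mouth, and the edge from reach *k* to its parent
carries barrier *b\_k* with passabilities `alpha_up`, `alpha_down` in
(0, 1]. Fully impassable barriers are excluded by construction — a reach
behind one is simply not part of the accessible network — which keeps the
tree connected and makes the linearized dynamics irreducible, so
Perron–Frobenius structure (a real dominant eigenvalue with positive
eigenvectors) is guaranteed rather than hoped for.

Lengths are *quality-adjusted* habitat lengths: any habitat-quality
weighting is assumed to have been folded into `l_i` before the network is
built. Because both indices and all relative metrics depend only on
ratios, the maximal length is normalized to one.

## The patch-occupancy model

Occupancy probabilities evolve as
`dp_i/dt = C_i(p)(1 - p_i) - E_i p_i` with extinction
`E_i = e / l_i^omega` and colonization
`C_i(p) = c l_i^gamma sum_j l_j^epsilon exp(-d_ij / D) cdir_ij p_j`.
Assumptions worth making explicit:

* **Directionality.** The dynamics use the *directed* cumulative
  passability `cdir` (downstream passability while a disperser descends,
  upstream while it ascends). The DCI uses the undirected product. This is
  exactly the wedge that lets the experiments separate what the index can
  and cannot see: two networks with identical per-barrier products are
  indistinguishable to the DCI but not to the model.
* **Distance decay.** Colonization pressure decays as `exp(-d_ij / D)`
  with `d_ij` the along-channel distance between reach midpoints.
* **No local dynamics.** Reaches are occupied or empty; abundance,
  Allee effects and within-reach structure are out of scope.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `c` | colonization strength (1/time) | 10 | fixes `c/e = 10`, the classic incidence-function regime; long-term outcomes depend only on the ratio |
| `e` | extinction parameter (1/time) | 1 | time-scale anchor |
| `omega` | length–extinction exponent, [0, 1] | 1 | linear habitat–extinction reduction, the reduction in which the model collapses to the classic terrestrial one |
| `gamma` | length–attractiveness exponent | 0 | colonization independent of recipient length in the default reduction |
| `epsilon` | length–productivity exponent | 1 | colonizer output proportional to source habitat |
| `D` | mean dispersal distance | per scenario | `L` (global) or `L/N` (local) |

The published exponent table behind the original figures is in an
unavailable supplement; the defaults above are the reduction the model
text itself singles out, and all exponents are arguments, not constants.

### Persistence metrics

From the linearization `J = B - diag(E)` at the empty state:
growth rate `lambda` (dominant eigenvalue), reproductive values `v`
(left Perron eigenvector, normalized to unit sum of squares), and the
basic reproduction number `R` as the spectral radius of the
next-generation matrix `K_ij = B_ij / E_j`. The verbal definition of `R`
— occupied reaches produced by one occupied reach over its lifetime —
pins this formula down: colonization pressure `B_ij` times mean occupied
lifetime `1/E_j`. It also yields the threshold identity
`sign(lambda) = sign(R - 1)`, which the suite verifies on hundreds of
random networks.

All metrics are reported relative to the *barrier-free baseline*: the
identical topology and lengths with every passability set to 1. That is
the only baseline under which `DCIp = 100` and every relative metric
equals 1 simultaneously on an unfragmented network. `G_s = exp(lambda -
lambda_0)` does depend on the overall time scale (jointly rescaling
`c` and `e` by `k` raises `G_s` to the power `k`), unlike `R_s` and
`P_s`; since all downstream analyses are rank correlations and `x ->
x^k` is strictly increasing, every correlation is invariant to the time
scale. The suite tests this rank invariance explicitly rather than
claiming value invariance.

## The synthetic-data generator: a stated world

The generator emulates a specific, deliberately stylized ensemble:

* **Topologies**: linear chains and full binary trees, the two limiting
  cases of dendritic branching. For sizes that are not `2^k - 1` the
  complete binary tree filled left-to-right in breadth-first order is
  used — the unique choice consistent with breadth-first labeling that
  reproduces the textbook 7-reach tree.
* **Lengths**: uniform on (0.5, 1) — half the maximal length to the
  maximal length — avoiding degenerate, near-zero reaches.
* **Passabilities**: uniform on (0, 1) via Latin hypercube sampling with
  60 design points per scenario cell, one row per replicate, jointly over
  all `2N - 1` attribute dimensions. Whether the original study used one
  joint design or separate ones for lengths and passabilities is not
  stated; the joint design was chosen because the symmetric and
  asymmetric scenarios must be paired draw-for-draw, and a single design
  shared between them achieves that with no further bookkeeping.
* **Pairing**: the asymmetric scenario sets `alpha_down = 1` and
  `alpha_up = a*a` from the same base draw `a` as the symmetric scenario,
  so the per-barrier product — and hence every undirected quantity and
  both DCIs — is *bit-identical* between the paired cells (see numerical
  choices below). A barrier between every pair of adjacent reaches, with
  passabilities drawn independently; spatially correlated passabilities
  are deliberately not modelled.
* **Seeds**: one master seed; each scenario cell derives a sub-seed from
  (seed, topology, size) only, so passability and dispersal modes share
  draws and every run is byte-reproducible.

What a green test on this world does *not* establish: anything about
realistic topologies (optimal channel networks, comb networks, real
basins), correlated or empirically calibrated passabilities, anadromous
life cycles, or abundance dynamics. The generator is the experiment's
stated world, not a river simulator.

## Numerical choices

* **Pairwise structure** is computed by one tree traversal per source
  reach, multiplying passability factors outward in traversal order
  (O(N^2 · depth), trivial at N ≤ 50). Multiplying raw factors instead of
  accumulating logs keeps the paired symmetric/asymmetric scenarios
  bit-identical on all undirected quantities, which the exact pairing
  check requires; products of at most N-1 factors in (0, 1] cannot
  overflow and only underflow in regimes that are numerically zero anyway.
* **Distance convention**: `d_ij` runs midpoint to midpoint
  (`l_i/2 + intermediate lengths + l_j/2`). The convention (midpoints vs
  endpoints vs confluences) is not fixed by the index literature; the
  midpoint rule is the symmetric choice with a zero diagonal and is used
  throughout.
* **Eigen-computations** use dense solvers (`eigen`) — the networks are
  small; the dominant eigenvalue is selected by maximal real part, and
  the left eigenvector's sign is fixed to the positive Perron direction
  with negative numerical dust clipped at zero.
* **Steady state**: monotone fixed-point iteration of
  `p <- C(p) / (C(p) + E)` from `p = 1` (the map is monotone from above,
  so it cannot oscillate), followed by a Newton polish on the residual
  `C(p)(1 - p) - E p`. Plain iteration alone slows down critically near
  the persistence threshold; Newton from the warm start restores
  quadratic convergence there. Residuals are driven below 1e-12 and a
  replicate errors out (and is flagged, not dropped) above 1e-8.
* **Dynamics integration** uses fixed-step classical RK4 with the step
  set from the fastest per-reach rate; the system is small, smooth and
  non-stiff at the rates the ensembles produce. It exists to validate
  the analytic steady state, not for production use.
* **Undefined correlations** (constant columns, e.g. all-passable smoke
  runs) are reported as `NA` flags, never coerced to 0.
* **Barrier-removal ratios** are oriented removed / in-place, so both
  ratios are ≥ 1 and "bigger = higher removal priority"; the reciprocal
  orientation used elsewhere in the literature is a strictly monotone
  transform, so Spearman results are unaffected.

## Scale of the shipped checks

The full default sweep (2 topologies × 2 passability modes × 2 dispersal
modes × sizes {3, 5, 7, 10, 15, 20, 30, 40, 50} × 60 replicates,
including the per-barrier removal analysis) runs in well under 15 minutes
on one CPU via `run_sweep(default_sweep_config())`. The shipped test
suite exercises the same code paths on an axis-complete but size-reduced
sweep (sizes {3, 7, 15}, 60 replicates, run twice for byte-identity) so
the whole suite stays fast; this is a scale reduction, not a change of
the stated world.

## Known limitations

* Only potamodromous movement; anadromous index variants are out of
  scope.
* Two topology classes; no intermediate or empirically derived networks.
* Independent barrier passabilities; no spatial correlation.
* Patch-occupancy only: no abundance, genetics, or individual behaviour.
* `G_s` values (not ranks) depend on the time-scale convention; compare
  ranks across studies, not raw values.
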
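# riverdci

Structural connectivity indices are the workhorses of river restoration
planning: they are cheap to compute from a barrier inventory, but they only
describe network *structure*. Whether they actually track the quantity
conservation cares about — can a fish population **persist** on this
fragmented network? — is a population-dynamics question. `riverdci`
implements both sides of that comparison and the simulation machinery to
correlate them, for potamodromous fish (species that complete their life
cycle entirely in fresh water) on dendritic river networks.

It is aimed at landscape ecologists and quantitative conservation
planners who want to compute the Dendritic Connectivity Index (DCI) on
tree-structured river networks, attach a barrier-aware metapopulation
model to the same network, and ask how well the former predicts the
latter — including which barrier to remove first.

## The model

A river network with `N` reaches is a rooted metric tree: the mouth is the
root (reach 1, breadth-first numbering), each reach `i` has a
quality-adjusted length `l_i`, and the edge from reach `k` to its parent
carries barrier `b_k` with upstream/downstream passabilities
`α_u, α_d ∈ (0, 1]`.

**Structure.** With `c_ij = Π_m α_u,m α_d,m` the product over barriers on
the unique path between reaches `i` and `j`, and `L = Σ l_i`:

    DCIp    = Σ_i Σ_j c_ij (l_i/L)(l_j/L) × 100
    DCIs(j) = Σ_i c_ij (l_i/L) × 100

`DCIp` is 100 exactly when every barrier is fully passable, and it is the
length-weighted average of the per-reach `DCIs`.

**Dynamics.** A patch-occupancy model tracks the probability `p_i(t)` that
reach `i` is occupied:

    dp_i/dt = C_i(p) (1 − p_i) − E_i p_i
    E_i     = e / l_i^ω
    C_i(p)  = c l_i^γ Σ_{j≠i} l_j^ε exp(−d_ij/D) c̃_ij p_j

where `d_ij` is the swim distance between reach midpoints, `D` the mean
dispersal distance, and `c̃_ij` the *directed* cumulative passability
(using `α_d` on downstream steps, `α_u` on upstream steps — which is how
the dynamics see barrier asymmetry that the DCI cannot). From the
linearization at the empty network come the metapopulation growth rate `λ`
(dominant Jacobian eigenvalue; persistence iff `λ > 0`), the basic
reproduction number `R` (spectral radius of the next-generation matrix
`B_ij/E_j`; persistence iff `R > 1`), reach reproductive values `v_i`
(left Perron eigenvector), and the positive steady state `p*`. All
metrics are reported relative to the same network with every barrier
removed: `G_s = e^{λ−λ₀}`, `R_s = R/R₀`, `P_s = p̄/p̄₀`, and per reach
`O_s(i) = p_i*/p_i0*`, `V_s(i) = v_i/v_i0`.

## Worked example

A 7-reach dendritic network with six barriers ships with the package:

```r
library(riverdci)
net <- read_network(system.file("extdata", "fig1_binary.csv", package = "riverdci"))

dci_p(net)
#> [1] 31.26446

params <- species_params(D = dispersal_distance(net, "global"))  # c/e = 10
m <- relative_metrics(net, params)
c(R = m$R, R_0 = m$R_0, R_s = m$R_s, P_s = m$P_s)
#>          R        R_0        R_s        P_s
#> 11.9561683 27.6304917  0.4327164  0.9353112
```

Barriers have cut this network's connectivity index to 31 out of 100 and
its reproduction number to 43% of the barrier-free value, while the mean
steady-state occupancy only drops to 94% — low-density persistence metrics
react to fragmentation much more strongly than the saturated equilibrium.
Which barrier should be removed first?

```r
t(sapply(2:7, function(k) removal_ratios(net, params, k)))
#>    rho_dci  rho_R
#> b2  1.4033 1.3841
#> b3  1.2053 1.2097
#> b4  1.1700 1.1130
#> b5  1.0385 1.0285
#> b6  1.3368 1.3323
#> b7  1.0661 1.0455
```

Removing barrier `b2` raises `DCIp` by 40% and `R` by 38% — the structural
index and the demographic metric agree on the priority ranking
(b2, b6, b3, …). Across a 60-replicate Latin-hypercube ensemble the
agreement is systematic:

```r
cfg <- scenario_config("binary", "symmetric", "global",
                       n_reaches = 7, n_replicates = 60, seed = 1)
tab <- run_scenario(cfg)
network_scale_correlations(tab)
#>  topology passability_mode dispersal_mode n_reaches metric       rho  n
#>    binary        symmetric         global         7    G_s 0.9158655 60
#>    binary        symmetric         global         7    R_s 0.9627674 60
#>    binary        symmetric         global         7    P_s 0.7300361 60
```

Spearman rank correlations between `DCIp` and the growth and reproduction
metrics exceed 0.9 in this (dendritic, symmetric, global-dispersal)
scenario; the density-dependent occupancy metric correlates less tightly,
as expected for an index that knows nothing about population interactions.
`run_sweep(default_sweep_config())` runs the full 2×2×2 scenario grid over
sizes 3–50 and `write_results()` emits tidy CSVs; a thin CLI over the same
functions is installed at `inst/cli/riverdci` (subcommands `generate`,
`dci`, `metrics`, `sweep`, `sensitivity`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from a fresh seeded network, the analytic anchor value of the
index machinery — the network-scale DCI of a fully passable dendritic
network — and writes it as JSON.

## Vignette

`vignettes/dci-metapopulation.Rmd` documents the model, the generator's
stated world (what it emulates and what it does not), the numerical
choices, and known limitations.
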
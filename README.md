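# metacrit

Stochastic metacommunity dynamics at the edge of extinction.

`metacrit` is for theoretical and spatial ecologists studying how dispersal
maintains biodiversity when many species compete weakly and local
populations are small enough that demographic noise dominates. It
implements a spatially explicit stochastic Lotka–Volterra metacommunity —
`S` species on `P` patches coupled by nearest-neighbour (1D ring) or global
dispersal — together with the analytical and statistical machinery needed
to study its extinction behaviour.

## The model

On each patch `x`, the abundance of species `i` follows

    dN_xi/dt = r N_xi (1 - (α/K) Σ_{j≠i} N_xj - N_xi/K)
               + Σ_y λ_{y,x} (N_yi - N_xi) + sqrt(N_xi) η ,

with growth rate `r`, carrying capacity `K`, relative interspecies
competition `α` (weak competition: `0 < α ≪ 1`), dispersal rate `λ`, and
demographic noise of variance proportional to abundance. The integrator
advances the deterministic drift by Euler substeps and redraws every
abundance from a Poisson distribution once per generation, which gives
integer abundances, an exactly absorbing all-extinct state, and noise
variance `N` per generation (amplitude ω = 1).

Three results are packaged as reusable analyses:

* **Dispersal threshold** — below a critical dispersal rate `λ_c` every
  species eventually dies out; `λ_c` is independent of `S` and `α`
  (`sweep_lambda()`, and analytically `critical_dispersal()` with the
  small-dispersal asymptote `λ_c ≈ e^{-Kr} sqrt(r/(4πK))`).
* **Self-organization to the extinction threshold** — the patch-averaged
  effective growth factor `g_eff(i)`, where
  `g_eff(x,i) = 1 - (α/K) Σ_{j≠i} N_xj`, is pushed for every species, as
  `S` grows, toward the critical growth factor `g_c` of the decoupled
  single-species lattice dynamics
  (`simulate_single_species()`, `estimate_gc()`).
* **Directed-percolation patterns** — near `g_c`, the lengths of contiguous
  extinct regions and the times from local extinction to recolonization
  are power-law distributed with the (1+1)D directed-percolation exponent
  magnitudes 1.747 and 1.840 (`extinction_run_lengths()`,
  `recolonization_times()`, `fit_power_law()`).

For global dispersal a self-consistent mean-field theory gives the species
abundance distribution `P(N) ∝ N^{2λN̄-1} exp{-Kr[(g_eff - λ/r) - N/K]²}`
in closed form up to one scalar self-consistency condition
(`abundance_density()`, `solve_self_consistent()`), interpolating between a
Fisher log-series at weak dispersal and a Gaussian bulk at strong growth.

## Worked example

Simulate a 20-species metacommunity above the dispersal threshold, then ask
where its effective growth factors ended up relative to the single-species
critical point:

```r
library(metacrit)

p <- model_params(r = 0.3, K = 10, alpha = 0.1, lambda = 0.4, S = 20, P = 200)
sim <- simulate_metacommunity(p, t_max = 2000, record_every = 10, seed = 1)
sim
#> <metacomm_sim> S = 20, P = 200, topology = nearest_neighbor_1d
#>   201 samples over 2000 generations; final mean abundance 2.738, 20 extant species

glance(sim)
#> # A tibble: 1 × 5
#>   t_final mean_abundance mean_geff n_extant_species globally_extinct
#>     <dbl>          <dbl>     <dbl>            <int> <lgl>
#> 1    2000           2.74     0.480               20 FALSE

estimate_gc(lambda = 0.4, P = 100, t_max = 2000, n_rep = 8, tol = 0.02, seed = 2)
#> <gc_estimate> g_c = 0.4234 (bracket [0.4094, 0.4375]) at lambda = 0.4
#>   protocol: P = 100, t_max = 2000 generations, 8 replicates per g
```

All 20 species persist, but their mean effective growth factor has dropped
from 1 (no suppression) to 0.48 — just above the estimated critical growth
factor `g_c ≈ 0.42` at this dispersal rate: the community has packed itself
down to the edge of extinction. With `S = 5` the same protocol settles near
0.75, and with `S = 100` it approaches `g_c` itself.

The global-dispersal mean-field theory is one call:

```r
solve_self_consistent(lambda = 0.1, S = 5)
#> <meanfield_solution> nbar = 5.81916, geff = 0.767234 (lambda = 0.1, S = 5)
#>   residual 2.4e-15 (converged)
```

`tidy()`, `glance()` and `autoplot()` methods are provided for simulations,
mean-field solutions, critical-point estimates and power-law fits; a thin
command-line front end lives in `exec/metacommunity`
(`simulate | meanfield | dp | sweep | reproduce` subcommands), and
`reproduce_figure()` reruns each headline experiment at reduced scale.

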
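# golgisim

Exact stochastic simulation of a minimal self-organisation model of the
Golgi apparatus, with its mean-field analytics and transport observables.

## The scientific problem

The Golgi apparatus is a stack-free collection of membrane compartments
(cisternae) through which secretory cargo flows from the endoplasmic
reticulum (ER) to the trans-Golgi network (TGN). Whether vesicular
transport through it is anterograde (toward the exit) or retrograde
(recycling toward the entry) has been debated for decades. `golgisim`
implements a minimal, space-free model in which both the compartmental
structure and the direction of vesicle flux *emerge* from three local,
composition-dependent stochastic processes acting on membrane patches of
cis, medial or trans identity:

- **Homotypic fusion.** Two compartments with composition fractions
  φ(a), φ(b) fuse at rate `Kf Σᵢ φᵢ(a) φᵢ(b)` (Kf ≡ 1 after
  normalisation). The ER (a fraction `α_ER` of cis patches) and TGN
  (`α_TGN` of trans) obey the same rule; fusing with a boundary removes
  the compartment — the only exit route.
- **Budding.** Any compartment larger than a vesicle sheds pure, size-1
  vesicles; each identity present buds at rate `kb·n` (saturated
  Michaelis–Menten kinetics; a `kb·nᵢ` linear variant is available).
- **Biochemical conversion.** Every patch matures irreversibly
  cis → medial → trans at per-patch rate `km` (a Rab-cascade-like local
  identity switch).

New cis vesicles enter at rate `j`, calibrated from a target mean system
size `N` by the well-sorted mean-field inversion
`j = N (α_ER + km) α_TGN / (2 α_TGN + km)`. The three dimensionless
parameters `j`, `kb`, `km` (rates relative to fusion) fully determine the
dynamics, which the package simulates exactly with an event-driven
Gillespie algorithm (compiled core, incremental propensity bookkeeping).

The model produces three steady-state regimes as `kb` grows — mixed
(large, impure compartments), sorted (large *and* pure), vesicular (tiny,
pure) — and, in lockstep, a transition of the cargo flux from retrograde
through centripetal (toward medial) to anterograde. Observables shipped
with the package: compartment size distribution and typical size
⟨n²⟩/⟨n⟩, size-weighted system purity `P = sqrt(3/2 Σᵢ (φᵢ − 1/3)²)`
(vesicles excluded), steady-state fluctuations, the cargo enrichment
vector `E` (normalised mean composition difference between acceptor and
donor over transport events) with its directionality classification,
barycentric composition-simplex occupancy/flux maps, and pulse-chase exit
kinetics.

## Worked example

```r
library(golgisim)

p   <- golgi_params(kb = 1, km = 1, n_target = 300,
                    t_max = 100, t_burn = 20, seed = 1)
sim <- golgi_simulate(p)
sim
#> <golgi_sim>
#>   kb = 1, km = 1, j = 200, t_max = 100, seed = 1
#>   events: 145,149
#>   final state: 47 compartments, 222 patches, 0 cargo
#>   steady-state size: 293.1 +/- 51.0 (rel SD 17.4%) over t > 20
glance(sim)
#> # A tibble: 1 x 9
#>      kb    km     j  seed mean_size rel_sd_size typical_size system_purity
#>   <dbl> <dbl> <dbl> <int>     <dbl>       <dbl>        <dbl>         <dbl>
#> 1     1     1   200     1      293.       0.174         20.8         0.821
```

At `kb = km = 1` the system sits in the sorted regime: the calibrated
influx (j = 200) holds the mean size at ~293 of the 300-patch target,
compartments average ~21 patches, and purity 0.82 means compositions sit
much closer to the simplex vertices than to the mixed point. A
pulse-chase ensemble on the same parameters classifies the flux and fits
the exit kinetics:

```r
base <- golgi_params(kb = 1, km = 1, n_target = 300, t_max = 60, t_burn = 20,
                     cargo_mode = "pulse", cargo_time = 20)
run_pulse_chase(golgi_config(base, seeds = 1:20), pulse_size = 50)
#> <golgi_pulse>
#>   ensemble of 20 runs, exit rate 0.729 (R^2 = 0.992)
#>   enrichment E = (-0.50, 0.17, 0.33) -> anterograde
```

Cargo leaves exponentially (R² = 0.99) and vesicles, on average, land on
compartments richer in trans and poorer in cis identity than their donor:
anterograde transport. `autoplot(sim)` draws the species totals over
time; `autoplot(simplex_maps(sim$snapshots, sim$transport, t_burn = 20))`
draws the composition-triangle occupancy and flux-arrow map;
`run_sweep()` + `plot_phase_diagram()` produce desk-scale phase diagrams.

A thin command-line driver wraps the same functions:

```sh
inst/exec/golgi-sos run --kb 1 --km 1 --tmax 100 --tburn 20 --seed 1 --out out/
inst/exec/golgi-sos sweep --grid-points 5 --seeds 1,2,3 --out sweep/
```

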
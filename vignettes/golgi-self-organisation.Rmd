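---
title: "Methods: a minimal self-organisation model of Golgi compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal self-organisation model of Golgi compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgisim)
```

## The model

`golgisim` simulates an organelle as a well-mixed population of membrane
*compartments*. A compartment is an integer number of membrane patches of
three identities — cis, medial, trans — plus a count of passive cargo
labels. There is no space: any two compartments may interact, and the
structure that emerges (sizes, compositions, flux directionality) is
entirely a product of the kinetics. Five elementary events drive the
system:

1. **Injection.** A new pure cis vesicle (size 1) enters at constant rate
   `j`, representing ER output.
2. **Homotypic fusion.** Compartments `a` and `b` fuse at rate
   $\sum_i \phi_i(a)\,\phi_i(b)$, the probability that they present the
   same identity at the contact site, with the rate between identical
   compartments normalised to 1 (all times are in units of the inverse
   fusion rate, 1/Kf).
3. **Boundary fusion.** The ER (a fraction $\alpha_{ER}$ of cis patches)
   and the TGN ($\alpha_{TGN}$ of trans) follow the same law, so a
   compartment exits through the ER at rate $\alpha_{ER}\,\phi_{cis}$ and
   through the TGN at rate $\alpha_{TGN}\,\phi_{trans}$. Exit removes the
   compartment with all its patches and cargo.
4. **Budding.** Any compartment of size $n \ge 2$ emits pure single-patch
   vesicles. In the default *saturated* mode every identity present buds
   at rate $k_b\,n$ regardless of abundance (the saturated limit of
   Michaelis–Menten kinetics: coat proteins bind anywhere on the
   compartment and find their target patch by diffusion). The *linear*
   mode uses $k_b\,n_i$ instead. Each cargo in the donor joins the
   vesicle independently with probability $1/n$.
5. **Conversion.** Every patch matures irreversibly
   cis $\to$ medial $\to$ trans at per-patch rate $k_m$, identical for
   both steps. Free vesicles convert too, which matters at very high
   budding rates where vesicles can mature *before* they fuse.

The state is a continuous-time Markov jump process; `golgi_simulate()`
samples it exactly with the Gillespie algorithm: exponential waiting
times at the total propensity, one event per jump.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `kb` | budding / fusion rate ratio | 1 | dimensionless |
| `km` | conversion / fusion rate ratio | 1 | dimensionless |
| `n_target` | target mean total size | 300 | patches |
| `j` | ER influx (derived from `n_target` unless given) | 200 | vesicles per 1/Kf |
| `alpha_er`, `alpha_tgn` | boundary identity fractions | 1 | fraction |
| `t_max`, `t_burn` | horizon and burn-in | 100, 20 | 1/Kf |
| `sample_dt`, `snapshot_dt` | series / snapshot sampling intervals | 0.1, 1 | 1/Kf |

`n_target = 300` corresponds to a Golgi ministack of a few hundred
50-nm-scale vesicle equivalents. The influx calibration inverts the
well-sorted steady state,
$j = N(\alpha_{ER}+k_m)\,\alpha_{TGN}/(2\alpha_{TGN}+k_m)$
(`calibrate_influx()`); it is fixed at initialisation and never adjusted
during a run. `kb` and `km` are the axes of the phase diagram; sweeps
default to 9 log-spaced points spanning $10^{-2}$–$10^{2}$, a desk-scale
version of the published grids.

## Mean-field companions

Two asymptotic descriptions are implemented as closed forms and used both
for calibration and to validate the simulator:

- **Well-sorted limit** ($k_b \gg k_m$, compartments pure): linear
  balance ODEs for the species totals (`denovo_growth()`), their fixed
  point $N_{cis} = N_{medial} = j/(\alpha_{ER}+k_m)$,
  $N_{trans} = (k_m/\alpha_{TGN})\,N_{cis}$ (`steady_state_amounts()`),
  and the per-species compartment size $N/(1+k_b)$
  (`wellsorted_compartment_size()`).
- **Maturation-dominated regime** ($k_b \ll 1$): a compartment founded by
  one cis vesicle and growing from a uniform vesicle pool has
  age-dependent composition $\phi_{cis}=e^{-k_m t}$,
  $\phi_{medial}=k_m t\,e^{-k_m t}$,
  $\phi_{trans}=1-(1+k_m t)e^{-k_m t}$
  (`maturation_composition()`), independent of the pool size. The medial
  fraction peaks at exactly $1/e$ at age $1/k_m$ (`medial_maximum()`) —
  maturation alone never makes pure medial compartments.

The test-suite checks the simulator against both: species totals within
three standard errors of the fixed point over ten seeds at
$k_b=10, k_m=0.1$, and the low-`kb` simplex occupancy ridge against the
maturation trajectory.

## Observables

- **Typical size** is $\langle n^2\rangle / \langle n\rangle$ over all
  compartments, vesicles included, pooled over post-burn-in snapshots —
  the moment ratio puts it near half the exponential cut-off of the
  aggregation–fragmentation size distribution.
- **System purity** is the size-weighted mean of
  $P=\sqrt{\tfrac32\sum_i(\phi_i-\tfrac13)^2}$ over compartments of size
  $\ge 2$. The closed form is fixed by its three anchors ($P=0$ mixed,
  $P=\tfrac12$ two identities, $P=1$ pure); vesicles are excluded because
  they are pure by construction and would swamp the average. It is
  computed per snapshot and then averaged over time.
- **Enrichment vector.** Every cargo-carrying vesicle records its donor
  composition at budding and its acceptor composition immediately before
  fusion (compositions drift between the two via conversion). The
  enrichment $E_i$ is the mean of
  $\Delta\phi_i = \phi_i^{acceptor}-\phi_i^{donor}$, cargo-weighted by
  default (a vesicle carrying two cargo counts twice; event weighting is
  available via `weight = "event"`), normalised so
  $\sum_i |E_i| = 1$. Episodes ending on a boundary are excluded by
  default (`include_boundary`) — enrichment quantifies
  *inter-compartment* exchange — while back-fusion episodes are kept
  (they are genuine budding/fusion events; their $\Delta\phi \approx 0$
  merely dilutes the vector before normalisation). `directionality()`
  applies the sign rules: anterograde when $E_{cis}<0, E_{trans}>0$,
  retrograde when reversed, centripetal when $E_{medial}$ is the unique
  positive maximum.
- **Simplex maps** bin compositions on a regular barycentric grid
  (default 20 bins per edge; nearest-center assignment, ties resolved
  toward the lower bin index). Occupancy conserves the time-averaged
  totals by construction; flux arrows point from a donor bin to the
  cargo-weighted mean acceptor composition, excluding back fusion, with
  weights equal to cargo flux per unit time normalised by the mean cargo
  content.
- **Exit kinetics** fits $\log(\text{remaining cargo})$ against time by
  least squares on the ensemble mean of $\ge 20$ seeded pulses (noise in
  single small pulses makes individual fits unstable).

## Numerical choices

- The engine keeps class propensities incrementally through the
  aggregates $S_i=\sum_a\phi_i(a)$ and $Q_i=\sum_a\phi_i(a)^2$ (total
  pair-fusion propensity $\sum_i(S_i^2-Q_i)/2$), rebuilt from scratch
  every 65,536 events to bound floating-point drift; event selection
  within a class is one linear scan. The contract — sampled event
  probabilities equal those of a full $O(M^2)$ recomputation — is
  enforced by a frozen-state oracle test (10⁴ draws per state,
  chi-square on class frequencies, KS exponentiality of waiting times).
- The simulator uses its own `mt19937_64` stream seeded from the `seed`
  parameter, so identical seed and parameters give bitwise-identical
  trajectories regardless of the caller's R RNG state.
- Cargo are massless labels: they never alter a propensity, and several
  may ride one vesicle (independent $1/n$ draws).
- A freshly budded vesicle is immediately a fusion partner of its donor
  (back fusion is part of the dynamics and is flagged in the transport
  log rather than forbidden).
- Inter-compartment fusion can be switched off (`fusion = FALSE`). The
  switch bars fusion between two compartments *both* larger than a
  vesicle; vesicle–compartment and vesicle–vesicle fusions keep the
  homotypic law. This is the only reading under which the
  fusion-prohibited variant retains vesicular exchange — with all fusion
  off the system would be an inert gas of vesicles — and it reproduces
  the expected phenomenology (the centripetal medial enrichment at
  intermediate `kb` disappears).
- Mean-field ODEs are integrated with `deSolve` at relative tolerance
  1e-8 (the system is linear and stiffness-free).
- Degenerate inputs: an empty system is legal (only injection fires); a
  zero-propensity state simply advances to the horizon; system purity
  over a vesicles-only snapshot is undefined and returned as `NA` with a
  warning; normalising a zero enrichment vector returns zeros with a
  warning.
- Burn-in must exceed the slowest relaxation time. The total size
  equilibrates over a few 1/Kf, but the medial pool relaxes on $1/k_m$;
  validation runs at $k_m=0.1$ therefore use `t_burn = 50` (five times
  $1/k_m$), and steady-state protocols at $k_m=1$ use `t_burn = 50` with
  `t_max = 200`.

## Problem sizes used by the validation suite

All validation is done at the main-text conditions `n_target = 300`,
$\alpha_{ER}=\alpha_{TGN}=1$: five-seed ensembles with horizons of
200/Kf for steady-state statistics (mixed regime `kb = 0.01` and
vesicular regime `kb = 100`, both at `km = 1`); twenty-seed pulse-chase
ensembles (50 cargo, horizon 60–80/Kf) for exit kinetics and
directionality; ten seeds at `kb = 10, km = 0.1` for the mean-field
comparison; and a million-event vesicular-regime run with per-event
conservation auditing (`check = TRUE`). Phase-diagram sweeps in examples
use short horizons and coarse grids; they reproduce the structure of the
published diagrams qualitatively, not pixel-by-pixel.

## What the simulations do and do not show

The simulator *is* the data generator: there is no external data, and
every tested behaviour is a property of the model under the stated
parameters. Passing tests therefore demonstrate internal correctness
(exact sampling of the specified jump process, conservation laws,
agreement with the model's own asymptotics) and reproduction of the
model-level phenomenology — they say nothing about real Golgi membranes
beyond what the model's assumptions encode. In particular the model
omits space and stacking, membrane mechanics and tension, tubular
connections, cooperative conversion, and any composition feedback on the
budding machinery; boundary compositions are static; and rates are
constant in time. Within those limits, the reproduced signatures are:
size control within about 10% of the calibration target with ~30–40%
fluctuations in the mixed regime, the purity transition from ~0.4–0.5 at
`kb = 0.01` to ~1 at `kb = 100`, the concurrent retrograde-to-anterograde
flip of the enrichment vector, exponential cargo exit, and the
maturation trajectory with its 1/e medial ceiling — each computed by the
test-suite or by `scripts/acceptance.R`, never asserted from the
literature.
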
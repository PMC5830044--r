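---
title: "Modeling urban cat population dynamics across ownership states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling urban cat population dynamics across ownership states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancats)
```

## The model

Urban domestic cats form one interconnected population spread over four
ownership states — owned, in shelters, free-roaming (socialized but
unowned), and feral — linked by human-mediated transitions: relinquishment,
loss, abandonment, adoption from shelters and off the street,
return-to-owner, surrender, and the feralization of free-roaming kittens.
Within each state, cats are classified into four life stages by age and
reproductive status: intact juveniles (< 12 months), intact adults, sterile
juveniles, and sterile adults. `urbancats` projects the female population
(assuming males are not limiting, and a 1:1 sex ratio when reporting
both-sex abundances) with an annual time step.

The population is a 16-entry vector `n`, stage-major (all states for stage
1, then stage 2, ...). One year of dynamics applies demography within each
state and then movement among states:

    n(t+1) = A n(t),    A = M K' B K

where `K` is the vec-permutation (commutation) matrix that rearranges the
vector between stage-major and state-major order (`vec_permutation_matrix()`),
`B` is block-diagonal with one 4x4 demography block per state
(`build_demography_block()`), and `M` is block-diagonal with one 4x4
column-stochastic transition block per stage (`build_transition_block()`).
This periodic construction keeps each process block-diagonal and therefore
easy to parameterize and perturb.

The demography block for a state with juvenile/adult survival `s0`, `s1`,
fecundity `f0`, `f1` (female kittens per female per year), and annual
sterilization probabilities `n0`, `n1` is

    [ s0 f0 (1-n0)   s1 f1 (1-n0)   0    0  ]
    [ s0 (1-n0)      s1 (1-n1)      0    0  ]
    [ s0 f0 n0       s1 f1 n0       0    0  ]
    [ s0 n0          s1 n1          s0   s1 ]

with column sums `s0 (1+f0)`, `s1 (1+f1)`, `s0`, `s1`. Note the offspring
rows: every newborn kitten faces the *juvenile* sterilization rate `n0` in
its first year, regardless of the mother's stage. This is a deliberate
design choice (`offspring_sterilization = "kitten_rate"`). The alternative
of splitting kittens by their mother's stage-specific rate
(`"parent_stage"`) is available, but it makes the owned-cat subsystem
supercritical at every latitude: with owned rates (s0 = 0.7, s1 = 0.8, 70%
juvenile sterilization, 10% adult, litter size 3.8) the intact-owned 2x2
block has dominant eigenvalue above 1 for any achievable number of litters
per year, so no equilibrium exists anywhere. Under the kitten-rate form the
owned subsystem is comfortably subcritical at temperate latitudes and
approaches criticality only near the equator, which matches the observed
behavior of this model family (temperate cities equilibrate; dense
near-equatorial configurations can fail to converge).

## City parameterization

Three census inputs parameterize a city: latitude, dwellings, and urban
area (hectares). Everything else is derived or defaulted:

* **Carrying capacities** (females, 1:1 sex ratio). Owned:
  `0.377 x 1.85 x dwellings / 2` (Canadian polling defaults for the
  proportion of dwellings with cats and cats per cat-owning dwelling; both
  overridable for other countries). Shelter: an annual throughput,
  `capacity x (365 / stay) / 2` with defaults of 187 spaces and a 30-day
  mean stay. Free-roaming and feral: equilibrium density times area over 2,
  with continental default densities `exp(-0.752664)` = 0.471 and
  `exp(-2.536883)` = 0.079 cats/ha — the geometric means of published
  density records, which are right-skewed with approximately lognormal
  distributions (`mean_density()`).
* **Reproduction.** Breeding season length follows a 4-parameter logistic
  in latitude with the upper asymptote fixed at 365 days
  (`breeding_season_length()`); litters per year = season / 149 days (65
  days gestation + 84 days weaning). Litter sizes are 3.8 (owned), 3.6
  (free-roaming), 3.5 (feral) kittens, halved for female kittens. Juvenile
  fecundity is discounted by the fraction of first-year cats past puberty,
  (365 - 212)/365 = 0.419. Shelter cats do not breed.
* **Sterilization.** Owned: 70% of kittens, 10% of remaining intact adults
  per year. Shelters sterilize everything they place. Unowned rates come in
  two published sets that disagree by an order of magnitude for feral cats;
  the set printed in the vital-rate table (5%/12.5% free-roaming, 1%/2.5%
  feral) is the default, the prose set (1%/2.5% and 0.1%/0.25%) is the
  `"text"` preset.
* **Transition constants.** Relinquishment 0.012/yr; abandonment 0.05/yr;
  shelter-routed loss 0.0049/yr (derived from a logarithmic loss model
  calibrated to 15% cumulative loss over 5 years, times the 6/69 fraction
  of lost cats that return via shelters — `derive_loss_rate()` exposes the
  chain, the default uses the published rounded constant);
  return-to-owner 0.0877 for sterile and 0.0385 for intact cats
  (`derive_recovery_rates()`); feral kittens 0.05/yr; feral surrender 1e-4.

## Density dependence

Unowned survival declines with density. Three published parameterizations
conflict, so all three ship as selectable variants
(`dd_variant`):

* `"calibrated"` (default): exponential decay `a exp(-b N/K)` with
  intercepts a = 0.82 (free-roaming adult), 0.65 (feral adult), 0.25
  (feral juvenile, six-month), and the decay rate solved from the one
  calibration the sources state explicitly — adult survival is exactly 0.5
  at carrying capacity. Juvenile feral survival shares the adult decay
  rate, rescaled to its own intercept.
* `"composite"`: the double-exponential composite forms as printed
  (`0.82 exp(-0.476 exp(0.0482 N/K))` etc.). The free-roaming form is
  nearly flat near 0.5 and the feral form *increases* with density; these
  are implemented verbatim and can drive collapse or diverging
  oscillations, which is useful for failure-mode analysis but not a
  sensible default.
* `"per_hectare"`: per-hectare forms, `0.82 exp(-0.475669 N/area)` and
  `0.65 exp(-10.0719 N/area)`. The published density unit is ambiguous;
  `density_interpretation` selects female counts per hectare (default,
  model units) or total counts.

Juvenile free-roaming survival is frequency-dependent in its first six
months — `-0.587 p + 0.907`, where p is the proportion of adult
free-roaming cats that are intact (aggression in intact colonies lowers
kitten survival) — and is completed to an annual rate by the adult rate:
the square root of annual adult survival by default (`"sqrt_adult"`, six
months at the adult rate), or the full annual rate (`"full_adult"`).
All evaluated rates are clamped to [0, 1].

Transitions are density dependent where humans mediate them: shelter
adoption is a logistic in owned abundance over carrying capacity (0.5 at
capacity, saturating near 1 when homes are empty); off-street adoption is
the product of an exponentially decaying owner-seeking term (0.3 at owned
capacity) and a logistic availability term; surrender of free-roaming cats
rises with free-roaming density through two increasing logistics. Away
from equilibrium these logistic outflows can transiently saturate — e.g.
adoption plus return-to-owner exceeding 1 when the owned population is far
below capacity. To keep every transition column a probability
distribution, adoption is capped at one minus return-to-owner and the
free-roaming outflows are rescaled proportionally when their sum would
exceed 1; constant rates summing past 1 remain a configuration error.

## Solving for equilibrium

`solve_equilibrium()` iterates the projection from the standard initial
vector (100 females per owned stage, 0 in shelters, 300 per free-roaming
stage, 40 per feral stage) for at most 1200 years. Convergence is declared
when the maximum relative step change drops below `tol = 1e-9`, chosen so
reported abundances are stable to well under 0.01 cats; the fixed-point
residual is below 10x tol and the equilibrium is independent of the
(positive) starting vector. A run that hits the iteration cap is *never*
reported as converged: the tail of the trajectory is classified as
oscillatory, divergent, or slowly converging, and the driver exits with a
distinct status. Density-dependent rates are evaluated at the
start-of-step vector, the only reading consistent with `n(t+1) = A(n(t))
n(t)`.

Reported abundances are doubled (1:1 sex ratio). The standing `total` is
owned + free-roaming + feral; the shelter state is an annual flow-through
(one-year residency per time step) and is reported separately as annual
throughput, with `total_with_shelter` also emitted. The shelter carrying
capacity is computed and reported but does not cap intake: the model
describes equilibrium states, not shelter policy; a ceiling would be the
natural extension for studying closed-admission policies.

```{r guelph}
guelph <- city_inputs(latitude = 43.55, dwellings = 52620, area_ha = 7885,
                      freeroaming_density = 0.787, feral_density = 0.246)
params <- build_parameter_set(guelph, dd_variant = "per_hectare")
eq <- solve_equilibrium(params)
eq
```

## Perturbation analysis

`elasticity_fd()` and `elasticity_implicit()` measure the proportional
response of equilibrium group abundance (owned, shelter, unowned, total)
to every lower-level parameter in `parameter_names()` — survival
baselines, litter sizes, sterilization rates, transition constants, and
density-dependence curve coefficients.

The finite-difference method is the default and assumption-free: each
parameter is perturbed by a relative `delta` (default 1e-3) in both
directions, the model is re-solved to equilibrium (warm-started from the
baseline), and the central difference of log abundance is formed.
One-sided differences are used at parameter bounds (e.g. shelter
sterilization fixed at 1). The implicit method differentiates the fixed
point `n* = A(n*, theta) n*` directly: it forms the Jacobian `J` of one
projection step by central numerical differentiation, solves
`(I - J) dn*/dtheta = dg/dtheta`, and scales to elasticities. It is two
orders of magnitude faster and valid whenever the equilibrium is locally
attracting; the two methods agree within 1% on every non-negligible entry
in our test suite, which is the module's core correctness check. A
parameter whose baseline value is 0 cannot be perturbed proportionally;
its entries are reported as absolute sensitivities and flagged in the
`scaling` column.

```{r elasticity}
base <- solve_equilibrium(params, max_iter = 5000, tol = 1e-11)
el <- elasticity_implicit(params, baseline = base)
head(el[order(-abs(el$elasticity)), ], 8)
```

These elasticities are fixed-point (equilibrium) sensitivities. Transient
accumulation along a trajectory is a different quantity and can differ in
sign for cross-network effects; where a directional effect matters for a
management question, we recommend confirming it with an explicit scenario
run (two solves at different parameter values) rather than relying on the
local derivative alone.

## Validation statistics

`one_to_one_regression()` fits observed on predicted abundance by ordinary
least squares and tests the intercept against 0 and the slope against 1
(t statistics on n-2 degrees of freedom) — a calibrated model should sit
on the 1:1 line. Exact fits are flagged `degenerate` rather than producing
unstable t statistics. The regression direction (observed on predicted) is
a documented choice; the reverse is a one-liner. `binomial_ci()` gives
exact Clopper-Pearson intervals for observed sterile proportions
(conservative by construction; Wilson intervals by flag).

## Synthetic fixtures

`generate_density_fixtures()` draws lognormal density records emulating a
compilation of published density studies — adequate for testing the
geometric-mean pipeline and stochastic-input plumbing. It does not emulate
the real features of such compilations: heterogeneous study areas and
methods, island/mainland differences for feral cats, or correlation
between density and detectability. Passing tests built on these fixtures
therefore validate the *computation*, not the field realism of any density
value.

## Problem sizes used in the test suite

The bundled tests solve equilibria for a small synthetic town (5,000
dwellings) where many re-solves are needed (elasticity cross-checks) and
for the Guelph-scale configuration (52,620 dwellings) for the case-study
and invariant checks; randomized structural invariants run on thousands of
parameter draws. These sizes were chosen because the model's cost is
independent of city size (16 state variables regardless), so small
configurations exercise every code path.

## Known limitations

* The model is deterministic; environmental and demographic stochasticity
  are out of scope, as are management-strategy optimization and spatial
  structure.
* The three published survival families disagree with each other and with
  the 0.5-at-carrying-capacity calibration; no single choice reproduces
  every published summary simultaneously. The variant sweep
  (`sweep_variants()`) makes the disagreement explicit.
* Several transition functions (surrender, availability) rest on sparse
  source data; their coefficients are used verbatim.
* Near-equatorial, high-fecundity configurations can fail to converge
  (diverging oscillations under the composite survival forms); the solver
  reports this explicitly rather than returning a pseudo-equilibrium.
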
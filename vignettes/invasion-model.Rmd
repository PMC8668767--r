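---
title: "An individual-based model of plant invasions on a gradient island"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of plant invasions on a gradient island}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

invasim simulates every plant on a small oceanic island individually —
genome, phenotype, mass, location — and uses that machinery to ask a
community-ecology question: under which combinations of propagule pressure,
productivity and disturbance do introduced species not only persist but
spread across the landscape, and what traits do the successful invaders
share? This vignette is the package's own account of the model, its
parameters, and the design choices behind them.

## The island

The landscape is a square grid of one-hectare patches (default 5 x 5). A
radially symmetric mountain rises in concentric rings (Chebyshev rings) from
elevation 0 on the outer ring to `(side - 1) / 2` at the central peak, and
temperature falls by 2 °C per unit of elevation from the configurable lowland
`base_temperature`. Orthogonally, an abstract "precipitation" resource varies
linearly across columns (default range 0–10). Each patch carries at most two
tonnes of plant biomass. One fixed lowland cell — by default the mid-edge
cell of the wettest-to-driest gradient's first column — is the point of entry
where all introduced propagules arrive.

Continuous coordinates matter only for seed dispersal: patch centers sit on
integer coordinates, cells are half-open unit squares, and anything outside
`[-0.5, side - 0.5)` in either axis is open ocean, where seeds die. These
conventions (rings, unit cells, mid-edge entry) are the simplest geometry
consistent with the system being emulated; none of the results below depend
on them qualitatively.

## Genetics and traits

Each plant carries a diploid genome. A shared architecture maps genes to the
eight quantitative traits: temperature optimum and tolerance, precipitation
optimum and tolerance, seed mass, adult (reproductive) mass, and the scale
and shape of the seed dispersal kernel. The default architecture places one
gene per trait on its own chromosome, so meiosis recombines freely *between*
traits and not at all within one. We deliberately model no linkage and no
mutation: both would confound the invasion question with evolutionary
dynamics, and the architecture is isolated behind `trait_architecture()` so
richer layouts can be swapped in.

A trait value is expressed as the arithmetic mean of all alleles coding for
it (both haplotypes), clamped to the trait's legal domain: tolerances and
kernel parameters strictly positive, kernel shape > 1 (so the dispersal
distribution has a finite mean), adult mass within 150 g – 1.2 t (the
grassland/shrubland range the model represents), and seed mass below half the
adult mass. Clamping, rather than redrawing, keeps expression a pure function
of the genome; at the default individual variation (`cv = 0.05`) clamping is
almost never active, so the induced bias is negligible.

Species are generated randomly. Mean traits are drawn uniformly within
generation ranges — log-uniformly for the two mass traits, which span four
orders of magnitude. The default ranges are:

| trait | range | rationale |
|---|---|---|
| temperature optimum | island range ± 2 × max tolerance | many species are badly adapted anywhere; assembly filters |
| temperature tolerance | 0.5–5 °C | specialists to moderate generalists |
| precipitation optimum | precip range ± max tolerance | as above |
| precipitation tolerance | 0.5–5 | as above |
| seed mass | 1–100 g (log-uniform) | allometrically plausible for a 150 g–1.2 t flora |
| adult mass | 150 g – 1.2 t (log-uniform) | the modeled ecosystem |
| dispersal scale | 0.1–2 grid units | median displacement up to two patches |
| dispersal shape | 1.1–4 | from heavy-tailed to compact kernels |

Native and alien pools use the *same* generator: any trait difference between
natives and invaders at the end of a run is an emergent result of 500 years
of community assembly plus the invasion process, not of construction. This is
itself a property the test suite relies on.

Individuals vary around their species means: at birth from the pool, each
trait is drawn from a normal distribution centered on the species mean with
standard deviation `cv` times the absolute mean, written homozygously to all
genes for that trait. The normal deviate is drawn per *trait*, not per
allele, so the realized trait standard deviation equals `cv · |mean|`
(a per-allele draw would shrink it by `1/sqrt(2g)`); heterozygosity then
arises through matings between carriers of different alleles.

## Adaptation and vital rates

A plant's fit to its patch is the product of two max-normalized Gaussians,

$$A_{ind} = e^{-(T_{env}-T_{opt})^2 / (2\,T_{tol}^2)} \cdot
           e^{-(P_{env}-P_{opt})^2 / (2\,P_{tol}^2)} \in (0, 1],$$

computed once at establishment (neither phenotype nor patch environment ever
changes). We use the max-normalized form — peak exactly 1 at the optimum —
rather than a probability density, because the quantity is a suitability
weight, not a distribution; a density would rescale every value by an
arbitrary `1/(2πcc')`.

Vital rates follow metabolic scaling,
$\text{rate} = c \cdot M^{\beta} \cdot e^{-E/kT}$, with activation energy
`E = 0.65` eV, Boltzmann's constant `k = 8.617e-5` eV/K, β = 3/4 for
whole-organism production (growth, fecundity) and β = −1/4 for mass-specific
mortality. The three coefficients are calibrated at a reference point
(20 °C, 1 kg) chosen to give multi-decade life cycles that reach
quasi-equilibrium within a 500-year burn-in:

* **mortality** `m0`: a perfectly temperature-adapted 1 kg plant dies with
  probability 0.05 per year. The realized hazard is divided by the plant's
  temperature adaptation (floored at 1e-6 and clamped at 1), so poorly
  adapted plants die sooner — the coupling is a design choice among several
  "linked to adaptation" forms, made explicit in `survival_step()`.
* **growth** `g0`: a 1 g seed reaches 1 kg in ten yearly steps at 20 °C.
  Because growth is applied in discrete yearly increments
  `M ← M + g0 M^{3/4} e^{-E/kT}` (capped at adult mass), the coefficient is
  solved against the discrete map with `uniroot()`, not against the
  continuous-time solution, which would undershoot the ten-year anchor by a
  third.
* **fecundity** `f0`: 5 % of the `M^{3/4}`-scaled yearly production is
  allocated to seeds; the seed count is that allocation divided by the
  mother's seed mass, rounded. Large plants therefore make more seeds, and
  small-seeded species make more but lighter seeds.

## The yearly schedule

Every simulated year applies, in fixed order: **survival** (density-
independent, adaptation-linked), **growth**, **competition** (while a patch
exceeds two tonnes, two random plants are compared and the lower
*precipitation* adaptation is removed; ties break uniformly at random to
avoid index-order bias), **reproduction** (each adult with at least one
conspecific adult in its patch mothers one brood; the pollen partner is drawn
uniformly among the *other* local conspecific adults — no selfing, no
between-patch pollen), **disturbance** (each plant independently removed with
probability `d`; only after burn-in), **transport** (exactly `P` alien
propagules placed at the point of entry, species drawn independently and
uniformly from the 100-species alien pool; only after burn-in), and
**dispersal** (each seed travels a log-logistic distance
`a (u/(1-u))^{1/s}` in a uniformly random direction; it dies over the ocean
or in any patch where its adaptation is below the establishment threshold).

Establishment is a hard threshold (default `A_ind ≥ 0.05`): "sufficiently
adapted" is read as a cutoff, not a lottery. A Bernoulli mode
(`establishment_mode = "bernoulli"`, establishment probability `A_ind`) is
available for sensitivity analysis. Transported propagules arrive at seed
mass and pass the same filter as dispersing seeds — their arrival stage is a
model choice; arriving as adults would shortcut the juvenile bottleneck that
propagule pressure is supposed to overcome.

Initialization places founders of each native species, as adults, in every
patch where the species' mean-trait adaptation clears the establishment
threshold, `floor(0.1 × capacity / adult mass)` founders per patch — smaller
species start more numerous, and the island starts moderately overfilled so
that the first competition rounds immediately impose the capacity. The
attempted pool is 50 native species; realized richness after burn-in is
emergent (typically around six, range roughly 1–15, on the default island).

## The experiment

`full_experiment()` crosses lowland temperature (15/35 °C, a productivity
proxy via the Arrhenius factor), propagule pressure (1/10 per year) and
disturbance (1 %/10 % per year) in a 2 × 2 × 2 design. Replicate `r` of
scenario `s` gets the seed `derive_seed(base, s, r)`; species pools are drawn
from a separate stream seeded by `derive_seed(base, 0, r)`, so all scenarios
of a replicate that share a temperature level see identical pools — a strict
superset of regenerating pools per run (recoverable with
`independent_pools = TRUE`) that enables paired scenario comparisons.

At the end of a run, extant species are categorized from the final census:
**native** (original community, still extant), **alien** (introduced, extant,
but confined to the point of entry) or **invasive** (introduced, with at
least one population beyond the entry cell — landscape spread). Introduced
species that died out entirely are tallied separately in the manifest
(`n_introduced_failed`), which distinguishes colonization pressure from
propagule pressure in the bookkeeping. `export_trait_table()` pools all
final-year populations with log(x+1)-transformed trait medians (dispersal
scale and shape, the two tolerances, the two masses, and adaptation; the
niche *optima* are excluded because they mostly mirror geography and the
temperature scenario). Downstream model fitting — mixed models, simultaneous
tests, ordination — is deliberately left to standard statistical tools
operating on that table; the package's contract ends at a correct, tidy
export.

## Problem sizes, determinism, numerics

The test suite and the acceptance script run a scaled-down design: a 3 × 3
island, 100-year burn-in, 300-year horizon and 20 replicates per scenario
(160 runs), plus five default-scale (5 × 5, 500-year) burn-in runs for the
richness distribution. These sizes are the package's choice of a desk-scale
experiment: large enough for the directional results (more invasions under
high propagule pressure; invaders with longer dispersal and higher adaptation
than the relevant comparison groups) to emerge, small enough to run in
minutes. Invasions are rare events at this scale — a handful across 160
runs — so count-based comparisons between scenario halves are meaningful,
while per-scenario counts fluctuate.

Determinism: a run is a pure function of its configuration (including the
seed). The population lives in compiled storage; the compiled year consumes
R's RNG stream in exactly the order of the exported step functions, an
equivalence the test suite asserts bit-for-bit. Census and map logs are
written with fixed-precision formatting, so re-running a configuration
reproduces the files byte for byte. Note that the world object has reference
semantics (its population state is an external pointer): `run_year()`
advances the state in place and returns the updated handle.

Numerical conventions worth knowing: seed counts use banker's rounding (R's
`round()`); competition ties break uniformly; the mortality divisor floors
temperature adaptation at 1e-6; adaptation underflows to exactly 0 for
grotesquely mismatched phenotypes (harmless: such seeds never establish);
and the biomass cap is guaranteed *after the competition step* — seedlings
establishing later in the same year add their (small) seed masses on top
until the next year's competition.

## What the generator does and does not emulate

The synthetic world captures the mechanisms of interest: metabolic scaling
of rates, niche-based filtering on two orthogonal gradients, local mate
limitation (an Allee effect that propagule pressure must overcome),
space-limited competition, and kernel-based spread. It does not attempt
realism in: weather variability (environments are constant), age or stage
structure beyond juvenile/adult, seed banks, pollen flow between patches,
mutation or plasticity, species interactions other than competition for
space, or landscape change. Passing tests therefore demonstrate internal
consistency and the direction of the modeled mechanisms — not predictions
for any particular real island.

## Known limitations

* Events per scenario are few at desk scale; only pooled or paired
  comparisons are stable.
* The mortality–adaptation coupling (division by `A_T`) is one of several
  defensible forms; the choice is localized in `survival_step()`.
* The 2 °C-per-elevation rule ties the temperature range to the island side;
  very large islands would need a rescaled gradient.
* Reference semantics of the world object surprise R users who expect
  copy-on-modify; treat a world like a connection, not a data frame.
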
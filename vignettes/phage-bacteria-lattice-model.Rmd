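---
title: "An individual-based model of phage-bacteria dynamics on structured lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of phage-bacteria dynamics on structured lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagelattice)
```

## The model

`phagelattice` simulates bacteria and bacteriophages as discrete agents on a
two-dimensional grid with Moore neighborhoods (the 8 cells at Chebyshev
distance 1, generalized to larger radii). Each location holds at most one
bacterial cell and at most `phage_cap_per_location` free virions. Free space
is the limiting resource: it appears when cells die and is recolonized by
the offspring of neighboring cells.

The defining axis of the package is *environmental structure*:

* **well-mixed** — the contents of every location are randomized at each
  iteration, emulating a shaken liquid culture. Competition for a free
  location is still resolved among its radius-1 neighbors, but because the
  community is reshuffled every iteration, every cell effectively competes
  everywhere.
* **semi-structured** — cells stay in place, but offspring may be placed
  within `reproduction_radius` (default Moore distance 3), and virions
  diffuse within `phage_diffusion_radius`.
* **structured** — a biofilm-like limit: cells never move, offspring are
  restricted to the adjacent 8 cells, and virions diffuse only locally
  (radius 1 in the structured presets).

Each iteration applies, in fixed order: antibiotic deployment/diffusion,
mixing or virion diffusion, virion decay, the infection pass, prophage
induction, lysis resolution (bursts), basal and antibiotic mortality,
reproduction into free space, and the resistance-mutation pass. The order
puts killing before reproduction so that space freed by a stressor is
contested in the same iteration; this ordering is a declared convention of
the package (the analyses in the acceptance layer are qualitative
comparisons across environments and are insensitive to reasonable
reorderings).

### Infection and the lysis-lysogeny decision

A free virion co-located with a bacterium passes a sequence of stochastic
gates: host resistance to the virion's attachment phenotype; adsorption,
with probability `host_range[phenotype, species] * adsorption_prob`;
superinfection exclusion, tested independently against each resident
prophage with the abort probabilities of the superinfection matrix; and the
lifecycle decision. Virulent phages always initiate lysis. Temperate phages
lysogenize with probability given by a Hill response of the local free-phage
count $n$ (the virions in the radius-1 Moore neighborhood including the
focal cell):

$$p_\text{lys}(n) = p_\text{max}\,\frac{n^h}{n^h + K^h},$$

which is zero in an empty environment, rises with local multiplicity of
infection, and saturates at `p_max`. Three stock curves are provided —
`Lysogeny1` ($K=5$), `Lysogeny2` ($K=15$) and `Lysogeny3` ($K=150$), all
with $p_\text{max}=0.9$, $h=2$ — spanning lysogenization that is likely at
low phage density to lysogenization that requires very high local density.
The curves are package choices: their qualitative ordering (not their exact
constants) is what the invasion analyses depend on. Local phage counts are
a snapshot taken at the start of each infection pass; within a location,
encounters are resolved sequentially in random order, so a lysogenization
changes the superinfection state seen by later virions in the same pass.
Locations do not interact within a pass (bursts are resolved in a later
phase), which is what makes per-location processing equivalent to a global
random encounter order.

An infection resolved as lysis kills the host at the lysis-resolution phase
of the same iteration, releasing `burst_size` virions at the host location;
there is no explicit eclipse period — one iteration is the time quantum.
Burst virions each draw an attachment phenotype through the per-offspring
mutation rule (probability `mu_attachment` of switching to a uniformly
chosen different phenotype) and then disperse through the same kernel as
ordinary diffusion. Prophages induce spontaneously with probability
`induction_prob` per iteration, multiplied by `stress_induction_factor`
when the lysogen sits at or above the antibiotic MIC threshold. Free
virions age and decay with a constant per-iteration hazard `decay_prob`
(geometric lifetime with half-life $\log 2 / -\log(1-p)$); age is tracked
so that age-dependent hazards can be added later.

### Antibiotics, death and fitness

The antibiotic is a per-location concentration field. A dose is deployed
either homogeneously (every location set to `dose`) or heterogeneously
(`n_foci` random locations). Each iteration the field diffuses — every
location keeps $1-f$ of its concentration and sends $f/8$ to each Moore-1
neighbor, the off-grid share staying in place on bounded lattices, so
diffusion conserves mass under both topologies — and then degrades by
`degradation_rate`. Killing is threshold-like: antibiotic-sensitive cells
at locations at or above `mic_threshold` die with `antibiotic_kill_prob`
per iteration; a dose-response curve was deliberately not modelled, since
only the contrast between exposed-sensitive and everyone else drives the
dynamics studied here.

Fitness is multiplicative:
`base_growth_rate * (1 - cost_ab)^[ab-resistant] * (1 - cost_ph)^(#resisted phenotypes)`,
which keeps fitness nonnegative and independent of the order in which
resistances were acquired. Reproduction into each free location is
fitness-proportionate (roulette wheel) among the live cells within the
competition radius; if all candidates have zero fitness the choice is
uniform (a convention that avoids an undefined normalization).

### Two design choices that deserve emphasis

**Bounded reproduction.** Only cells alive at the start of the reproduction
pass can parent, and each cell divides at most once per iteration, so the
population can at most double within one iteration. The alternative — a
newly placed offspring immediately parenting later fills in the same pass —
makes within-iteration growth nearly unbounded (a handful of survivors can
refill most of a lattice in a single pass), which lets a population
equilibrate indefinitely under a lethal sustained antibiotic. Under bounded
reproduction a lethal homogeneous dose drives sensitive populations extinct
— more slowly when competitors are absent, which is the behavior the
combined-treatment analyses probe. Reproduction remains asynchronous across
the population: which cells divide is determined by where space frees up.

**Per-cell per-iteration mutation.** Resistance mutation (to the antibiotic,
and to a uniformly chosen not-yet-resisted attachment phenotype) is applied
to every living cell once per iteration, in a dedicated phase, at rates
`mu_antibiotic` and `mu_phage_receptor`. Coupling mutation to birth events
alone would scale the realized emergence rate by the per-cell birth rate
(about the basal death probability, so roughly one twentieth), making
resistance emergence at the nominal rates unobservably rare. The
`mutate_offspring()` operation expresses the same gates for single-cell
use. Phage attachment mutation, in contrast, is genuinely a replication
error and is applied per burst offspring.

## Parameters and defaults

| Parameter | Default | Units / meaning |
|---|---|---|
| `width`, `height` | 50, 50 | lattice dimensions |
| `topology` | bounded | edge handling |
| `reproduction_radius` | 3 | offspring placement (semi-structured) |
| `phage_diffusion_radius` | 3 (1 structured) | virion movement per iteration |
| `phage_cap_per_location` | 50 | free virions a location can hold |
| `burst_size` | 50 | virions per lysis |
| `adsorption_prob` | 0.9 | per-encounter, times the host-range entry |
| `decay_prob` | 0.05 | per-iteration virion hazard |
| `basal_death_prob` | 0.05 | per-iteration intrinsic death |
| `antibiotic_kill_prob` | 0.95 | per-iteration, sensitive cells at >= MIC |
| `mic_threshold` | 1 | concentration units |
| `dose`, `n_foci` | 10, 10 | deployment |
| `degradation_rate` | 0.01 | slow-degrading single dose |
| `diffusion_fraction` | 0.2 | antibiotic diffusion per iteration |
| `induction_prob` | 1e-3 (0.01 invasion presets) | spontaneous induction |
| `stress_induction_factor` | 10 | induction multiplier at >= MIC |

The scenario presets (`scenario()`) encode the stock experiments at
50 x 50 scale: two-species communities under antibiotics and/or 10 virulent
phage particles; single-species resistance evolution under both stressors
(mutation rates 1e-4 per cell per iteration); a two-phenotype
coevolutionary arms race (receptor resistance at 1e-3, phage attachment
mutation at 1e-4); and lysogen invasion at a 1:10 invader:resident ratio
with the lysogenized-resident count at iteration 15 as the response
variable. The invasion presets use `induction_prob = 0.01`: at a quarter of
the cell numbers used for the full-scale setting (~2.2k cells here), the
absolute spontaneous-induction event rate must be preserved for the
iteration-15 response to be informative, and 1 every ~50 lysogen-iterations
is within the range observed for SOS-inducible prophages. These values were
fixed when the presets were written and are not tuned per analysis.

## What the simulations do and do not emulate

The scenario ensembles emulate the qualitative contrasts that motivate the
model: delayed phage-driven extinction under structure; inversion of the
extinction order under combined antibiotic-plus-phage treatment; enrichment
of double-resistant lineages in structured, patchily treated environments;
suppression of lysogenization when the decision requires very high local
phage density; and slower early lysogenization of resident populations in
structured environments. They do not emulate bacterial physiology (receptor
expression, growth-state-dependent adsorption), temporal or spatial change
of the structure regime itself, explicit genomes, or continuous-space
biofilm mechanics. An iteration is an abstract time quantum — its mapping
to wall-clock generations depends on the death and reproduction parameters
— so passing tests support the *ordering* of outcomes across environments,
not calibrated absolute rates in any particular organism.

## Numerical and degenerate-input conventions

* One bacterium per location is structural (the occupancy grid is a flat
  vector); the virion cap is enforced at every movement phase. A virion
  whose entire candidate neighborhood is saturated stays queued at its
  origin and is counted in the `capacity_queued` tally; the state tracks
  this overflow so the capacity assertion distinguishes queued excess from
  bookkeeping bugs.
* Antibiotic diffusion uses the discrete 8-neighbor kernel described above
  — the simplest mass-conserving local scheme; conservation on toroidal
  grids without degradation holds to 1e-12 relative tolerance and is
  asserted in the tests.
* All stochastic gates draw from a single seeded stream in fixed phase
  order, so `(configuration, seed)` determines a trajectory bitwise.
  Ensembles derive per-replicate seeds from one master seed.
* `emergence_time()` returns `NA` both when a genotype never reaches the
  detection threshold and when it never appears at all: in coevolution
  analyses, "never arose" is an informative outcome, not an error.
  Emergence CVs are computed over detected replicates only, with the
  detection count reported alongside.
* A roulette wheel whose weights are all zero falls back to a uniform
  choice. A lysogeny curve at local count 0 returns exactly 0.
* The population-level adsorption estimator regresses the decay-corrected
  log virion count on cumulative host exposure over an early window
  (default iterations 0-5, at least 3 usable points); iterations with a
  zero virion count shrink the window, and an estimate is refused if too
  few points remain.
* The environment-comparison test for early lysogenization is an
  analysis-of-covariance analogue: a pooled quadratic regression with
  environment interaction terms, tested jointly by an F-test. A named
  classical ANCOVA without model details admits several implementations;
  the interaction test was chosen because it uses exactly the quantities
  the fits already produce.

## Worked example

```{r example, eval = FALSE}
pair <- scenario("fig2_phage")
traj <- run_simulation(pair$general, pair$eco, seed = 1)
species_extinction_iteration(traj, "SabR")   # phage-sensitive species

st <- scenario("fig2_phage",
               overrides = list("general.structure" = "structured"))
traj_st <- run_simulation(st$general, st$eco, seed = 1)
species_extinction_iteration(traj_st, "SabR")
```

On seed 1 the phage-sensitive species (`SabR`) is extinct by iteration 4 in
the well-mixed run and only by iteration 19 in the structured run — the
delayed-extinction contrast that the 20-seed acceptance ensemble tests with
a one-sided rank test.

## Problem sizes used by the packaged analyses

The test suite runs the qualitative ensembles at 50 x 50 with 20 seeds per
condition and at most 80 iterations per run (invasion analyses use 16
iterations, since their response is read at iteration 15). The
`scripts/acceptance.R` report recomputes the same quantities with 10 seeds
per condition, and runs its sweep at 60 parameter combinations with 2
repeats on a 25 x 25 lattice — sizes chosen so the full report completes in
minutes on a single core; the full-scale settings (30 replicates, 100 x 100,
3000 x 30 sweeps) remain available through the same functions.

## Known limitations

* Defective phages are placeholders: they adsorb and abort, nothing more,
  and no preset uses them.
* Whether antibiotic stress modulates induction continuously or by
  threshold is unresolved in the literature this model abstracts; the
  threshold form was chosen to match the MIC-like kill model.
* The RFA layer claims ordering properties (planted drivers rank first,
  the dummy parameter sits at the noise floor), not any particular
  percentage increase in MSE: importance magnitudes depend on the sweep
  ranges, which are package-declared stand-ins.
* With more than 30 attachment phenotypes or 30 phage-species-phenotype
  combinations the bitmask state representation refuses the registry.
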
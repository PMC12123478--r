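---
title: "Lunar emergence timing, tidal zonation and strain coexistence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lunar emergence timing, tidal zonation and strain coexistence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalcoex)
```

## The scientific problem

Some intertidal insects, most famously the marine midge *Clunio marinus*,
compress their entire adult life -- emergence, mating, oviposition, death --
into a few hours around one low tide.  Reproduction is only possible when
the habitat is out of the water, so endogenous circalunar clocks lock adult
emergence to the spring-tide days of the lunar cycle.  Sympatric
*timing strains* differ in which days they use: a full-moon strain (FM)
emerges around the full moon, when low tides are lowest, while a new-moon
strain (NM) emerges several days *before* the new moon, at distinctly
higher water.  Because eggs are laid near the waterline of the emergence
day, the timing niche of the adults sets the elevation zone where the
offspring grow up.  `tidalcoex` implements a spatiotemporal simulation of
this coupling and asks when two timing strains can stably coexist, plus
the empirical genotype-score analysis that tests the model's central
prediction -- that larvae of the two strains settle at different depths.

## The habitat: a discretised tidal cycle

The lunar month is approximated as 2 x 14 days (full moon on day 1, new
moon on day 15), and the beach as six elevation zones, zone 1 highest.
`tidal_schedule()` returns the number of exposed zones `H(t)` for each
cycle day.  Spring tides expose all six zones for three days (days 2--4
and 16--18); neap tides expose only zone 1 for three days; in between,
exposure changes by exactly one zone per day.  These constraints determine
the schedule uniquely -- the test-suite proves uniqueness by exhaustive
search -- including the neap plateaus (days 9--11 and 23--25), which are
not stated anywhere but are forced.

## Strains and their timing traits

A strain is its emergence peak day plus a window from four days before to
four days after the peak.  How sharply emergence is concentrated on the
peak is set by a symmetric Beta(v, v) distribution over the window,
discretised by probability mass over nine equal sub-intervals
(`strain_timing()`).  Mass discretisation (rather than density sampled at
midpoints) preserves normalisation exactly and is defined for every
positive shape.  `v = 2` is the broad default; `v = 5` gives a narrow
niche; `v = 1` is uniform.  The field pair is FM = peak day 1 and
NM = peak day 11.

## Daily population dynamics

The model tracks continuous expected counts of females by strain, zone and
developmental stage (0..21).  Each day, in a fixed order that is part of
the model definition: density-dependent survival; stage transitions;
emergence; adult migration; oviposition.

**Survival.**  Feeding larvae in zone `z` survive the day with probability
`s_z(t) = s_max * exp(-alpha_z * N_z(t)^2)`, where `N_z` is the zone's
total feeding-larva count across strains and stages -- competition is
strain-blind.  The squared term keeps survival near `s_max` until
competitors are numerous and then drops it steeply (an overcompensating,
scramble-type regulation).

**The egg stage.**  Stage 0 represents the egg clutch: eggs do not feed,
so they neither contribute to nor suffer the density-dependent term, and
experience only the background survival `s_max` until they hatch into
stage 1 (mean `1/r` days).  This distinction matters.  If freshly laid
egg pulses are counted into the competitive density, the enormous
same-day pulse (C = 50 daughters per female) dominates the within-cycle
density profile, and a rare strain shifted by exactly 14 days gains a
systematic advantage simply by avoiding its own natal pulse -- producing
mutual invasibility where the biology argues for a priority effect.
Treating eggs as non-competing removes that artefact.

**Development.**  Stages 0..19 advance with daily probability `r = 0.45`,
so completing development is a sum of geometric waits -- a realistic
spread of about one to two months rather than a synchronous cohort.
Stage 20 ignores `r`: the pool is released into the final pre-emergence
stage 21 exactly 16 days before the strain's next window start
(`window_start()` minus 16, once per cycle).  Stage-21 larvae keep
competing and dying like any other larva until they emerge.

**Emergence and the waterline.**  On window day `t` the stage-21 pool of
an eligible zone releases the fraction `w_k / (w_k + ... + w_8)` of its
current size (the drain rule), so a pool eligible all window is split in
proportion to the Beta weights and is empty after the last window day.
Eligibility is the second structural choice: adults can only emerge from
zones near the descending waterline, `z >= H(t) - 1` -- the waterline
zone, the just-exposed zone directly above it (these are the emergers the
downward-migration rule can carry one zone towards the water), and all
submerged zones, whose emergers surface and relocate upward to
`z = H(t)`.  A pre-emergence pool stranded high and dry waits, under
ordinary mortality, for a window day on which its zone qualifies --
possibly in the next cycle.  Without this restriction a strain whose
window spans the spring tides seeds a self-sustaining population in the
*highest* zones (high-zone larvae emerging on spring days simply
re-oviposit in place), which flattens the strain's depth profile,
erases most spatial segregation, and -- at low downward migration --
lets the full-moon strain competitively swallow the new-moon strain's
shallow refuge.  Emergence at the falling waterline is also what the
field data show: daily abundance peaks just before the low tide.
The band is configurable (`emergence_band`, `Inf` disables).

**Migration and reproduction.**  Upward migration is obligatory
(oviposition under water is impossible); downward migration moves a
proportion `m` of emergers one zone towards the water's edge where the
zone below is exposed, computed simultaneously with no chaining.  Each
female then lays `C = 50` daughters in her post-dispersal zone and dies.

**`s_max`.**  The baseline survival is not stated in the main model
description.  The naive bound `s_max^(21/r) * C > 1` ignores the waiting
phases: a realised life cycle spans roughly 75 days (44 days of r-driven
development, on average half a cycle waiting for the maturation gate, 16
days in the pre-emergence hold), so viability requires about
`s_max > 0.95`.  The default is `s_max = 0.99`, giving a low-density
egg-to-adult survival of about 2% -- a plausible figure for a
high-fecundity capital breeder -- and leaving density dependence, not
background mortality, as the operative regulating force.  `dynamics_params()`
warns when a parameter set is non-viable.

## Invasion experiments

`run_invasion()` follows the pairwise-invasibility protocol: establish a
single-strain resident (burn-in of at least 26 cycles, extended until the
cycle-mean total settles), convert 1% of every zone-stage cell to the
invader label (so the invader inherits the resident's spatial structure
and its global frequency is exactly 1%), and iterate until the 28-day
mean of the resident's global frequency changes by less than `1e-5`
between consecutive cycles, or 100 years (1300 cycles of 28 days;
13 x 28 = 364-day years) elapse.  Because invasion trajectories wobble
for a few cycles after the relabelling, convergence is only declared
after three consecutive sub-tolerance changes -- a single crossing can
otherwise stop a run spuriously.  A strain whose global count falls below
one individual is zeroed out (expected-value dynamics never reach exact
zero).  Outcomes: resident extinct -> `invader_wins`; invader extinct ->
`invader_fails`; both alive -> `coexistence`, unless the invader merely
persists below twice its introduction frequency, which recodes the
dynamically neutral identical-timing case as a failed invasion.

The default dynamics are deterministic expectation flows, which make
grids exactly reproducible.  A seeded stochastic mode (integer counts,
binomial transitions) is provided and is checked against the
deterministic flows at large population size; with the egg-stage and
waterline choices above, the headline outcomes do not depend on
demographic noise.

`invasion_grid()` sweeps resident x invader peak days (reusing each
resident's burn-in) and `bin_by_segregation()` summarises the
minority-strain terminal frequency in four segregation categories.
Cells with SC exactly 0 form their own bin, because extinction forces
SC to zero and causality there is confounded; the non-zero cells are
split at thirds (0--1/3, 1/3--2/3, above 2/3).

## The segregation coefficient

`segregation_coefficient()` implements the segregation/aggregation
statistic `SC = 1 - (N / XY) * sum_z x_z y_z / n_z`: the observed
frequency of between-strain co-occurrence within zones relative to random
mixing.  It is 0 under proportional overlap and when only one strain
remains, 1 under complete segregation; tiny negative floating-point
results are clamped.  A finite-count variant (`variant = "small_sample"`,
using `(N-1)` and `(n_z - 1)`) is available for sensitivity checks but is
not the default because it does not attain 0 exactly under proportional
overlap.  Grid cells report SC on per-zone larval counts pooled (summed)
over the final 28-day cycle: pooling is always defined, whereas daily SC
is undefined on days when a strain happens to have no larvae.

## The empirical arm: genotype scores and the depth cline

Diagnostic SNPs are selected by the stated filters -- `F_ST >= 0.3`,
major-allele frequency above 0.8 in one strain with that allele below 0.4
in the other, then, per locus, the SNP with the fewest missing genotypes
(ties broken by genomic coordinate, then identifier).  A diploid call
scores 1 (two FM alleles), 0.5 (heterozygous) or 0 (two NM alleles), and
an individual's genotype score is the mean over non-missing loci
(individuals with no scorable call are dropped with a message; the
granularity is 1/(2L) for L scored loci).

`fit_depth_cline()` regresses score on sampling depth with a logit link
and a random intercept per sampling site (`lme4::glmer`).  Scores in
[0, 1] are treated as quasi-Bernoulli proportions with unit weights; this
is deliberately conservative, since the true score variance given the
mixture structure is below the Bernoulli bound, so Wald intervals tend to
over- rather than under-cover.  If the mixed fit errors or fails to
converge, a fixed-effects logistic regression is substituted and
flagged (`method = "glm_fallback"`).  Sign convention: score 1 = FM-like;
depth is elevation in metres, more negative = deeper; FM-like genotypes
at depth therefore give a *negative* slope.

## The synthetic-data generator

`simulate_larval_sample()` produces a field-like sample: sites along a
depth gradient, a logistic cline of strain composition with site-level
random intercepts, F1-like hybrids (one allele drawn from each strain's
pool, hence het-enriched; default fraction 0.1), within-strain diagnostic
allele frequencies of 0.9, and flat missingness (default 5%).

Two calibration decisions make parameter recovery a well-posed test.
First, `true_slope` parameterises the logit-linear cline of the
*expected genotype score* -- the estimand the GLMM actually fits -- and
strain-membership probabilities are derived by inverting the calibration
`E[score] = c0 + (c1 - c0) * P(FM)`, where `c0` and `c1` are the expected
scores of pure NM and pure FM individuals under the configured allele
frequencies and hybrid fraction (0.14 and 0.86 at the defaults).  Naively
placing the nominal slope on the membership probability instead biases
the fitted slope towards zero (scores plateau at `c1 < 1`, not at 1), and
a recovery test against the nominal value would fail for reasons that
have nothing to do with the fitting code.  Second, the default
`depth_range` (-3.75 to -2.25 m, around the default midpoint at -3 m) is
the transition band on which that calibration is exact, mirroring the
field observation that intermediate elevations carry the full range of
genotype scores; outside it the expected score saturates and the
generator clips membership probabilities to [0, 1].  With the defaults
the generator reproduces the published design size: 94 larvae across 49
sites at 8 loci, with generating slope -2.48.  That field estimate is
used *only* as generator truth for recovery testing -- reproducing the
published coefficient itself would require the field data.

What a green recovery test establishes: that the scoring and fitting
pipeline recovers a known score-cline slope, with conservative coverage
and near-nominal type-I error, from data with the sample size, hybrid
load and missingness of the real design.  What it does not establish:
correctness of the published estimate, robustness to informative
missingness, genotyping error beyond flat missingness, or linkage among
loci -- none of which the generator emulates.

## Numerical choices and degenerate inputs

* Emergence-drain weights use CDF differences; the last window day always
  releases the full remaining pool (an explicit guard against floating
  residue).
* The convergence detector needs three consecutive sub-tolerance cycles;
  on a constant-frequency sequence it halts within four cycles.
* `segregation_coefficient()` rejects the all-zero table, returns 0 when a
  strain is absent, and clamps to [0, 1].
* CSV output from the workflow layer is fixed at 10 significant digits so
  byte-level regression comparisons are stable.
* All randomness (stochastic mode, synthetic data) flows through explicit
  integer seeds; deterministic runs are bit-reproducible and the run
  manifest records every parameter plus the schedule fingerprint.

## Known limitations

* Only females are modelled; adults neither feed nor face density
  dependence (regulation is purely larval, as the biology argues).
* One low tide per day: the semidiurnal tide and diel timing variation
  within a day are outside the model.
* No hybridisation or Allee effects in the dynamics; strains breed true.
* Larvae never move between zones after oviposition.
* The tuned constants absent from the primary description (`s_max`, the
  egg stage, the waterline band) were fixed once against the qualitative
  behaviour the source system is known to show -- a viable resident,
  coexistence of the real FM/NM pair at every downward-migration rate,
  priority effects for 14-day-shifted pairs -- and are exposed as
  configuration, not re-tuned per experiment.
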
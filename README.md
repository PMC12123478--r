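# tidalcoex

Tidal timing, spatial segregation and coexistence of lunar-rhythm
strains of intertidal insects.

## What problem this solves, and for whom

Marine midges such as *Clunio marinus* compress their entire adult life
into a few hours around one low tide, so circalunar clocks lock adult
emergence to particular days of the lunar cycle.  Sympatric *timing
strains* use different days — a full-moon strain (FM) emerges at the
lowest spring-tide water, a new-moon strain (NM) several days before new
moon at higher water — and because eggs are laid near the waterline of
the emergence day, a strain's temporal niche sets the beach elevation
where its larvae grow up and compete.  `tidalcoex` is for ecologists and
chronobiologists who want to ask, quantitatively: *when does a timing
difference translate into enough spatial segregation of larvae to allow
stable coexistence, rather than a priority effect?*  It also ships the
empirical companion analysis — multi-locus genotype scoring of larvae
and a mixed-model depth cline — exercised end-to-end on synthetic data.

## The model in brief

* **Habitat** — the lunar month as 2 × 14 days over six elevation zones;
  `H(t) ∈ {1..6}` zones are exposed at the daily low tide (spring: all
  six for 3 days; neap: one), changing by one zone/day.
* **Timing** — each strain emerges in a 9-day window centred on its peak
  day, weighted by a symmetric Beta(v, v) mass discretisation (v = 2
  broad, 5 narrow).
* **Dynamics** — daily stage-structured bookkeeping of female counts:
  density-dependent larval survival `s_z(t) = s_max · exp(−α_z N_z(t)²)`
  with strain-blind, zone-local competition; geometric stage transitions
  (`r = 0.45`); a maturation gate 16 days before the next window;
  emergence restricted to zones near the descending waterline; obligatory
  upward migration of submerged emergers to `z = H(t)`; optional downward
  migration (proportion `m`) one zone towards the water's edge; `C = 50`
  daughters laid in the mother's post-dispersal zone.
* **Experiments** — pairwise invasion analysis (resident established,
  invader introduced at 1%, run to a 10⁻⁵ frequency-convergence criterion
  or 100 years) over all 28 × 28 peak-day pairs, with outcomes classified
  as coexistence / invader wins / invader fails.
* **Segregation** — the segregation coefficient
  `SC = 1 − (N / XY) Σ_z x_z y_z / n_z` (0 = complete overlap,
  1 = complete segregation) on per-zone larval counts pooled over the
  final cycle.
* **Empirical arm** — diagnostic-SNP filters (F_ST ≥ 0.3, major-allele
  frequency > 0.8 in one strain, < 0.4 in the other), diploid scoring
  (1 / 0.5 / 0), per-larva genotype score (hybrid index), and a
  logit-link mixed model of score on sampling depth with a site random
  intercept.

See `vignettes/timing-coexistence.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(tidalcoex)

tidal_schedule()
#> 28-day tidal exposure schedule (6 zones)
#> H(t): 5 6 6 6 5 4 3 2 1 1 1 2 3 4 5 6 6 6 5 4 3 2 1 1 1 2 3 4

# the real strain pair: FM resident (peak day 1), NM invader (peak day 11)
run_invasion(strain_timing(1, 2), strain_timing(11, 2),
             dynamics_params(m = 0.5))
#> invasion: resident peak 1 vs invader peak 11 -> coexistence
#>   terminal freq (28-day mean): resident 0.8271, invader 0.1729
#>   SC = 0.451, 45 cycles, converged: TRUE

# complete spatial segregation scores SC = 1
segregation_coefficient(c(100, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 100))
#> [1] 1

# synthetic larval sample (94 larvae, 49 sites, 8 loci) and the
# depth-cline fit; the generator's true score-cline slope is -2.48
sim <- simulate_larval_sample(cline_config(seed = 1))
sc  <- genotype_scores(sim$genotypes)
fit_depth_cline(sc$score, sc$depth, sc$site)
#> depth cline (glm_fallback, n = 94): slope = -2.409 (SE 0.628), p = 0.000125
#>   intercept = -6.928, site variance = 0.000
```

Reading the numbers: the NM invader rises from 1% to a stable ~17%
minority while the strains segregate across zones (SC ≈ 0.45); shifting
the invader's peak to day 15 (exactly two weeks from the resident)
instead drives it extinct — a priority effect.  The cline fit recovers a
negative slope close to the generating −2.48: genotypes shift from
NM-like (score 0) towards FM-like (score 1) with increasing depth.  (For
this seed the site random-intercept fit is singular, so the flagged
fixed-effects fallback is reported.)

Full sweeps: `invasion_grid()` for one panel,
`reproduce_invasion_panels()` for the m ∈ {0.2, 0.5, 1} suite,
`run_all()` for the whole pipeline.  A command-line entry point with
subcommands (`schedule`, `invade`, `grid`, `figure4`, `sc`, `genoscore`,
`cline-fit`, `synth`, `run-all`) is installed at `inst/cli/tidalcoex`.

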
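Package: tidalcoex
Title: Tidal Timing, Spatial Segregation and Coexistence of Lunar-Rhythm
    Strains
Version: 0.1.0
Authors@R:
    person("Rowan", "Keller", email = "rowan.keller@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how lunar-cycle
    timing of adult emergence in intertidal insects translates into
    vertical zonation of offspring and, ultimately, into coexistence or
    competitive exclusion of reproductive-timing strains.  Provides a
    discretised 28-day tidal exposure schedule, Beta-distributed
    emergence windows, a stage-structured daily population model with
    density-dependent larval survival, pairwise invasion experiments
    over all emergence-peak combinations, a spatial segregation
    coefficient (SSAS), multi-locus genotype scoring with a
    depth-cline mixed model, and a synthetic-data generator for
    end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
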
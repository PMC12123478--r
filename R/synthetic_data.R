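# Synthetic-data generators: a two-strain larval genotype sample whose
# strain composition follows a logistic cline in depth, and ready-to-run
# population fixtures for the headline invasion scenarios.

#' Configuration for the synthetic larval cline sample
#'
#' The generator emulates the structure of a field sample of intertidal
#' larvae genotyped at a small diagnostic SNP panel: sampling sites
#' strung along a depth gradient, a logistic cline of strain
#' composition in depth with a site-level random intercept, a minority
#' of het-enriched hybrids, within-strain allele frequencies below
#' fixation, and flat missingness.
#'
#' `true_slope` and `true_intercept` parameterise the logit-linear
#' cline of the *expected genotype score* -- the estimand of
#' [fit_depth_cline()] -- on the depth scale (metres of elevation;
#' negative = deeper).  Strain-membership probabilities are derived
#' from it by inverting the score calibration
#' `E[score] = c0 + (c1 - c0) * P(FM)`, where `c0` and `c1` are the
#' expected scores of pure NM and pure FM individuals under the
#' configured allele frequencies and hybrid fraction (clipped to
#' `[0, 1]` where the cline saturates).  The default `depth_range`
#' covers the transition band where the expected score stays between
#' `c0` and `c1`, mirroring the observation that intermediate
#' elevations carry the full range of genotype scores.
#'
#' @param n_sites Number of sampling sites (default 49).
#' @param n_larvae Total larvae sampled (default 94), spread across
#'   sites as evenly as possible.
#' @param depth_range Length-2 numeric, metres (default
#'   `c(-3.75, -2.25)`, the default truth's transition band).
#' @param true_slope Logit-scale depth coefficient of the expected
#'   genotype score (default -2.48: FM-like genotypes at depth).
#' @param true_intercept Logit-scale intercept (default -7.44, placing
#'   the cline midpoint at -3 m).
#' @param site_sd SD of the site-level random intercept on the logit
#'   scale (default 0.5).
#' @param hybrid_fraction Probability a larva is an F1-like hybrid
#'   (default 0.1).
#' @param missing_rate Per-call missingness (default 0.05).
#' @param n_loci Number of diagnostic loci (default 8).
#' @param within_strain_major_freq Frequency of the FM-typical allele
#'   in the FM strain (and of the NM-typical allele in the NM strain;
#'   default 0.9).
#' @param seed Integer RNG seed.
#' @return Object of class `cline_config`.
#' @export
cline_config <- function(n_sites = 49L, n_larvae = 94L,
                         depth_range = c(-3.75, -2.25),
                         true_slope = -2.48, true_intercept = -7.44,
                         site_sd = 0.5, hybrid_fraction = 0.1,
                         missing_rate = 0.05, n_loci = 8L,
                         within_strain_major_freq = 0.9,
                         seed = 1L) {
  stopifnot(n_sites >= 2, n_larvae >= n_sites, length(depth_range) == 2,
            depth_range[1] < depth_range[2], site_sd >= 0,
            hybrid_fraction >= 0, hybrid_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, n_loci >= 1,
            within_strain_major_freq >= 0.5,
            within_strain_major_freq <= 1)
  structure(list(n_sites = as.integer(n_sites),
                 n_larvae = as.integer(n_larvae),
                 depth_range = depth_range,
                 true_slope = true_slope, true_intercept = true_intercept,
                 site_sd = site_sd, hybrid_fraction = hybrid_fraction,
                 missing_rate = missing_rate, n_loci = as.integer(n_loci),
                 within_strain_major_freq = within_strain_major_freq,
                 seed = as.integer(seed)),
            class = "cline_config")
}

#' Simulate a larval genotype sample along a depth gradient
#'
#' Site depths are drawn uniformly within `depth_range` and each site
#' receives a normal random intercept.  Each larva is a hybrid with
#' probability `hybrid_fraction`; otherwise it belongs to the FM strain
#' with the depth-dependent membership probability (see
#' [cline_config()]) and to the NM strain otherwise.  Diploid calls per
#' locus are drawn allele-wise from the within-strain frequencies; a
#' hybrid draws one allele from each strain's pool (het-enriched).
#' Missingness is applied uniformly at random per call.
#'
#' @param config A [cline_config()].
#' @return List with `genotypes` (a `data.frame`: `id`, `site`,
#'   `depth`, and `n_loci` call columns `L1..Lk` coded
#'   `homFM`/`het`/`homNM`/`NA`) and `truth` (the generating
#'   configuration plus per-site depths/effects and each larva's latent
#'   origin).
#' @export
simulate_larval_sample <- function(config = cline_config()) {
  stopifnot(inherits(config, "cline_config"))
  set.seed(config$seed)
  f <- config$within_strain_major_freq
  h <- config$hybrid_fraction
  c0 <- (1 - h) * (1 - f) + h / 2
  c1 <- (1 - h) * f + h / 2

  site_depth <- stats::runif(config$n_sites, config$depth_range[1],
                             config$depth_range[2])
  site_eff <- stats::rnorm(config$n_sites, 0, config$site_sd)
  site_of <- sort(rep_len(seq_len(config$n_sites), config$n_larvae))

  depth <- site_depth[site_of]
  eta <- config$true_intercept + config$true_slope * depth +
    site_eff[site_of]
  mu <- stats::plogis(eta)
  p_fm <- pmin(1, pmax(0, (mu - c0) / (c1 - c0)))

  n <- config$n_larvae
  is_hybrid <- stats::runif(n) < h
  is_fm <- stats::runif(n) < p_fm
  origin <- ifelse(is_hybrid, "hybrid", ifelse(is_fm, "FM", "NM"))

  # per-allele probability of drawing the FM-typical allele: one allele
  # per parental pool; hybrids take one from each (het-enriched)
  p1 <- rep(ifelse(origin == "NM", 1 - f, f), config$n_loci)  # FM/hybrid pool
  p2 <- rep(ifelse(origin == "FM", f, 1 - f), config$n_loci)  # NM/hybrid pool
  a1 <- stats::runif(n * config$n_loci) < p1
  a2 <- stats::runif(n * config$n_loci) < p2
  copies <- matrix(as.integer(a1) + as.integer(a2), nrow = n)
  calls <- matrix(c("homNM", "het", "homFM")[copies + 1L], nrow = n)
  calls[matrix(stats::runif(n * config$n_loci) < config$missing_rate,
               nrow = n)] <- NA

  gt <- data.frame(id = sprintf("larva_%03d", seq_len(n)),
                   site = sprintf("site_%02d", site_of),
                   depth = depth, stringsAsFactors = FALSE)
  colnames(calls) <- paste0("L", seq_len(config$n_loci))
  gt <- cbind(gt, as.data.frame(calls, stringsAsFactors = FALSE))

  list(genotypes = gt,
       truth = list(config = config, site_depth = site_depth,
                    site_effect = site_eff, origin = origin,
                    p_fm = p_fm, score_bounds = c(c0 = c0, c1 = c1)))
}

#' Write / read a genotype table as TSV
#'
#' Plain-text interchange for [simulate_larval_sample()] output and
#' [genotype_scores()] input: one row per individual, columns `id`,
#' `site`, `depth` and one column per locus with calls coded
#' `homFM`/`het`/`homNM` (empty = missing).
#'
#' @param genotypes Genotype `data.frame`.
#' @param path File path.
#' @return `write_genotype_tsv` returns `path` invisibly;
#'   `read_genotype_tsv` returns the `data.frame`.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  gt <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  gt
}

#' Ready-to-run invasion fixtures
#'
#' Named presets for the headline timing scenarios, wired with the
#' standard parameters (Beta shape 2, constant `alpha = 1e-8`,
#' `C = 50`, `r = 0.45`): `fm_vs_nm` (resident peak 1 vs invader peak
#' 11, the field pair), `symmetric_14day` (peak 1 vs 15, reproduction
#' exactly two weeks apart), `identical` (equal peaks) and
#' `single_strain` (no invader).
#'
#' @param scenario One of `"fm_vs_nm"`, `"symmetric_14day"`,
#'   `"identical"`, `"single_strain"`.
#' @param m Downward-migration proportion (default 0.5).
#' @param shape Beta shape (default 2).
#' @return List with `resident`, `invader` (`NULL` for
#'   `single_strain`), `params`, `protocol` and `state` (the seeded
#'   pre-burn-in [population_state()]).
#' @export
fixture_population <- function(scenario = c("fm_vs_nm", "symmetric_14day",
                                            "identical", "single_strain"),
                               m = 0.5, shape = 2) {
  scenario <- match.arg(scenario)
  peaks <- switch(scenario,
    fm_vs_nm        = c(1L, 11L),
    symmetric_14day = c(1L, 15L),
    identical       = c(1L, 1L),
    single_strain   = c(1L, NA))
  params <- dynamics_params(m = m)
  protocol <- invasion_protocol()
  state <- population_state()
  state$larvae[1L, , 1L] <- protocol$seed_density
  list(resident = strain_timing(peaks[1L], shape),
       invader = if (is.na(peaks[2L])) NULL
                 else strain_timing(peaks[2L], shape),
       params = params, protocol = protocol, state = state,
       scenario = scenario)
}
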
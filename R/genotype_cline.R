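# Empirical arm: SNP scorability filters, diploid locus scoring, the
# per-individual genotype score (hybrid index), and the depth-cline
# mixed model.

#' Select scorable SNPs
#'
#' Applies the diagnostic-marker filters to a per-SNP summary table, in
#' order: (1) remove all SNPs with `fst < 0.3`; (2) keep SNPs whose
#' major allele frequency in one strain exceeds 0.8 while (3) that same
#' allele is below 0.4 in the other strain.  Within each locus the SNP
#' with the fewest missing genotypes is retained (ties broken by lowest
#' genomic coordinate, then SNP identifier).
#'
#' @param sites `data.frame` with columns `locus` (locus identifier),
#'   `snp` (SNP identifier), `pos` (genomic coordinate), `fst`
#'   (between-strain differentiation in `[0, 1]`), `major_freq`
#'   (frequency of the focal allele in the strain where it is major)
#'   and `other_freq` (frequency of the same allele in the other
#'   strain), `n_missing` (missing genotype count).
#' @param fst_min,major_min,other_max Filter thresholds
#'   (defaults 0.3, 0.8, 0.4).
#' @return The retained rows, one per locus, ordered by `locus`.
#'   Empty result triggers a warning, not an error.
#' @export
select_scorable_snps <- function(sites, fst_min = 0.3, major_min = 0.8,
                                 other_max = 0.4) {
  need <- c("locus", "snp", "pos", "fst", "major_freq", "other_freq",
            "n_missing")
  stopifnot(is.data.frame(sites), all(need %in% names(sites)))
  keep <- sites$fst >= fst_min &
    sites$major_freq > major_min &
    sites$other_freq < other_max
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    warning("no SNPs pass the scorability filters")
    return(s)
  }
  s <- s[order(s$locus, s$n_missing, s$pos, s$snp), , drop = FALSE]
  s <- s[!duplicated(s$locus), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Score a diploid genotype call
#'
#' `homFM` (two copies of the typical full-moon-strain allele) scores
#' 1, `homNM` scores 0, `het` scores 0.5; missing calls propagate as
#' `NA`.  Numeric input is interpreted as the count of FM-allele
#' copies (0, 1, 2) and scored as `copies / 2`.
#'
#' @param call Character vector in `{homFM, het, homNM}` (NA allowed),
#'   or numeric vector in `{0, 1, 2}`.
#' @return Numeric vector in `{0, 0.5, 1, NA}`.
#' @export
score_call <- function(call) {
  if (is.numeric(call)) {
    stopifnot(all(call %in% c(0, 1, 2) | is.na(call)))
    return(call / 2)
  }
  map <- c(homFM = 1, het = 0.5, homNM = 0)
  bad <- !is.na(call) & !(call %in% names(map))
  if (any(bad)) stop("unrecognised calls: ",
                     paste(unique(call[bad]), collapse = ", "))
  unname(map[call])
}

#' Per-individual genotype scores (hybrid index)
#'
#' The genotype score of an individual is the mean of its locus scores
#' over all loci with a non-missing call: 1 is a 'pure' FM genotype,
#' 0 a pure NM genotype, intermediate values indicate mixed ancestry.
#' Individuals with no scorable call are dropped with a message.
#'
#' @param genotypes A `data.frame` with columns `id`, `site`, `depth`
#'   and one column per locus containing calls accepted by
#'   [score_call()], or a matrix/data.frame of calls only (rows =
#'   individuals) when `loci` is `NULL`.
#' @param loci Character vector naming the locus columns; defaults to
#'   all columns except `id`, `site`, `depth`.
#' @return `data.frame` with `id`, `site`, `depth` (when present),
#'   `score` in `[0, 1]` and `n_loci_scored`.
#' @export
genotype_scores <- function(genotypes, loci = NULL) {
  stopifnot(is.data.frame(genotypes))
  meta <- intersect(c("id", "site", "depth"), names(genotypes))
  if (is.null(loci)) loci <- setdiff(names(genotypes), meta)
  stopifnot(length(loci) >= 1, all(loci %in% names(genotypes)))
  sc <- vapply(genotypes[loci], score_call, numeric(nrow(genotypes)))
  sc <- matrix(sc, nrow = nrow(genotypes))
  n_scored <- rowSums(!is.na(sc))
  score <- ifelse(n_scored > 0, rowMeans(sc, na.rm = TRUE), NA_real_)
  out <- cbind(genotypes[meta],
               data.frame(score = score, n_loci_scored = n_scored))
  dropped <- n_scored == 0
  if (any(dropped)) {
    ids <- if ("id" %in% meta) genotypes$id[dropped] else which(dropped)
    message("dropping ", sum(dropped),
            " individual(s) with no scorable call: ",
            paste(utils::head(ids, 10), collapse = ", "))
    out <- out[!dropped, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fit the genotype-score depth cline
#'
#' Fits a logit-link mixed model of genotype score on sampling depth
#' with a random intercept per sampling site (`lme4::glmer`, binomial
#' family; scores in `[0, 1]` are treated as quasi-Bernoulli
#' proportions, so the non-integer-response warning is expected and
#' suppressed).  When the mixed fit fails or is reported unconverged, a
#' fixed-effects logistic regression is used instead and flagged.
#'
#' Sign convention: score 1 = FM-like, 0 = NM-like; depth is elevation
#' in metres (more negative = deeper, towards the sea).  A shift from
#' NM-like towards FM-like genotypes with increasing depth therefore
#' appears as a *negative* slope.
#'
#' @param scores Numeric vector of genotype scores in `[0, 1]` (e.g.
#'   from [genotype_scores()]).
#' @param depths Numeric vector of elevations (metres; negative =
#'   below datum).
#' @param sites Factor or vector of sampling-site identifiers.
#' @param weights Optional per-individual binomial weights (e.g.
#'   `2 * n_loci_scored` to weight by scored allele count); default 1.
#' @return Object of class `cline_fit`: list with `slope`, `intercept`,
#'   `slope_se`, `p_value` (Wald), `site_variance` (random-intercept
#'   variance; 0 for the fallback), `method` (`"glmm"` or
#'   `"glm_fallback"`), `converged`, `n` and the underlying `fit`.
#' @export
fit_depth_cline <- function(scores, depths, sites, weights = NULL) {
  stopifnot(length(scores) == length(depths),
            length(scores) == length(sites),
            all(scores >= 0 & scores <= 1, na.rm = TRUE))
  ok <- !is.na(scores) & !is.na(depths) & !is.na(sites)
  d <- data.frame(score = scores[ok], depth = depths[ok],
                  site = factor(sites[ok]))
  if (length(unique(d$depth)) < 2 || nlevels(d$site) < 2)
    stop("need at least two distinct depths and two sites")
  d$w <- if (is.null(weights)) 1 else weights[ok]

  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(score ~ depth + (1 | site), data = d, weights = w,
                  family = stats::binomial()))),
    error = function(e) NULL)
  method <- "glmm"
  conv <- !is.null(fit) &&
    length(fit@optinfo$conv$lme4) == 0 &&
    fit@optinfo$conv$opt == 0
  if (!conv) {
    fit <- suppressWarnings(
      stats::glm(score ~ depth, data = d, weights = w,
                 family = stats::binomial()))
    method <- "glm_fallback"
  }
  if (method == "glmm") {
    cf <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    site_var <- vc$vcov[vc$grp == "site"][1]
  } else {
    cf <- summary(fit)$coefficients
    site_var <- 0
  }
  structure(list(slope = cf["depth", 1], intercept = cf["(Intercept)", 1],
                 slope_se = cf["depth", 2], p_value = cf["depth", 4],
                 site_variance = site_var, method = method,
                 converged = method == "glmm" || fit$converged,
                 n = nrow(d), fit = fit),
            class = "cline_fit")
}

#' @method print cline_fit
#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("depth cline (%s, n = %d): slope = %.3f (SE %.3f), p = %.3g\n",
              x$method, x$n, x$slope, x$slope_se, x$p_value))
  cat(sprintf("  intercept = %.3f, site variance = %.3f\n",
              x$intercept, x$site_variance))
  invisible(x)
}

#' Serialise a cline fit to JSON
#'
#' @param x A `cline_fit`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
cline_fit_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cline_fit"))
  obj <- x[c("slope", "intercept", "slope_se", "p_value", "site_variance",
             "method", "converged", "n")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
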
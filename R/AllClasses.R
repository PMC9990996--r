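## S4 class definitions and validity methods for the package's central
## data objects.

.REC_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
               "eaf", "beta", "se", "pval", "n")

#' AssocSet: marginal summary statistics for one trait over a region
#'
#' Container for one trait's per-variant marginal association statistics
#' (one row per variant: identifiers, alleles, effect-allele frequency,
#' beta, standard error, p-value, sample size). Betas are on the log-odds
#' scale for binary traits and per phenotype SD for quantitative traits.
#' Records are kept sorted by (chrom, pos) and variant ids are unique.
#'
#' @slot traitId character scalar identifying the trait.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot sdY phenotype SD for quantitative traits (`NA` when unknown).
#' @slot records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot metadata free-form list (e.g. the load report from
#'   [readSumstats()]).
#' @export
setClass("AssocSet",
  representation(traitId = "character", traitType = "character",
                 sdY = "numeric", records = "data.frame",
                 metadata = "list"),
  prototype(traitId = NA_character_, traitType = "quantitative",
            sdY = NA_real_, records = data.frame(), metadata = list()))

.validAssocRecords <- function(rec, checkP = TRUE) {
  missing <- setdiff(.REC_COLS, names(rec))
  if (length(missing))
    return(paste("missing record columns:", paste(missing, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (anyDuplicated(rec$variant_id)) return("variant_ids not unique")
  ok_allele <- c("A", "C", "G", "T")
  if (!all(rec$effect_allele %in% ok_allele) ||
      !all(rec$other_allele %in% ok_allele))
    return("alleles must be single bases A/C/G/T")
  if (any(rec$effect_allele == rec$other_allele))
    return("effect and other allele must differ")
  if (any(!is.finite(rec$se)) || any(rec$se <= 0)) return("se must be > 0")
  if (any(!is.finite(rec$beta))) return("beta must be finite")
  if (any(!is.finite(rec$pval)) || any(rec$pval <= 0) || any(rec$pval > 1))
    return("pval must lie in (0, 1]")
  if (any(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1)))
    return("eaf must lie in (0, 1) or be NA")
  if (any(!is.finite(rec$n)) || any(rec$n <= 0)) return("n must be > 0")
  if (any(rec$pos < 1)) return("pos must be >= 1")
  o <- order(rec$chrom, rec$pos, method = "radix")
  if (!identical(o, seq_len(nrow(rec))))
    return("records must be sorted by (chrom, pos)")
  if (checkP) {
    pz <- twoSidedP(rec$beta / rec$se)
    bad <- rec$pval > 1e-300 & abs(rec$pval - pz) > 0.1 * pz
    if (any(bad))
      return(sprintf("%d record(s) with pval inconsistent with beta/se", sum(bad)))
  }
  TRUE
}

setValidity("AssocSet", function(object) {
  if (length(object@traitId) != 1L) return("traitId must be length 1")
  if (!object@traitType %in% c("quantitative", "binary"))
    return("traitType must be 'quantitative' or 'binary'")
  if (length(object@sdY) != 1L || (!is.na(object@sdY) && object@sdY <= 0))
    return("sdY must be a positive scalar or NA")
  .validAssocRecords(object@records)
})

#' Construct an AssocSet
#'
#' Validates, normalizes (upper-case alleles) and sorts a record table
#' into an [AssocSet-class]. Rows violating the record invariants cause
#' an error; use [readSumstats()] to drop-and-report instead.
#'
#' @param records data.frame of per-variant statistics (see
#'   [AssocSet-class]).
#' @param traitId trait identifier.
#' @param traitType `"quantitative"` (default) or `"binary"`.
#' @param sdY phenotype SD for quantitative traits; default `NA`.
#' @param metadata optional list of free-form metadata.
#' @return an `AssocSet`.
#' @export
AssocSet <- function(records, traitId, traitType = "quantitative",
                     sdY = NA_real_, metadata = list()) {
  records <- as.data.frame(records)[, .REC_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  records <- records[order(records$chrom, records$pos, method = "radix"), ,
                     drop = FALSE]
  rownames(records) <- NULL
  methods::new("AssocSet", traitId = as.character(traitId),
               traitType = traitType, sdY = as.numeric(sdY),
               records = records, metadata = metadata)
}

#' GenomicWindow: a 1-based inclusive genomic interval
#'
#' @slot chrom chromosome name.
#' @slot start,end 1-based inclusive coordinates, `start <= end`.
#' @export
setClass("GenomicWindow",
  representation(chrom = "character", start = "numeric", end = "numeric"))

setValidity("GenomicWindow", function(object) {
  if (length(object@chrom) != 1L) return("chrom must be length 1")
  if (object@start > object@end) return("start must be <= end")
  if (object@start < 1) return("start must be >= 1")
  TRUE
})

#' @rdname GenomicWindow-class
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @return a `GenomicWindow`.
#' @export
genomicWindow <- function(chrom, start, end) {
  methods::new("GenomicWindow", chrom = as.character(chrom),
               start = as.numeric(start), end = as.numeric(end))
}

#' LDMatrix: signed correlation matrix over an ordered variant list
#'
#' @slot variantIds ordered variant identifiers.
#' @slot r symmetric matrix of signed Pearson correlations with unit
#'   diagonal, entries in \[-1, 1\].
#' @export
setClass("LDMatrix",
  representation(variantIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  r <- object@r
  m <- length(object@variantIds)
  if (!identical(dim(r), c(m, m))) return("r dimensions must match variantIds")
  if (anyDuplicated(object@variantIds)) return("variantIds not unique")
  if (m == 0L) return(TRUE)
  if (max(abs(r - t(r))) > 1e-12) return("r must be symmetric within 1e-12")
  if (any(diag(r) != 1)) return("diagonal must be exactly 1")
  if (any(r < -1) || any(r > 1)) return("entries must lie in [-1, 1]")
  TRUE
})

#' Construct an LDMatrix
#'
#' Symmetrizes tiny numerical asymmetries, clamps entries to \[-1, 1\]
#' and forces a unit diagonal before validation.
#'
#' @param r square correlation matrix.
#' @param variantIds variant identifiers for the rows/columns.
#' @return an `LDMatrix`.
#' @export
LDMatrix <- function(r, variantIds = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(nrow(r)))
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(variantIds, variantIds)
  methods::new("LDMatrix", variantIds = as.character(variantIds), r = r)
}

#' ClumpResult: greedy LD-clumping output
#'
#' @slot indexVariants index variant ids, ordered by ascending p-value.
#' @slot assignments named character vector mapping each pruned variant
#'   to the index variant that absorbed it.
#' @export
setClass("ClumpResult",
  representation(indexVariants = "character", assignments = "character"))

#' MRResult: one exposure-outcome Mendelian randomization estimate
#'
#' @slot exposureId,outcomeId identifiers of the exposure and outcome.
#' @slot method `"wald"` or `"ivw"`.
#' @slot nSnps number of instruments used.
#' @slot beta,se,pval causal-effect estimate, its standard error, and
#'   two-sided normal p-value.
#' @slot passesBonferroni whether `pval < bonferroniThreshold`.
#' @slot bonferroniThreshold the family-wise threshold applied (`NA`
#'   for a stand-alone estimate).
#' @slot notes character vector of analysis notes (e.g. a
#'   weak-instrument warning).
#' @export
setClass("MRResult",
  representation(exposureId = "character", outcomeId = "character",
                 method = "character", nSnps = "integer",
                 beta = "numeric", se = "numeric", pval = "numeric",
                 passesBonferroni = "logical",
                 bonferroniThreshold = "numeric", notes = "character"))

setValidity("MRResult", function(object) {
  if (!object@method %in% c("wald", "ivw")) return("method must be wald/ivw")
  if (object@nSnps < 1L) return("nSnps must be >= 1")
  if (object@se <= 0) return("se must be > 0")
  pz <- twoSidedP(object@beta / object@se)
  if (abs(object@pval - pz) > 1e-10 * pz)
    return("pval inconsistent with beta/se")
  TRUE
})

#' ColocPriors: per-configuration priors for pairwise colocalization
#'
#' @param p1,p2 prior probability that a variant is causal for trait 1
#'   (resp. 2) only; default 1e-4.
#' @param p12 prior probability that a variant is causal for both;
#'   default 1e-5. Must satisfy `0 < p12 <= min(p1, p2) < 1`.
#' @return a named list with elements `p1`, `p2`, `p12`.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= p1, p12 <= p2, p1 < 1, p2 < 1)
  list(p1 = p1, p2 = p2, p12 = p12)
}

#' ColocResult: posterior probabilities over the 5 pairwise hypotheses
#'
#' Hypotheses: H0 no association; H1 trait-1 only; H2 trait-2 only;
#' H3 two distinct causal variants; H4 one shared causal variant.
#'
#' @slot pp named numeric vector `PP.H0` ... `PP.H4`, summing to 1.
#' @slot nSnps number of shared variants used.
#' @slot priors the [colocPriors()] list used.
#' @export
setClass("ColocResult",
  representation(pp = "numeric", nSnps = "integer", priors = "list"))

setValidity("ColocResult", function(object) {
  if (length(object@pp) != 5L) return("pp must have length 5")
  if (abs(sum(object@pp) - 1) > 1e-10) return("pp must sum to 1 within 1e-10")
  if (any(object@pp < 0) || any(object@pp > 1)) return("pp must lie in [0,1]")
  TRUE
})

#' MolocResult: multi-trait colocalization posteriors
#'
#' @slot posteriors named numeric vector over the sharing configurations
#'   (15 for three traits), summing to 1. Names use `/` to separate
#'   distinct-variant groups and `,` to join traits sharing one variant
#'   (e.g. `"E,M/G"`); `"null"` is the no-association configuration.
#' @slot ppaFull posterior of the single configuration in which all
#'   traits share one causal variant.
#' @slot cpgId CpG probe evaluated (`NA` outside CpG scans).
#' @slot nSnps number of shared variants used.
#' @export
setClass("MolocResult",
  representation(posteriors = "numeric", ppaFull = "numeric",
                 cpgId = "character", nSnps = "integer"))

setValidity("MolocResult", function(object) {
  if (abs(sum(object@posteriors) - 1) > 1e-10)
    return("posteriors must sum to 1 within 1e-10")
  TRUE
})

#' EffectMatrix: gene-by-trait MR effect matrix for clustering
#'
#' @slot values per-column standardized MR betas with missing cells
#'   imputed to 0 (for distance computation only).
#' @slot raw the unstandardized betas with `NA` for missing cells.
#' @slot mask logical matrix, `TRUE` where an estimate was available.
#' @export
setClass("EffectMatrix",
  representation(values = "matrix", raw = "matrix", mask = "matrix"))

setValidity("EffectMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values/mask dimensions differ")
  if (nrow(object@values) && any(rowSums(object@mask) == 0))
    return("every retained row needs at least one observed cell")
  TRUE
})

#' ScenarioConfig: full specification of a simulated cis-region
#'
#' Defines the LD structure, allele frequencies and causal assignments
#' from which [simulateSummaryStats()] draws marginal summary statistics
#' for 1-3 traits.
#'
#' @slot m number of variants in the region.
#' @slot ldRho AR(1) LD decay parameter in \[0, 1).
#' @slot mafRange minor-allele-frequency range (lo, hi) in (0, 0.5\].
#' @slot traits list of per-trait specs: `trait_id`, `trait_type`, `n`
#'   (effective sample size; for binary traits supply `n_cases` and
#'   `n_controls` instead), `causal_pos` (integer variant indices),
#'   `causal_beta` (standardized per-allele effects), optional `sd_y`,
#'   optional `coverage` list (`center_pos`, `window_bp`, `p_max`)
#'   emulating truncated QTL release formats.
#' @slot mediationTheta when not `NA`, the last trait's causal effects
#'   are replaced by `theta` times the first trait's (vertical
#'   pleiotropy with known causal ratio).
#' @slot seed RNG seed (`NA` to use the caller's RNG state).
#' @export
setClass("ScenarioConfig",
  representation(m = "integer", ldRho = "numeric", mafRange = "numeric",
                 traits = "list", mediationTheta = "numeric",
                 seed = "numeric"))

setValidity("ScenarioConfig", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@ldRho < 0 || object@ldRho >= 1) return("ldRho must be in [0,1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    return("mafRange must be (lo, hi) within (0, 0.5]")
  if (length(object@traits) < 1L) return("at least one trait required")
  for (tr in object@traits) {
    if (is.null(tr$trait_id)) return("each trait needs trait_id")
    n <- .effectiveN(tr)
    if (!is.finite(n) || n <= 0) return("each trait needs n > 0")
    if (length(tr$causal_pos)) {
      if (any(tr$causal_pos < 1) || any(tr$causal_pos > object@m))
        return("causal positions must lie within the region")
      if (length(tr$causal_pos) != length(tr$causal_beta))
        return("causal_pos and causal_beta lengths differ")
    }
  }
  TRUE
})

.effectiveN <- function(tr) {
  if (!is.null(tr$n_cases) && !is.null(tr$n_controls))
    return(4 / (1 / tr$n_cases + 1 / tr$n_controls))
  if (!is.null(tr$n)) return(tr$n)
  NA_real_
}

#' @rdname ScenarioConfig-class
#' @param m,ldRho,mafRange,traits,mediationTheta,seed see slots above.
#' @return a `ScenarioConfig`.
#' @export
scenarioConfig <- function(m, ldRho, traits, mafRange = c(0.05, 0.5),
                           mediationTheta = NA_real_, seed = NA_real_) {
  methods::new("ScenarioConfig", m = as.integer(m), ldRho = as.numeric(ldRho),
               mafRange = as.numeric(mafRange), traits = traits,
               mediationTheta = as.numeric(mediationTheta),
               seed = as.numeric(seed))
}

#' SimulatedRegion: simulator output with recorded truth
#'
#' @slot ld the true [LDMatrix-class] of the region.
#' @slot panel reference dosage matrix (individuals x variants) or
#'   `NULL` when no panel was requested.
#' @slot assoc named list of [AssocSet-class] objects, one per trait.
#' @slot truth list recording per-trait causal indices/ids and
#'   standardized effects, allele frequencies and the mediation ratio.
#' @export
setClass("SimulatedRegion",
  representation(ld = "LDMatrix", panel = "ANY", assoc = "list",
                 truth = "list"))

setValidity("SimulatedRegion", function(object) {
  for (a in object@assoc)
    if (!all(a@records$variant_id %in% object@ld@variantIds))
      return("assoc variant ids must be a subset of ld variant ids")
  TRUE
})
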
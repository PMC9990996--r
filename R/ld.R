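## LD estimation from a reference panel, greedy clumping, and
## approximate conditional analysis of marginal summary statistics.

#' Estimate LD from reference-panel dosages
#'
#' Computes the signed Pearson correlation between dosage columns.
#' Monomorphic variants (zero variance) are excluded with a warning.
#'
#' @param dosages numeric matrix, individuals x variants, entries in
#'   \[0, 2\].
#' @param variantIds variant identifiers for the columns; defaults to
#'   the column names.
#' @return an [LDMatrix-class] over the retained variants.
#' @export
estimateLD <- function(dosages, variantIds = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(ncol(dosages)))
  stopifnot(ncol(dosages) >= 1L, length(variantIds) == ncol(dosages))
  v <- apply(dosages, 2L, stats::var)
  mono <- v <= 0 | !is.finite(v)
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) excluded from LD: ",
            paste(variantIds[mono], collapse = ", "))
    dosages <- dosages[, !mono, drop = FALSE]
    variantIds <- variantIds[!mono]
  }
  if (ncol(dosages) == 0L) stop("no polymorphic variants left")
  LDMatrix(stats::cor(dosages), variantIds)
}

#' Read a reference genotype panel as a dosage matrix
#'
#' Accepts either a VCF (dosages from the DS field when present,
#' otherwise ALT-allele counts from GT) or a plain tab-delimited dosage
#' matrix (individuals x variants, header row of variant ids).
#'
#' @param path file path (`.vcf` or TSV).
#' @return numeric dosage matrix, individuals x variants, columns named
#'   by variant id.
#' @export
readDosagePanel <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ids <- vcfR::getID(vcf)
    fmt <- vcf@gt[, "FORMAT"]
    if (all(grepl("DS", fmt))) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- apply(gt, c(1, 2), function(g)
        if (is.na(g)) NA_real_
        else sum(strsplit(g, "[/|]")[[1]] != "0"))
    }
    dos <- t(ds)
    colnames(dos) <- ids
    return(dos)
  }
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Greedy LD clumping of association statistics
#'
#' PLINK-style greedy clumping: repeatedly take the unassigned variant
#' with the smallest p-value at or below `pIndex` as an index variant,
#' and assign to it every unassigned variant within `windowKb` whose
#' squared correlation with the index is at least `r2Thresh`. Ties in p
#' are broken by smaller position, then lexicographic variant id, so
#' the output is deterministic and invariant to record order. All
#' pairwise r-squared values among index variants are below `r2Thresh`.
#'
#' @param assoc an [AssocSet-class]; its variants must be a subset of
#'   the LD matrix's.
#' @param ld an [LDMatrix-class] from a reference panel.
#' @param pIndex index-variant p-value threshold; default 5e-8 (the
#'   genome-wide instrument threshold).
#' @param r2Thresh r-squared above which a variant is absorbed into a
#'   clump; default 0.01.
#' @param windowKb clumping window in kb around each index; default
#'   1000.
#' @return a [ClumpResult-class]; empty when no variant reaches
#'   `pIndex`.
#' @export
clumpVariants <- function(assoc, ld, pIndex = 5e-8, r2Thresh = 0.01,
                          windowKb = 1000) {
  rec <- records(assoc)
  if (!all(rec$variant_id %in% variantIds(ld)))
    stop("assoc variants must be a subset of the LD matrix variants")
  r <- corMatrix(ld)[rec$variant_id, rec$variant_id, drop = FALSE]
  o <- .orderByP(rec$pval, rec$pos, rec$variant_id,
                 zabs = abs(rec$beta / rec$se))
  assigned <- rep(FALSE, nrow(rec))
  index <- character(0)
  assignment <- character(0)
  for (i in o) {
    if (assigned[i] || rec$pval[i] > pIndex) next
    assigned[i] <- TRUE
    index <- c(index, rec$variant_id[i])
    near <- !assigned &
      abs(rec$pos - rec$pos[i]) <= windowKb * 1000 &
      r[i, ]^2 >= r2Thresh
    if (any(near)) {
      assignment <- c(assignment,
                      stats::setNames(rep(rec$variant_id[i], sum(near)),
                                      rec$variant_id[near]))
      assigned[near] <- TRUE
    }
  }
  methods::new("ClumpResult", indexVariants = index,
               assignments = assignment)
}

.conditionMatrix <- function(ld, conditionIdx) {
  R <- corMatrix(ld)
  Rcc <- R[conditionIdx, conditionIdx, drop = FALSE]
  if (kappa(Rcc) > 1e8) Rcc <- Rcc + diag(1e-6, nrow(Rcc)) # ridge guard
  solve(Rcc)
}

#' Approximate conditional z-score
#'
#' Adjusts a target variant's z-score for the effects of a condition
#' set using reference-panel LD:
#' \deqn{z_{j|C} = \frac{z_j - r_{jC} R_{CC}^{-1} z_C}
#'                    {\sqrt{1 - r_{jC} R_{CC}^{-1} r_{Cj}}}}
#' A ridge of 1e-6 is added to \eqn{R_{CC}} when its condition number
#' exceeds 1e8. A z-score-scale approximation of summary-statistics
#' conditional analysis (the full joint estimator also rescales by the
#' residual variance).
#'
#' @param z numeric vector of z-scores, ordered as `ld`.
#' @param ld an [LDMatrix-class].
#' @param conditionIdx integer indices (into `z`) of the condition set;
#'   empty set returns `z[targetIdx]` unchanged.
#' @param targetIdx integer index of the target variant (not in the
#'   condition set).
#' @return the adjusted z-score.
#' @export
conditionalZ <- function(z, ld, conditionIdx, targetIdx) {
  stopifnot(length(targetIdx) == 1L, !(targetIdx %in% conditionIdx),
            length(z) == nVariants(ld))
  if (length(conditionIdx) == 0L) return(z[targetIdx])
  R <- corMatrix(ld)
  RccInv <- .conditionMatrix(ld, conditionIdx)
  rjc <- R[targetIdx, conditionIdx, drop = FALSE]
  denom2 <- 1 - drop(rjc %*% RccInv %*% t(rjc))
  if (denom2 <= 1e-6)
    stop("collinearity error: target variant nearly collinear with the ",
         "condition set")
  (z[targetIdx] - drop(rjc %*% RccInv %*% z[conditionIdx])) / sqrt(denom2)
}

#' Condition an association set on selected variants
#'
#' Replaces every record's z-score by its conditional z given the
#' condition variants ([conditionalZ()]), recomputes `beta` as
#' `z * se` (original standard errors retained) and the p-value from
#' the normal tail, and removes the condition variants from the output.
#' Condition variants absent from `assoc` are ignored for this trait.
#'
#' @param assoc an [AssocSet-class].
#' @param ld an [LDMatrix-class] covering the assoc variants.
#' @param conditionIds variant ids to condition on; empty input returns
#'   `assoc` unchanged.
#' @return the conditioned `AssocSet`.
#' @export
conditionalAssoc <- function(assoc, ld, conditionIds) {
  rec <- records(assoc)
  conditionIds <- intersect(conditionIds, rec$variant_id)
  if (length(conditionIds) == 0L) return(assoc)
  if (!all(rec$variant_id %in% variantIds(ld)))
    stop("assoc variants must be a subset of the LD matrix variants")
  sub <- LDMatrix(corMatrix(ld)[rec$variant_id, rec$variant_id,
                                drop = FALSE], rec$variant_id)
  z <- rec$beta / rec$se
  cIdx <- match(conditionIds, rec$variant_id)
  targets <- setdiff(seq_len(nrow(rec)), cIdx)
  ## vectorized form of conditionalZ over all targets at once
  R <- corMatrix(sub)
  RccInv <- .conditionMatrix(sub, cIdx)
  Rtc <- R[targets, cIdx, drop = FALSE]
  denom2 <- 1 - rowSums((Rtc %*% RccInv) * Rtc)
  if (any(denom2 <= 1e-6))
    stop("collinearity error: variant(s) nearly collinear with the ",
         "condition set: ",
         paste(rec$variant_id[targets][denom2 <= 1e-6], collapse = ", "))
  zc <- (z[targets] - drop(Rtc %*% RccInv %*% z[cIdx])) / sqrt(denom2)
  out <- rec[targets, , drop = FALSE]
  out$beta <- zc * out$se
  out$pval <- twoSidedP(zc)
  rownames(out) <- NULL
  methods::initialize(assoc, records = out)
}
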
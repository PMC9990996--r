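## Summary-statistics I/O, allele harmonization and cis-window
## extraction.

#' Column-name mapping for summary-statistics files
#'
#' @param snp,chr,bp,ea,oa,eaf,beta,se,p,n column names in the file for
#'   variant id, chromosome, position, effect allele, other allele,
#'   effect-allele frequency, beta, standard error, p-value and sample
#'   size.
#' @return named character vector mapping internal fields to file
#'   columns.
#' @export
sumstatDialect <- function(snp = "SNP", chr = "CHR", bp = "BP", ea = "EA",
                           oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                           p = "P", n = "N") {
  c(variant_id = snp, chrom = chr, pos = bp, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = p, n = n)
}

#' Read marginal summary statistics from a tab-delimited file
#'
#' Loads a GWAS/QTL summary-statistics table, normalizes alleles to
#' upper case, drops rows that violate the record invariants (se <= 0,
#' identical alleles, p outside (0,1], p inconsistent with beta/se
#' beyond 10\% relative tolerance, non-positive n, out-of-range eaf) and
#' returns a validated [AssocSet-class]. The drop counts are recorded in
#' a load report retrievable with [loadReport()].
#'
#' @param path file path of a tab-delimited table with a header row.
#' @param traitId trait identifier for the resulting set.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param sdY phenotype SD (quantitative traits), default `NA`.
#' @param dialect column mapping from [sumstatDialect()].
#' @return an `AssocSet`; `loadReport(x)` gives `n_read`, `n_kept`,
#'   `drop_count` and per-reason counts.
#' @export
readSumstats <- function(path, traitId, traitType = "quantitative",
                         sdY = NA_real_, dialect = sumstatDialect()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing))
    stop("summary-statistics format error: missing column(s) ",
         paste(missing, collapse = ", "))
  rec <- stats::setNames(raw[, unname(dialect), drop = FALSE], names(dialect))
  rec$variant_id <- as.character(rec$variant_id)
  rec$chrom <- as.character(rec$chrom)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))

  bases <- c("A", "C", "G", "T")
  reasons <- list(
    bad_allele = !(rec$effect_allele %in% bases &
                     rec$other_allele %in% bases) |
      rec$effect_allele == rec$other_allele,
    bad_se = !is.finite(rec$se) | rec$se <= 0,
    bad_beta = !is.finite(rec$beta),
    bad_pval = !is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1,
    bad_eaf = !is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1),
    bad_n = !is.finite(rec$n) | rec$n <= 0,
    bad_pos = !is.finite(rec$pos) | rec$pos < 1,
    dup_id = duplicated(rec$variant_id)
  )
  drop <- Reduce(`|`, reasons)
  ok <- !drop
  ## p/beta/se consistency checked only on otherwise-valid rows
  pz <- twoSidedP(ifelse(ok, rec$beta / rec$se, 0))
  inconsistent <- ok & rec$pval > 1e-300 & abs(rec$pval - pz) > 0.1 * pz
  reasons$p_inconsistent <- inconsistent
  drop <- drop | inconsistent

  kept <- rec[!drop, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("empty-input error: no valid summary-statistic rows in ", path)
  report <- list(n_read = nrow(rec), n_kept = nrow(kept),
                 drop_count = sum(drop),
                 drop_reasons = vapply(reasons, sum, integer(1)))
  AssocSet(kept, traitId = traitId, traitType = traitType, sdY = sdY,
           metadata = list(load_report = report))
}

#' Write an AssocSet back to the tab-delimited dialect
#'
#' Numeric fields are written with full double precision so that a
#' write/read round trip is bit-identical on valid rows.
#'
#' @param assoc an [AssocSet-class].
#' @param path output file path.
#' @param dialect column mapping from [sumstatDialect()].
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(assoc, path, dialect = sumstatDialect()) {
  rec <- records(assoc)
  out <- rec
  for (col in c("eaf", "beta", "se", "pval", "n"))
    out[[col]] <- sprintf("%.17g", rec[[col]])
  out$pos <- sprintf("%d", as.integer(rec$pos))
  names(out) <- dialect[names(rec)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene/CpG coordinates from a BED-like TSV
#'
#' Expects four tab-separated columns: chrom, start, end, feature_id
#' (1-based inclusive coordinates, with a header row).
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `feature_id`.
#' @export
readFeatureCoords <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "feature_id")
  if (!all(need %in% names(df)))
    stop("feature-coordinate format error: need columns ",
         paste(need, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df[, need]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs the two traits' records on shared `variant_id`s and aligns the
#' outcome's effects to the exposure's effect allele. If the outcome's
#' alleles are swapped (directly or on the opposite strand) the outcome
#' beta is negated and its effect-allele frequency complemented.
#' Palindromic variants (A/T or C/G) are aligned through effect-allele
#' frequency when both frequencies are informative, and dropped as
#' ambiguous when either frequency is missing or lies inside
#' `palindromeEafRange`. Allele sets that cannot be reconciled are
#' dropped. Harmonizing already-harmonized data is a no-op (the
#' operation is an involution).
#'
#' @param exposure,outcome [AssocSet-class] objects.
#' @param palindromeEafRange frequency window treated as strand-
#'   ambiguous for palindromic variants; default `c(0.42, 0.58)`.
#' @return data.frame with one row per retained shared variant:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf_exp`, `beta_exp`, `se_exp`, `pval_exp`, `n_exp` and the
#'   matching `_out` columns (outcome aligned to the exposure allele).
#'   Attribute `"report"` carries drop counts by reason.
#' @export
harmonizeSumstats <- function(exposure, outcome,
                              palindromeEafRange = c(0.42, 0.58)) {
  ex <- records(exposure)
  ou <- records(outcome)
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L)
    stop("empty-intersection error: no shared variants between '",
         traitId(exposure), "' and '", traitId(outcome), "'")
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- ou[match(shared, ou$variant_id), , drop = FALSE]

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  flip_ea <- .complementAllele(ou$effect_allele)
  flip_oa <- .complementAllele(ou$other_allele)
  strand <- !same & !swap & ex$effect_allele == flip_ea &
    ex$other_allele == flip_oa
  strand_swap <- !same & !swap & ex$effect_allele == flip_oa &
    ex$other_allele == flip_ea

  pal <- .isPalindromic(ex$effect_allele, ex$other_allele)
  ambiguous_eaf <- function(f) {
    is.na(f) | (f >= palindromeEafRange[1] & f <= palindromeEafRange[2])
  }
  drop_pal <- pal & (ambiguous_eaf(ex$eaf) | ambiguous_eaf(ou$eaf))
  irreconcilable <- !(same | swap | strand | strand_swap)

  ## strand flips are a no-op for non-palindromic variants; for
  ## palindromic variants same/swap vs strand/strand_swap are
  ## indistinguishable from alleles, so eaf decides
  needs_flip <- swap | strand_swap
  pal_keep <- pal & !drop_pal
  eaf_out_aligned <- ifelse(needs_flip, 1 - ou$eaf, ou$eaf)
  freq_discordant <- pal_keep &
    sign(ex$eaf - 0.5) * sign(eaf_out_aligned - 0.5) < 0
  freq_discordant[is.na(freq_discordant)] <- FALSE
  needs_flip <- xor(needs_flip, freq_discordant)

  keep <- !(drop_pal | irreconcilable)
  out <- data.frame(
    variant_id = ex$variant_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf_exp = ex$eaf, beta_exp = ex$beta, se_exp = ex$se,
    pval_exp = ex$pval, n_exp = ex$n,
    eaf_out = ifelse(needs_flip, 1 - ou$eaf, ou$eaf),
    beta_out = ifelse(needs_flip, -ou$beta, ou$beta),
    se_out = ou$se, pval_out = ou$pval, n_out = ou$n,
    stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    stop("empty-intersection error: all shared variants dropped during ",
         "harmonization")
  attr(out, "report") <- list(
    n_shared = length(shared), n_kept = nrow(out),
    n_palindromic_dropped = sum(drop_pal),
    n_irreconcilable = sum(irreconcilable & !drop_pal),
    n_flipped = sum(needs_flip & keep))
  out
}

#' Write a harmonized pair table as TSV
#'
#' @param pairs output of [harmonizeSumstats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the cis-window of a feature from an association set
#'
#' Returns the records lying within `flankBp` of the feature interval
#' (1-based inclusive on both ends) on the feature's chromosome,
#' preserving record order. The default 1 Mb flank is the conventional
#' cis-QTL window.
#'
#' @param assoc an [AssocSet-class].
#' @param feature a [GenomicWindow-class] giving the feature's
#'   coordinates.
#' @param flankBp flank in base pairs either side of the feature;
#'   default 1e6.
#' @return an `AssocSet` restricted to the cis-window (possibly empty).
#' @export
extractCisWindow <- function(assoc, feature, flankBp = 1e6) {
  stopifnot(methods::is(feature, "GenomicWindow"), flankBp >= 0)
  rec <- records(assoc)
  keep <- rec$chrom == feature@chrom &
    rec$pos >= feature@start - flankBp &
    rec$pos <= feature@end + flankBp
  methods::initialize(assoc, records = {
    r <- rec[keep, , drop = FALSE]; rownames(r) <- NULL; r
  })
}
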
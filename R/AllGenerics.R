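## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for omicsMR S4 objects
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an omicsMR S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("sdY", function(x) standardGeneric("sdY"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))
#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))
#' @rdname accessors
#' @export
setGeneric("indexVariants", function(x) standardGeneric("indexVariants"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))
#' @rdname accessors
#' @export
setGeneric("ppaFull", function(x) standardGeneric("ppaFull"))
#' @rdname accessors
#' @export
setGeneric("effectValues", function(x) standardGeneric("effectValues"))
#' @rdname accessors
#' @export
setGeneric("effectMask", function(x) standardGeneric("effectMask"))
#' @rdname accessors
#' @export
setGeneric("simAssoc", function(x) standardGeneric("simAssoc"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("simLD", function(x) standardGeneric("simLD"))

#' @rdname accessors
#' @export
setMethod("traitId", "AssocSet", function(x) x@traitId)
#' @rdname accessors
#' @export
setMethod("traitType", "AssocSet", function(x) x@traitType)
#' @rdname accessors
#' @export
setMethod("sdY", "AssocSet", function(x) x@sdY)
#' @rdname accessors
#' @export
setMethod("records", "AssocSet", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("variantIds", "AssocSet", function(x) x@records$variant_id)
#' @rdname accessors
#' @export
setMethod("nVariants", "AssocSet", function(x) nrow(x@records))
#' @rdname accessors
#' @export
setMethod("loadReport", "AssocSet", function(x) x@metadata$load_report)

#' @rdname accessors
#' @export
setMethod("variantIds", "LDMatrix", function(x) x@variantIds)
#' @rdname accessors
#' @export
setMethod("nVariants", "LDMatrix", function(x) length(x@variantIds))
#' @rdname accessors
#' @export
setMethod("corMatrix", "LDMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("indexVariants", "ClumpResult", function(x) x@indexVariants)
#' @rdname accessors
#' @export
setMethod("assignments", "ClumpResult", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("posteriorProbs", "ColocResult", function(x) x@pp)
#' @rdname accessors
#' @export
setMethod("posteriorProbs", "MolocResult", function(x) x@posteriors)
#' @rdname accessors
#' @export
setMethod("ppaFull", "MolocResult", function(x) x@ppaFull)

#' @rdname accessors
#' @export
setMethod("effectValues", "EffectMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("effectMask", "EffectMatrix", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("simAssoc", "SimulatedRegion", function(x) x@assoc)
#' @rdname accessors
#' @export
setMethod("simTruth", "SimulatedRegion", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("simLD", "SimulatedRegion", function(x) x@ld)

setMethod("show", "AssocSet", function(object) {
  cat(sprintf("AssocSet '%s' (%s): %d variants\n", object@traitId,
              object@traitType, nrow(object@records)))
  if (nrow(object@records)) {
    r <- object@records
    cat(sprintf("  region: chr%s:%s-%s\n", r$chrom[1],
                format(min(r$pos), big.mark = ","),
                format(max(r$pos), big.mark = ",")))
    cat(sprintf("  min p: %.3g at %s\n", min(r$pval),
                r$variant_id[which.min(r$pval)]))
  }
})

setMethod("show", "GenomicWindow", function(object) {
  cat(sprintf("GenomicWindow chr%s:%d-%d\n", object@chrom,
              as.integer(object@start), as.integer(object@end)))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@variantIds)))
})

setMethod("show", "ClumpResult", function(object) {
  cat(sprintf("ClumpResult: %d index variant(s), %d pruned\n",
              length(object@indexVariants), length(object@assignments)))
  if (length(object@indexVariants))
    cat("  index:", paste(object@indexVariants, collapse = ", "), "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult %s -> %s [%s, %d SNP(s)]\n", object@exposureId,
              object@outcomeId, object@method, object@nSnps))
  cat(sprintf("  beta = %.4g (se %.4g), p = %.3g\n", object@beta,
              object@se, object@pval))
  if (!is.na(object@bonferroniThreshold))
    cat(sprintf("  Bonferroni %.3g: %s\n", object@bonferroniThreshold,
                if (isTRUE(object@passesBonferroni)) "pass" else "fail"))
  for (nt in object@notes) cat("  note:", nt, "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult over %d shared variant(s)\n", object@nSnps))
  print(round(object@pp, 4))
})

setMethod("show", "MolocResult", function(object) {
  cat(sprintf("MolocResult over %d shared variant(s)%s\n", object@nSnps,
              if (is.na(object@cpgId)) "" else paste0(" [CpG ", object@cpgId, "]")))
  cat(sprintf("  PPA(all traits share one variant) = %.4f\n", object@ppaFull))
  top <- sort(object@posteriors, decreasing = TRUE)[1:3]
  cat("  top configurations:\n")
  for (i in seq_along(top))
    cat(sprintf("    %-8s %.4f\n", names(top)[i], top[i]))
})

setMethod("show", "EffectMatrix", function(object) {
  cat(sprintf("EffectMatrix: %d gene(s) x %d trait(s), %d missing cell(s)\n",
              nrow(object@values), ncol(object@values), sum(!object@mask)))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: m = %d, AR(1) rho = %.2f, %d trait(s)\n",
              object@m, object@ldRho, length(object@traits)))
  for (tr in object@traits)
    cat(sprintf("  %s (%s, n_eff = %.0f): %d causal variant(s)\n",
                tr$trait_id, tr$trait_type %||% "quantitative",
                .effectiveN(tr), length(tr$causal_pos)))
  if (!is.na(object@mediationTheta))
    cat(sprintf("  mediation ratio theta = %.3g\n", object@mediationTheta))
})

setMethod("show", "SimulatedRegion", function(object) {
  cat(sprintf("SimulatedRegion: %d variants, traits: %s\n",
              length(object@ld@variantIds),
              paste(names(object@assoc), collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an MRResult to a one-row data.frame
#'
#' @param x an [MRResult-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return a one-row data.frame with all result fields.
#' @export
as.data.frame.MRResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(exposure_id = x@exposureId, outcome_id = x@outcomeId,
             method = x@method, n_snps = x@nSnps, beta = x@beta, se = x@se,
             pval = x@pval, passes_bonferroni = x@passesBonferroni,
             bonferroni_threshold = x@bonferroniThreshold,
             stringsAsFactors = FALSE)
}
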
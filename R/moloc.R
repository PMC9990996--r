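## Multi-trait colocalization over all sharing configurations, CpG
## scanning, and conditional decomposition of multi-signal loci.

## All set partitions of a character vector, in a deterministic
## recursive order (first element joins each existing block in turn,
## then opens a new block).
.setPartitions <- function(els) {
  if (length(els) == 0L) return(list(list()))
  if (length(els) == 1L) return(list(list(els)))
  rest <- .setPartitions(els[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(els[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(els[1L]), p)
  }
  out
}

.configLabel <- function(groups) {
  if (length(groups) == 0L) return("null")
  paste(vapply(groups, paste, "", collapse = ","), collapse = "/")
}

#' Enumerate causal-sharing configurations for k traits
#'
#' A configuration chooses a subset S of the traits (those with any
#' association) and partitions S into groups, each group sharing one
#' distinct causal variant. For k = 2 this yields the 5 pairwise
#' hypotheses H0-H4; for k = 3 it yields 15 configurations
#' (1 null + 3 singles + 6 pair patterns + 5 three-trait partitions).
#'
#' @param k number of traits (1 to 4; k = 4 is supported for
#'   combinatorial checking only).
#' @param labels trait labels; default `c("E","M","G","Z")[1:k]`
#'   (expression, methylation, GWAS trait).
#' @return list of configurations, each a list with `groups` (list of
#'   character vectors, traits in canonical order) and `label` (groups
#'   joined by `/`, members by `,`; the empty configuration is
#'   `"null"`). Deterministic canonical ordering.
#' @export
enumerateConfigs <- function(k, labels = c("E", "M", "G", "Z")[seq_len(k)]) {
  stopifnot(k >= 1L, k <= 4L, length(labels) == k)
  configs <- list(list(groups = list(), label = "null"))
  for (size in seq_len(k)) {
    subsets <- utils::combn(labels, size, simplify = FALSE)
    for (s in subsets) {
      for (p in .setPartitions(s)) {
        groups <- lapply(p, function(g) g[order(match(g, labels))])
        groups <- groups[order(vapply(groups,
                                      function(g) min(match(g, labels)), 1))]
        configs[[length(configs) + 1L]] <-
          list(groups = groups, label = .configLabel(groups))
      }
    }
  }
  configs
}

## log of sum over assignments of distinct variants to groups of the
## product of grouped per-variant weights (inclusion-exclusion over
## coincident variants; exact, no O(m^r) loop). ug: list of log-weight
## vectors, one per group, aligned on the same variants.
.logDistinctSum <- function(ug) {
  r <- length(ug)
  if (r == 0L) return(0)
  if (r == 1L) return(.logSumExp(ug[[1L]]))
  S <- vapply(ug, .logSumExp, numeric(1))
  if (r == 2L)
    return(.logDiffExp(S[1] + S[2], .logSumExp(ug[[1L]] + ug[[2L]])))
  if (r == 3L) {
    D12 <- .logSumExp(ug[[1L]] + ug[[2L]])
    D13 <- .logSumExp(ug[[1L]] + ug[[3L]])
    D23 <- .logSumExp(ug[[2L]] + ug[[3L]])
    D123 <- .logSumExp(ug[[1L]] + ug[[2L]] + ug[[3L]])
    res <- .signedLogSum(
      c(S[1] + S[2] + S[3], S[1] + D23, S[2] + D13, S[3] + D12,
        log(2) + D123),
      c(1, -1, -1, -1, 1))
    return(if (res[2] > 0) res[1] else -Inf)
  }
  stop("distinct-variant sums implemented for up to 3 groups")
}

#' Multi-trait colocalization
#'
#' Evaluates all causal-sharing configurations for 2-3 traits. Each
#' configuration's likelihood (relative to the null) is the product
#' over its groups of the per-cardinality prior, times the sum over
#' assignments of distinct variants to groups of the product of the
#' grouped traits' per-variant ABFs; posteriors are normalized over all
#' configurations. Variants are matched on `variant_id` across all
#' traits (intersection).
#'
#' @param assocList named list of 2 or 3 [AssocSet-class] objects (for
#'   the canonical three-trait analysis: expression, methylation, GWAS
#'   trait).
#' @param priors per-cardinality prior weights: probability that a
#'   variant is causal for exactly one trait, shared by exactly two,
#'   shared by all three; default `c(1e-4, 1e-6, 1e-7)`.
#' @param priorSds optional numeric vector of effect-prior SDs per
#'   trait; default from [priorSdForTrait()].
#' @param cpgId CpG identifier recorded in the result (`NA` outside CpG
#'   scans).
#' @return a [MolocResult-class]; `ppaFull(x)` is the posterior of the
#'   single configuration in which all traits share one causal variant.
#' @export
molocTest <- function(assocList, priors = c(1e-4, 1e-6, 1e-7),
                      priorSds = NULL, cpgId = NA_character_) {
  k <- length(assocList)
  stopifnot(k >= 2L, k <= 3L, !is.null(names(assocList)),
            length(priors) >= k)
  abfs <- lapply(seq_len(k), function(i)
    .abfVector(assocList[[i]], priorSds[i]))
  shared <- Reduce(intersect, lapply(abfs, names))
  if (length(shared) == 0L)
    stop("empty-intersection error: no variants shared by all traits")
  abfs <- lapply(abfs, function(l) l[shared])
  names(abfs) <- names(assocList)

  configs <- enumerateConfigs(k, labels = names(assocList))
  logL <- vapply(configs, function(cf) {
    if (length(cf$groups) == 0L) return(0)
    ug <- lapply(cf$groups, function(g)
      Reduce(`+`, abfs[g]))
    logPrior <- sum(log(priors[vapply(cf$groups, length, 1L)]))
    logPrior + .logDistinctSum(ug)
  }, numeric(1))
  post <- exp(logL - .logSumExp(logL))
  post <- post / sum(post)
  names(post) <- vapply(configs, `[[`, "", "label")
  fullLabel <- paste(names(assocList), collapse = ",")
  methods::new("MolocResult", posteriors = post,
               ppaFull = unname(post[fullLabel]),
               cpgId = as.character(cpgId), nSnps = length(shared))
}

#' Scan CpG sites near a gene with multi-trait colocalization
#'
#' Runs [molocTest()] on (expression, methylation, trait) for every CpG
#' whose position lies within `windowBp` (default 100 kb, inclusive) of
#' the gene's coordinates, and returns the result with maximal
#' all-shared posterior together with the full per-CpG table.
#'
#' @param geneId gene identifier (for reporting).
#' @param assocE expression [AssocSet-class].
#' @param cpgAssoc named list of methylation [AssocSet-class] objects,
#'   one per CpG probe.
#' @param assocG trait/GWAS [AssocSet-class].
#' @param geneWindow [GenomicWindow-class] with the gene coordinates.
#' @param cpgCoords data.frame with columns `feature_id`, `chrom`,
#'   `start`, `end` (CpG probe positions, as from
#'   [readFeatureCoords()]).
#' @param windowBp maximal distance from the gene edge; default 1e5.
#' @param priors,priorSds passed to [molocTest()].
#' @return list with `best` (a [MolocResult-class], or `NULL`),
#'   `table` (per-CpG data.frame of `cpg_id`, `n_snps`, `ppa_full` and
#'   all configuration posteriors) and `reason` (`NA` or why no CpG was
#'   evaluated).
#' @export
scanCpgs <- function(geneId, assocE, cpgAssoc, assocG, geneWindow,
                     cpgCoords, windowBp = 1e5,
                     priors = c(1e-4, 1e-6, 1e-7), priorSds = NULL) {
  stopifnot(methods::is(geneWindow, "GenomicWindow"))
  cc <- cpgCoords[cpgCoords$feature_id %in% names(cpgAssoc), , drop = FALSE]
  eligible <- cc$chrom == geneWindow@chrom &
    cc$end >= geneWindow@start - windowBp &
    cc$start <= geneWindow@end + windowBp
  ids <- cc$feature_id[eligible]
  if (length(ids) == 0L)
    return(list(best = NULL, table = data.frame(),
                reason = "no CpG within window"))
  rows <- list()
  results <- list()
  for (id in sort(ids)) {
    res <- tryCatch(
      molocTest(list(E = assocE, M = cpgAssoc[[id]], G = assocG),
                priors = priors, priorSds = priorSds, cpgId = id),
      error = function(e) NULL)
    if (is.null(res)) next
    results[[id]] <- res
    rows[[id]] <- data.frame(gene_id = geneId, cpg_id = id,
                             n_snps = res@nSnps, ppa_full = res@ppaFull,
                             t(posteriorProbs(res)), check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  if (length(results) == 0L)
    return(list(best = NULL, table = data.frame(),
                reason = "no CpG shared variants with both other traits"))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- results[[which.max(vapply(results, ppaFull, numeric(1)))]]
  list(best = best, table = tab, reason = NA_character_)
}

#' Conditional decomposition of a multi-signal locus, then CpG scan
#'
#' When clumping the expression statistics yields several independent
#' eQTL signals, each signal is evaluated in turn: all three traits'
#' statistics are conditioned on the *other* index variants
#' ([conditionalAssoc()]) and the CpG scan is run on the conditioned
#' statistics. A single-signal locus reduces to [scanCpgs()] on the
#' unconditioned data.
#'
#' @param geneId gene identifier.
#' @param assocE,cpgAssoc,assocG,geneWindow,cpgCoords,windowBp,priors,priorSds
#'   as in [scanCpgs()].
#' @param ld [LDMatrix-class] covering the expression variants.
#' @param pIndex,r2Thresh,windowKb clumping parameters (defaults 5e-8,
#'   0.01, 1000).
#' @return named list (one element per eQTL signal, named by index
#'   variant) of [scanCpgs()] results; signals whose conditioning
#'   fails with a collinearity error are reported with
#'   `reason = "collinearity"` and skipped.
#' @export
decomposeAndMoloc <- function(geneId, assocE, cpgAssoc, assocG, ld,
                              geneWindow, cpgCoords, pIndex = 5e-8,
                              r2Thresh = 0.01, windowKb = 1000,
                              windowBp = 1e5,
                              priors = c(1e-4, 1e-6, 1e-7),
                              priorSds = NULL) {
  cl <- clumpVariants(assocE, ld, pIndex = pIndex, r2Thresh = r2Thresh,
                      windowKb = windowKb)
  idx <- indexVariants(cl)
  if (length(idx) <= 1L) {
    res <- scanCpgs(geneId, assocE, cpgAssoc, assocG, geneWindow,
                    cpgCoords, windowBp, priors, priorSds)
    return(stats::setNames(list(res),
                           if (length(idx)) idx else "unconditioned"))
  }
  out <- list()
  for (iv in idx) {
    others <- setdiff(idx, iv)
    res <- tryCatch({
      condE <- conditionalAssoc(assocE, ld, others)
      condG <- conditionalAssoc(assocG, ld, others)
      condM <- lapply(cpgAssoc, conditionalAssoc, ld = ld,
                      conditionIds = others)
      scanCpgs(geneId, condE, condM, condG, geneWindow, cpgCoords,
               windowBp, priors, priorSds)
    }, error = function(e) {
      list(best = NULL, table = data.frame(),
           reason = paste("collinearity:", conditionMessage(e)))
    })
    out[[iv]] <- res
  }
  out
}
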
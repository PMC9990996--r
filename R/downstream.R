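## Cross-trait effect clustering, enrichment, phenome-wide MR scanning
## and cross-tissue replication comparison.

#' Build a gene-by-trait MR effect matrix
#'
#' Arranges MR betas into a gene-by-trait matrix, z-scores each trait
#' column over its non-missing cells (so binary log-odds and
#' quantitative per-SD effects become comparable), and imputes missing
#' cells to 0 *after* standardization for distance computation only;
#' the availability mask and raw betas are retained. Constant columns
#' (sd = 0) standardize to all-zero with a warning.
#'
#' @param results data.frame with columns `exposure_id`, `outcome_id`,
#'   `beta` (e.g. from [transcriptomeScan()]), or a list of
#'   [MRResult-class] objects.
#' @return an [EffectMatrix-class].
#' @export
buildEffectMatrix <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  stopifnot(all(c("exposure_id", "outcome_id", "beta") %in% names(results)))
  key <- paste(results$exposure_id, results$outcome_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, trait) pair(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  genes <- sort(unique(results$exposure_id))
  traits <- sort(unique(results$outcome_id))
  raw <- matrix(NA_real_, length(genes), length(traits),
                dimnames = list(genes, traits))
  raw[cbind(match(results$exposure_id, genes),
            match(results$outcome_id, traits))] <- results$beta
  mask <- !is.na(raw)
  values <- raw
  for (j in seq_along(traits)) {
    obs <- mask[, j]
    mu <- mean(raw[obs, j])
    sdv <- stats::sd(raw[obs, j])
    if (!is.finite(sdv) || sdv == 0) {
      if (sum(obs) > 1L)
        warning("constant column '", traits[j], "' standardized to zero")
      values[obs, j] <- 0
    } else {
      values[obs, j] <- (raw[obs, j] - mu) / sdv
    }
  }
  values[!mask] <- 0
  methods::new("EffectMatrix", values = values, raw = raw, mask = mask)
}

#' Cluster genes and traits on Euclidean distance
#'
#' Computes pairwise Euclidean distances between the standardized
#' effect-matrix rows (and columns) and applies hierarchical
#' agglomeration with complete linkage. Rows and columns are pre-sorted
#' by identifier so the leaf order is deterministic under ties.
#'
#' @param effMat an [EffectMatrix-class] with at least 2 rows.
#' @return list with `dist` (full symmetric row-distance matrix),
#'   `rowOrder`, `colOrder` (leaf orders as identifiers), and the
#'   underlying `hclustRow`/`hclustCol` objects (`hclustCol` is `NULL`
#'   with fewer than 2 columns).
#' @export
euclideanCluster <- function(effMat) {
  values <- effectValues(effMat)
  stopifnot(nrow(values) >= 2L)
  values <- values[order(rownames(values)), order(colnames(values)),
                   drop = FALSE]
  d <- stats::dist(values, method = "euclidean")
  hr <- stats::hclust(d, method = "complete")
  hc <- if (ncol(values) >= 2L)
    stats::hclust(stats::dist(t(values)), method = "complete") else NULL
  list(dist = as.matrix(d),
       rowOrder = rownames(values)[hr$order],
       colOrder = if (is.null(hc)) colnames(values)
                  else colnames(values)[hc$order],
       hclustRow = hr, hclustCol = hc)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and
#' an annotation set within a gene universe:
#' \eqn{p = P(X \ge k)} for X hypergeometric with the observed margins.
#'
#' @param hitGenes character vector of hit genes (subset of
#'   `universe`).
#' @param annotationSet character vector of annotated genes (subset of
#'   `universe`).
#' @param universe character vector of all tested genes (non-empty).
#' @return list with `overlap` (k), `pval`, `expected` (mean overlap
#'   under the null), `n_hits`, `n_annotated`, `n_universe`.
#' @export
hypergeomEnrichment <- function(hitGenes, annotationSet, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hitGenes <- unique(hitGenes)
  annotationSet <- unique(annotationSet)
  stopifnot(all(hitGenes %in% universe), all(annotationSet %in% universe))
  k <- length(intersect(hitGenes, annotationSet))
  N <- length(universe)
  K <- length(annotationSet)
  n <- length(hitGenes)
  p <- if (k == 0L) 1 else
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, pval = p, expected = n * K / N,
       n_hits = n, n_annotated = K, n_universe = N)
}

#' Phenome-wide MR scan of one gene against an outcome catalogue
#'
#' Clumps the gene's cis-QTL statistics once, then for every outcome in
#' the catalogue: harmonize, estimate the MR effect (Wald/IVW), and
#' optionally colocalize the full regional statistics. Results are
#' flagged at the phenome-wide Bonferroni threshold
#' `alpha / n_outcomes`; the pleiotropy count is the number of flagged
#' outcomes.
#'
#' @param exposure the gene's [AssocSet-class].
#' @param outcomeCatalogue named list of outcome [AssocSet-class]
#'   objects (>= 1).
#' @param ld [LDMatrix-class] for clumping the exposure.
#' @param pInstrument,r2Thresh,windowKb clumping parameters.
#' @param alpha family-wise error rate; threshold is
#'   `alpha / length(outcomeCatalogue)`.
#' @param doColoc also compute the shared-variant posterior `PP.H4` per
#'   outcome; default `FALSE`.
#' @param colocPriorsList priors for the optional colocalization.
#' @return list with `table` (one row per scanned outcome: MR fields,
#'   `pp_h4` when requested, `flagged`), `bonferroniThreshold`,
#'   `pleiotropyCount` and `skipped` (outcomes with no shared
#'   variants).
#' @export
phewasScan <- function(exposure, outcomeCatalogue, ld,
                       pInstrument = 5e-8, r2Thresh = 0.01,
                       windowKb = 1000, alpha = 0.05, doColoc = FALSE,
                       colocPriorsList = colocPriors()) {
  stopifnot(is.list(outcomeCatalogue), !is.null(names(outcomeCatalogue)))
  if (length(outcomeCatalogue) == 0L)
    stop("phenome-wide scan requires at least one outcome")
  cl <- clumpVariants(exposure, ld, pIndex = pInstrument,
                      r2Thresh = r2Thresh, windowKb = windowKb)
  if (length(indexVariants(cl)) == 0L)
    stop("empty instrument set: no clumped instrument at pInstrument")
  threshold <- bonferroniThreshold(length(outcomeCatalogue), alpha)
  rows <- list()
  skipped <- character(0)
  for (id in names(outcomeCatalogue)) {
    pairs <- tryCatch(harmonizeSumstats(exposure, outcomeCatalogue[[id]]),
                      error = function(e) NULL)
    if (is.null(pairs)) {
      skipped[id] <- "no shared variants"
      next
    }
    res <- .mrFromPairs(pairs, indexVariants(cl), traitId(exposure), id,
                        threshold)
    if (is.null(res)) {
      skipped[id] <- "no harmonizable instrument"
      next
    }
    row <- as.data.frame(res)
    if (doColoc) {
      cres <- tryCatch(colocABF(exposure, outcomeCatalogue[[id]],
                                priors = colocPriorsList),
                       error = function(e) NULL)
      row$pp_h4 <- if (is.null(cres)) NA_real_
                   else unname(posteriorProbs(cres)["PP.H4"])
    }
    row$flagged <- row$pval < threshold
    rows[[id]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(tab) <- NULL
  list(table = tab, bonferroniThreshold = threshold,
       pleiotropyCount = if (nrow(tab)) sum(tab$flagged) else 0L,
       skipped = skipped)
}

#' Compare primary-tissue MR effects against a proxy tissue
#'
#' For every (gene, outcome) effect in the primary results that has a
#' matching proxy-tissue result, checks whether the proxy p-value falls
#' below the heuristic threshold (default 0.05). Reports the
#' replication percentage, its complement (effects overlooked by the
#' proxy tissue), the reverse comparison, and sign concordance among
#' replicated pairs.
#'
#' @param primaryResults,proxyResults data.frames with columns
#'   `exposure_id`, `outcome_id`, `beta`, `pval` (or lists of
#'   [MRResult-class]).
#' @param heuristicP replication p-value heuristic; default 0.05.
#' @return list with `nPrimary`, `nCompared`, `nReplicated`,
#'   `replicationPct`, `overlookedPct` (both rounded to 1 decimal, `NA`
#'   when nothing was compared), `signConcordancePct`, and
#'   `reverse` (the proxy-to-primary counts).
#' @export
crossTissueCompare <- function(primaryResults, proxyResults,
                               heuristicP = 0.05) {
  asDF <- function(x) {
    if (is.list(x) && !is.data.frame(x))
      x <- do.call(rbind, lapply(x, as.data.frame))
    stopifnot(all(c("exposure_id", "outcome_id", "beta", "pval") %in%
                    names(x)))
    x
  }
  prim <- asDF(primaryResults)
  prox <- asDF(proxyResults)
  keyP <- paste(prim$exposure_id, prim$outcome_id, sep = "\r")
  keyX <- paste(prox$exposure_id, prox$outcome_id, sep = "\r")
  idx <- match(keyP, keyX)
  compared <- !is.na(idx)
  if (!any(compared))
    return(list(nPrimary = nrow(prim), nCompared = 0L, nReplicated = 0L,
                replicationPct = NA_real_, overlookedPct = NA_real_,
                signConcordancePct = NA_real_,
                reverse = list(nProxy = nrow(prox), nCompared = 0L,
                               nReplicated = 0L, replicationPct = NA_real_),
                reason = "no overlapping (gene, outcome) keys"))
  replicated <- compared & prox$pval[idx] < heuristicP
  nC <- sum(compared)
  nR <- sum(replicated)
  concord <- sign(prim$beta[replicated]) ==
    sign(prox$beta[idx[replicated]])
  ridx <- match(keyX, keyP)
  rcomp <- !is.na(ridx)
  rrep <- rcomp & prim$pval[ridx] < heuristicP
  list(
    nPrimary = nrow(prim), nCompared = nC, nReplicated = nR,
    replicationPct = round(100 * nR / nC, 1),
    overlookedPct = round(100 * (nC - nR) / nC, 1),
    signConcordancePct = if (nR) round(100 * mean(concord), 1) else NA_real_,
    reverse = list(nProxy = nrow(prox), nCompared = sum(rcomp),
                   nReplicated = sum(rrep),
                   replicationPct = if (sum(rcomp))
                     round(100 * sum(rrep) / sum(rcomp), 1) else NA_real_),
    reason = NA_character_)
}
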
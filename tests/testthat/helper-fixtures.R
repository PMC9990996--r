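## Fixture builders and independent oracles used across the suite.
## Oracles deliberately re-derive results by a different route than the
## implementation (plain double loops, exhaustive enumeration,
## quadrature) so agreement is informative.

## Build an AssocSet from a z-score vector on a 1 kb grid.
assocFromZ <- function(z, n = 10000, maf = 0.3, traitId = "trait",
                       traitType = "quantitative", pos = NULL,
                       ids = NULL) {
  m <- length(z)
  if (is.null(pos)) pos <- 1 + (seq_len(m) - 1) * 1000
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  maf <- rep_len(maf, m)
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  AssocSet(data.frame(variant_id = ids, chrom = "1", pos = pos,
                      effect_allele = "A", other_allele = "G", eaf = maf,
                      beta = z * se, se = se, pval = twoSidedP(z), n = n),
           traitId = traitId, traitType = traitType)
}

## One fully-specified summary-statistics row, overridable per field.
recRow <- function(...) {
  base <- list(variant_id = "rs1", chrom = "1", pos = 100,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta = 0.1, se = 0.05, pval = twoSidedP(0.1 / 0.05),
               n = 1000)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

writeSumstatFile <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, rows)
  names(df) <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE",
                 "P", "N")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

## --- independent oracles -------------------------------------------------

## Greedy clumping re-implemented in a different style (repeat loop,
## explicit candidate scan) for cross-checking clumpVariants.
oracleClump <- function(rec, r, pIndex = 5e-8, r2 = 0.01,
                        windowKb = 1000) {
  remaining <- seq_len(nrow(rec))
  index <- character(0)
  repeat {
    cand <- remaining[rec$pval[remaining] <= pIndex]
    if (length(cand) == 0L) break
    zab <- abs(rec$beta / rec$se)
    best <- cand[order(rec$pval[cand], -zab[cand], rec$pos[cand],
                       rec$variant_id[cand])][1L]
    index <- c(index, rec$variant_id[best])
    absorbed <- remaining[
      abs(rec$pos[remaining] - rec$pos[best]) <= windowKb * 1000 &
        r[rec$variant_id[best], rec$variant_id[remaining]]^2 >= r2]
    remaining <- setdiff(remaining, c(best, absorbed))
  }
  index
}

## Wakefield log-ABF by numerical integration of the two-Gaussian
## marginal-likelihood ratio.
oracleLogABF <- function(beta, se, W) {
  m1 <- stats::integrate(function(b)
    stats::dnorm(beta, b, se) * stats::dnorm(b, 0, W),
    -Inf, Inf, rel.tol = 1e-12)$value
  log(m1 / stats::dnorm(beta, 0, se))
}

## Pairwise colocalization posteriors by explicit enumeration: the H3
## term is an explicit i != j double loop on the plain (non-log) scale.
oracleColoc <- function(l1, l2, p1, p2, p12) {
  b1 <- exp(l1)
  b2 <- exp(l2)
  m <- length(b1)
  L3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) L3 <- L3 + b1[i] * b2[j]
  L <- c(1, p1 * sum(b1), p2 * sum(b2), p1 * p2 * L3, p12 * sum(b1 * b2))
  L / sum(L)
}

## Multi-trait colocalization posteriors by exhaustive enumeration over
## all assignments of distinct variants to groups (feasible for small
## m). abfs: named list of log-ABF vectors; configs from
## enumerateConfigs(k, names(abfs)); priors per sharing cardinality.
oracleMoloc <- function(abfs, configs, priors) {
  m <- length(abfs[[1L]])
  L <- vapply(configs, function(cf) {
    groups <- cf$groups
    if (length(groups) == 0L) return(1)
    r <- length(groups)
    grid <- as.matrix(expand.grid(rep(list(seq_len(m)), r)))
    distinct <- apply(grid, 1L, function(row) !anyDuplicated(row))
    total <- 0
    for (row in which(distinct)) {
      term <- 1
      for (g in seq_len(r)) {
        v <- grid[row, g]
        term <- term * prod(exp(vapply(groups[[g]],
                                       function(tr) abfs[[tr]][v],
                                       numeric(1))))
      }
      total <- total + term
    }
    prod(priors[vapply(groups, length, 1L)]) * total
  }, numeric(1))
  stats::setNames(L / sum(L), vapply(configs, `[[`, "", "label"))
}

## Count subset-partition configurations by direct recursion
## (independent of .setPartitions): sum over subset sizes s of
## choose(k, s) * Bell(s), with Bell numbers from the recurrence.
oracleConfigCount <- function(k) {
  bell <- function(n) {
    if (n == 0L) return(1)
    sum(vapply(0:(n - 1L), function(i)
      choose(n - 1L, i) * bell(i), numeric(1)))
  }
  sum(vapply(0:k, function(s) choose(k, s) * bell(s), numeric(1)))
}

## Conditional z by the precision-matrix (full joint inverse) route,
## algebraically distinct from the Schur form in the implementation.
oracleConditionalZ <- function(z, R, cIdx, tIdx) {
  sub <- c(tIdx, cIdx)
  Omega <- solve(R[sub, sub])
  mean_t <- -sum(Omega[1, -1] * z[cIdx]) / Omega[1, 1]
  sd_t <- sqrt(1 / Omega[1, 1])
  (z[tIdx] - mean_t) / sd_t
}

## Hypergeometric upper tail from log-factorial sums.
oracleHyperTail <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## A small multi-gene synthetic study for pipeline tests: each gene
## gets its own region (ids/positions offset so they never collide),
## the per-region outcome chunks are concatenated into one GWAS
## AssocSet. Genes 1..nShared share a causal variant with the outcome,
## then one distinct-causal gene, the rest are eQTL-only (null
## outcome).
makeSyntheticStudy <- function(nGenes = 6, nShared = 3, m = 60,
                               seed = 1) {
  set.seed(seed)
  exposures <- list()
  lds <- list()
  outcomeChunks <- list()
  truthShared <- character(0)
  for (i in seq_len(nGenes)) {
    kind <- if (i <= nShared) "h4" else if (i == nShared + 1) "h3" else "null"
    causalE <- as.integer(m / 2)
    gwasCausal <- switch(kind, h4 = causalE, h3 = as.integer(m / 6),
                         null = integer(0))
    gwasBeta <- if (length(gwasCausal)) 0.04 else numeric(0)
    sc <- scenarioConfig(m, 0.9, list(
      list(trait_id = "e", trait_type = "quantitative", n = 1194,
           causal_pos = causalE, causal_beta = 0.3),
      list(trait_id = "g", trait_type = "quantitative", n = 50000,
           causal_pos = gwasCausal, causal_beta = gwasBeta)))
    reg <- simulateSummaryStats(sc)
    gid <- sprintf("gene%02d", i)
    prefix <- sprintf("g%02d_", i)
    offset <- (i - 1) * 10 * m * 1000
    rename <- function(a) {
      r <- records(a)
      r$variant_id <- paste0(prefix, r$variant_id)
      r$pos <- r$pos + offset
      AssocSet(r, traitId = traitId(a), traitType = traitType(a))
    }
    sa <- simAssoc(reg)
    exposures[[gid]] <- rename(sa$e)
    outcomeChunks[[gid]] <- records(rename(sa$g))
    lds[[gid]] <- LDMatrix(corMatrix(simLD(reg)),
                           paste0(prefix, variantIds(simLD(reg))))
    if (kind == "h4") truthShared <- c(truthShared, gid)
  }
  outRec <- do.call(rbind, outcomeChunks)
  outRec$n <- 50000
  outcome <- AssocSet(outRec, traitId = "gwas")
  list(exposures = exposures, outcome = outcome, ld = lds,
       truthShared = truthShared)
}
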
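test_that("the effect matrix standardizes columns and masks missing cells", {
  res <- data.frame(exposure_id = c("g1", "g2", "g1", "g2"),
                    outcome_id = c("t1", "t1", "t2", "t2"),
                    beta = c(0.2, -0.4, 0.1, 0.3))
  em <- buildEffectMatrix(res)
  v <- effectValues(em)
  expect_equal(dim(v), c(2L, 2L))
  expect_lt(max(abs(colMeans(v))), 1e-12)
  expect_true(all(effectMask(em)))
  ## missing cell: masked and imputed to 0 after standardization
  em2 <- buildEffectMatrix(res[-4, ])
  expect_false(effectMask(em2)["g2", "t2"])
  expect_equal(effectValues(em2)["g2", "t2"], 0)
  ## sd-zero guard
  cst <- data.frame(exposure_id = c("g1", "g2"),
                    outcome_id = c("t1", "t1"), beta = c(0.5, 0.5))
  expect_warning(em3 <- buildEffectMatrix(cst), "constant column")
  expect_equal(unname(effectValues(em3)[, 1]), c(0, 0))
  ## duplicates are an error
  expect_error(buildEffectMatrix(rbind(res, res[1, ])), "duplicate")
})

test_that("Euclidean clustering reproduces hand distances and a brute-force oracle", {
  em <- buildEffectMatrix(data.frame(
    exposure_id = rep(c("g1", "g2"), each = 2),
    outcome_id = rep(c("t1", "t2"), 2),
    beta = c(0, 0, 3, 4)))
  raw <- em@raw
  expect_equal(sqrt(sum((raw["g1", ] - raw["g2", ])^2)), 5)  # 3-4-5
  cl <- euclideanCluster(em)
  expect_equal(dim(cl$dist), c(2L, 2L))
  ## identical rows: distance 0 and adjacent leaves
  em2 <- buildEffectMatrix(data.frame(
    exposure_id = rep(c("g1", "g2", "g3"), each = 2),
    outcome_id = rep(c("t1", "t2"), 3),
    beta = c(1, 2, 1, 2, 8, 9)))
  cl2 <- euclideanCluster(em2)
  expect_equal(cl2$dist["g1", "g2"], 0)
  expect_equal(abs(diff(match(c("g1", "g2"), cl2$rowOrder))), 1)
  ## random matrix vs element-wise double loop
  set.seed(53)
  vals <- matrix(rnorm(24), 6, 4,
                 dimnames = list(paste0("g", 1:6), paste0("t", 1:4)))
  df <- data.frame(exposure_id = rep(rownames(vals), 4),
                   outcome_id = rep(colnames(vals), each = 6),
                   beta = as.vector(vals))
  em3 <- buildEffectMatrix(df)
  got <- euclideanCluster(em3)$dist
  v <- effectValues(em3)[rownames(got), , drop = FALSE]
  brute <- matrix(0, 6, 6, dimnames = dimnames(got))
  for (i in 1:6) for (j in 1:6) {
    s <- 0
    for (k in 1:4) s <- s + (v[i, k] - v[j, k])^2
    brute[i, j] <- sqrt(s)
  }
  expect_equal(got, brute, tolerance = 1e-12)
  ## metric properties
  expect_equal(got, t(got))
  expect_equal(unname(diag(got)), rep(0, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(got[i, j], got[i, k] + got[k, j] + 1e-12)
})

test_that("hypergeometric enrichment equals exhaustive tail enumeration", {
  u <- paste0("g", 1:20)
  hits <- paste0("g", 1:5)
  annot <- paste0("g", c(1:3, 6, 7))
  res <- hypergeomEnrichment(hits, annot, u)
  expect_equal(res$overlap, 3L)
  expect_equal(res$pval, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$pval, oracleHyperTail(3, 20, 5, 5), tolerance = 1e-12)
  ## annotation = universe: certain overlap, p = 1
  expect_equal(hypergeomEnrichment(hits, u, u)$pval, 1)
  ## zero overlap: P(X >= 0) = 1
  expect_equal(hypergeomEnrichment(hits, paste0("g", 16:20), u)$pval, 1)
  expect_error(hypergeomEnrichment(character(0), character(0),
                                   character(0)), "empty universe")
  ## monotone non-increasing in the overlap for fixed margins
  ps <- vapply(0:5, function(k)
    oracleHyperTail(k, 20, 5, 5), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  for (k in 1:5) {
    hk <- c(annot[seq_len(k)], head(setdiff(u, annot), 5 - k))
    expect_equal(hypergeomEnrichment(hk, annot, u)$overlap, k)
  }
})

test_that("the phenome-wide scan flags the single true outcome", {
  set.seed(59)
  nOut <- 50
  flagged <- replicate(100, {
    traits <- c(
      list(list(trait_id = "eqtl", trait_type = "quantitative",
                n = 31684, causal_pos = 25L, causal_beta = 0.5),
           list(trait_id = "out_true", trait_type = "quantitative",
                n = 50000, causal_pos = 25L, causal_beta = 0.15)),
      lapply(seq_len(nOut - 1), function(i)
        list(trait_id = paste0("out_null", i),
             trait_type = "quantitative", n = 50000,
             causal_pos = integer(0), causal_beta = numeric(0))))
    reg <- simulateSummaryStats(scenarioConfig(50, 0.9, traits))
    sa <- simAssoc(reg)
    scan <- phewasScan(sa$eqtl, sa[-1], simLD(reg))
    scan$pleiotropyCount
  })
  expect_gte(mean(flagged == 1), 0.9)
  ## threshold arithmetic and the empty-instrument error
  reg <- simulateSummaryStats(scenarioConfig(50, 0.9, list(
    list(trait_id = "eqtl", trait_type = "quantitative", n = 31684,
         causal_pos = 25L, causal_beta = 0.5),
    list(trait_id = "out", trait_type = "quantitative", n = 50000,
         causal_pos = integer(0), causal_beta = numeric(0)))))
  sa <- simAssoc(reg)
  scan <- phewasScan(sa$eqtl, sa["out"], simLD(reg))
  expect_equal(scan$bonferroniThreshold, 0.05)
  weak <- assocFromZ(c(1, 2), ids = c("v1", "v2"))
  expect_error(phewasScan(weak, sa["out"],
                          LDMatrix(diag(2), c("v1", "v2"))),
               "empty instrument")
})

test_that("cross-tissue comparison reproduces the replication arithmetic", {
  primary <- data.frame(
    exposure_id = sprintf("gene%02d", 1:91),
    outcome_id = "trait", beta = rep(c(0.3, -0.2), length.out = 91),
    pval = 1e-8)
  proxy <- primary
  proxy$pval <- c(rep(0.01, 53), rep(0.5, 38))
  rep1 <- crossTissueCompare(primary, proxy)
  expect_equal(rep1$nCompared, 91L)
  expect_equal(rep1$nReplicated, 53L)
  expect_equal(rep1$replicationPct, 58.2)
  expect_equal(rep1$overlookedPct, 41.8)
  expect_equal(rep1$replicationPct + rep1$overlookedPct, 100)
  expect_equal(rep1$signConcordancePct, 100)
  ## zero key overlap: NA percentages with a reason
  proxy2 <- proxy
  proxy2$outcome_id <- "other"
  rep2 <- crossTissueCompare(primary, proxy2)
  expect_equal(rep2$nCompared, 0L)
  expect_true(is.na(rep2$replicationPct))
  ## proxy identical to primary: full replication and concordance
  rep3 <- crossTissueCompare(primary, primary)
  expect_equal(rep3$replicationPct, 100)
  expect_equal(rep3$signConcordancePct, 100)
  expect_equal(rep3$reverse$replicationPct, 100)
})
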
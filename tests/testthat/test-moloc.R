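test_that("configuration enumeration matches the combinatorial count", {
  for (k in 1:4) {
    cfg <- enumerateConfigs(k)
    expect_equal(length(cfg), oracleConfigCount(k))
    expect_equal(anyDuplicated(vapply(cfg, `[[`, "", "label")), 0L)
  }
  expect_equal(length(enumerateConfigs(1)), 2L)
  expect_equal(length(enumerateConfigs(2)), 5L)
  expect_equal(length(enumerateConfigs(3)), 15L)
  ## k = 2 reduces to the pairwise hypothesis space H0-H4
  labels2 <- vapply(enumerateConfigs(2, c("A", "B")), `[[`, "", "label")
  expect_setequal(labels2, c("null", "A", "B", "A/B", "A,B"))
})

test_that("single-variant moloc matches hand enumeration of all 15 terms", {
  ## every trait with per-SNP Bayes factor 10 at the only variant:
  ## configurations needing >= 2 distinct variants get likelihood 0
  l <- log(10)
  se <- 0.03; W <- 0.15
  r <- W^2 / (se^2 + W^2)
  z <- sqrt((2 * (l - 0.5 * log(1 - r))) / r)
  a <- AssocSet(recRow(variant_id = "v1", beta = z * se, se = se,
                       pval = twoSidedP(z)), "t")
  priors <- c(1e-4, 1e-6, 1e-7)
  res <- molocTest(list(E = a, M = a, G = a), priors = priors,
                   priorSds = rep(W, 3))
  post <- posteriorProbs(res)
  L <- c(null = 1,
         E = 1e-4 * 10, M = 1e-4 * 10, G = 1e-4 * 10,
         `E,M` = 1e-6 * 100, `E/M` = 0,
         `E,G` = 1e-6 * 100, `E/G` = 0,
         `M,G` = 1e-6 * 100, `M/G` = 0,
         `E,M,G` = 1e-7 * 1000,
         `E,M/G` = 0, `E,G/M` = 0, `E/M,G` = 0, `E/M/G` = 0)
  expect_equal(post[names(L)], L / sum(L), tolerance = 1e-10)
  expect_equal(ppaFull(res), unname(L["E,M,G"] / sum(L)),
               tolerance = 1e-10)
})

test_that("moloc matches the exhaustive assignment oracle on random regions", {
  set.seed(23)
  priors <- c(1e-4, 1e-6, 1e-7)
  for (rep in 1:10) {
    m <- 5
    sets <- list(E = assocFromZ(rnorm(m, 0, 3)),
                 M = assocFromZ(rnorm(m, 0, 3)),
                 G = assocFromZ(rnorm(m, 0, 2), n = 50000))
    res <- molocTest(sets, priors = priors)
    W <- priorSdForTrait("quantitative", 1)
    abfs <- lapply(sets, function(a) {
      r <- records(a)
      stats::setNames(logABF(r$beta, r$se, W), r$variant_id)
    })
    oracle <- oracleMoloc(abfs, enumerateConfigs(3, names(sets)), priors)
    expect_equal(posteriorProbs(res)[names(oracle)], oracle,
                 tolerance = 1e-9)
    expect_lt(abs(sum(posteriorProbs(res)) - 1), 1e-10)
  }
})

test_that("a null third trait reduces moloc to the pairwise ranking", {
  set.seed(29)
  a1 <- assocFromZ(c(8, rnorm(9)))
  a2 <- assocFromZ(c(7.5, rnorm(9)))
  g0 <- assocFromZ(rep(0, 10), n = 50000)
  ## matched priors: coloc (p1, p2, p12) = per-cardinality (p1, p1, p2)
  res <- molocTest(list(E = a1, M = a2, G = g0),
                   priors = c(1e-4, 1e-6, 1e-7))
  post <- posteriorProbs(res)
  cres <- colocABF(a1, a2, priors = colocPriors(1e-4, 1e-4, 1e-6))
  pp <- posteriorProbs(cres)
  reduction <- c(null = "PP.H0", E = "PP.H1", M = "PP.H2",
                 `E/M` = "PP.H3", `E,M` = "PP.H4")
  expect_equal(order(post[names(reduction)]),
               order(pp[reduction]))
})

test_that("posteriors are invariant to trait relabeling", {
  set.seed(31)
  sets <- list(E = assocFromZ(rnorm(6, 0, 2)),
               M = assocFromZ(rnorm(6, 0, 2)),
               G = assocFromZ(rnorm(6, 0, 2)))
  p1 <- posteriorProbs(molocTest(sets))
  perm <- sets[c("M", "G", "E")]
  p2 <- posteriorProbs(molocTest(perm))
  relabel <- function(lab) {
    if (lab == "null") return("null")
    groups <- strsplit(strsplit(lab, "/")[[1]], ",")
    canon <- lapply(groups, function(g) sort(g))
    canon <- canon[order(vapply(canon, `[`, "", 1))]
    paste(vapply(canon, paste, "", collapse = ","), collapse = "/")
  }
  n1 <- vapply(names(p1), relabel, "")
  n2 <- vapply(names(p2), relabel, "")
  expect_equal(unname(p1[order(n1)]), unname(p2[order(n2)]),
               tolerance = 1e-12)
})

test_that("the CpG scan honours the 100 kb window and selects the signal carrier", {
  gw <- genomicWindow("1", 100000, 120000)
  coords <- data.frame(chrom = c("1", "1", "2"),
                       start = c(50000, 220001, 100000),
                       end = c(50000, 220001, 100000),
                       feature_id = c("cg_in", "cg_out", "cg_chr2"))
  set.seed(37)
  e <- assocFromZ(c(8, rnorm(9)))
  g <- assocFromZ(c(7.5, rnorm(9)), n = 50000)
  cpgs <- list(cg_in = assocFromZ(c(8, rnorm(9))),
               cg_out = assocFromZ(c(8, rnorm(9))),
               cg_chr2 = assocFromZ(c(8, rnorm(9))))
  res <- scanCpgs("geneA", e, cpgs, g, gw, coords)
  ## cg_out is 100001 bp beyond the gene edge; cg_chr2 is off-chromosome
  expect_equal(res$table$cpg_id, "cg_in")
  expect_equal(res$best@cpgId, "cg_in")
  ## single eligible CpG: best equals that CpG's moloc result
  direct <- molocTest(list(E = e, M = cpgs$cg_in, G = g), cpgId = "cg_in")
  expect_equal(posteriorProbs(res$best), posteriorProbs(direct))
  ## no eligible CpG: reason code, not an error
  none <- scanCpgs("geneA", e, cpgs["cg_chr2"], g, gw, coords)
  expect_null(none$best)
  expect_match(none$reason, "no CpG")
})

test_that("the scan picks the carrier CpG under a three-way shared signal", {
  set.seed(41)
  lib <- scenarioLibrary()
  gw <- genomicWindow("1", 99001, 99001)  # causal variant position
  hits <- replicate(100, {
    reg <- simulateSummaryStats(lib$three_way_shared)
    sa <- simAssoc(reg)
    decoys <- lapply(1:4, function(i)
      simAssoc(simulateSummaryStats(scenarioConfig(200, 0.9, list(
        list(trait_id = "m", trait_type = "quantitative", n = 1194,
             causal_pos = integer(0), causal_beta = numeric(0))))))$m)
    cpgs <- c(list(cg_signal = sa$mqtl),
              stats::setNames(decoys, paste0("cg_null", 1:4)))
    coords <- data.frame(chrom = "1",
                         start = seq(60000, 140000, length.out = 5),
                         end = seq(60000, 140000, length.out = 5),
                         feature_id = names(cpgs))
    res <- scanCpgs("geneA", sa$eqtl, cpgs, sa$gwas, gw, coords)
    res$best@cpgId == "cg_signal" && ppaFull(res$best) > 0.8
  })
  expect_gte(mean(hits), 0.8)
})

test_that("decomposition reduces to a plain scan at single-signal loci", {
  set.seed(43)
  lib <- scenarioLibrary()
  reg <- simulateSummaryStats(lib$three_way_shared)
  sa <- simAssoc(reg)
  gw <- genomicWindow("1", 99001, 99001)
  coords <- data.frame(chrom = "1", start = 99001, end = 99001,
                       feature_id = "cg1")
  dec <- decomposeAndMoloc("geneA", sa$eqtl, list(cg1 = sa$mqtl),
                           sa$gwas, simLD(reg), gw, coords)
  expect_equal(length(dec), 1L)
  plain <- scanCpgs("geneA", sa$eqtl, list(cg1 = sa$mqtl), sa$gwas, gw,
                    coords)
  expect_equal(posteriorProbs(dec[[1]]$best),
               posteriorProbs(plain$best))
})

test_that("decomposition separates two independent eQTL signals", {
  set.seed(47)
  lib <- scenarioLibrary()
  gw <- genomicWindow("1", 49001, 49001)
  coords <- data.frame(chrom = "1", start = 49001, end = 49001,
                       feature_id = "cg1")
  wins <- replicate(60, {
    reg <- simulateSummaryStats(lib$two_eqtl_signals)
    sa <- simAssoc(reg)
    dec <- decomposeAndMoloc("geneA", sa$eqtl, list(cg1 = sa$mqtl),
                             sa$gwas, simLD(reg), gw, coords,
                             windowBp = 1e6)
    ## only the signal near v50 is shared with methylation and the
    ## trait; classify each decomposed signal by its index position
    ppas <- vapply(dec, function(x)
      if (is.null(x$best)) NA_real_ else ppaFull(x$best), numeric(1))
    vidx <- as.integer(sub("^v", "", names(ppas)))
    sharedSig <- ppas[vidx < 100]
    otherSig <- ppas[vidx >= 100]
    if (length(sharedSig) != 1L || length(otherSig) != 1L) return(NA)
    unname(sharedSig > otherSig)
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
  ## each decomposed run excludes the conditioned-on index variants
  reg <- simulateSummaryStats(lib$two_eqtl_signals)
  sa <- simAssoc(reg)
  cl <- clumpVariants(sa$eqtl, simLD(reg))
  idx <- indexVariants(cl)
  if (length(idx) >= 2) {
    cond <- conditionalAssoc(sa$eqtl, simLD(reg), idx[2])
    expect_false(idx[2] %in% variantIds(cond))
  }
})
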
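test_that("reading a well-formed table loads every row and reports no drops", {
  path <- writeSumstatFile(list(
    recRow(variant_id = "rs1", pos = 100),
    recRow(variant_id = "rs2", pos = 200, beta = -0.2,
           pval = twoSidedP(-0.2 / 0.05)),
    recRow(variant_id = "rs3", pos = 300, eaf = 0.45)))
  a <- readSumstats(path, traitId = "t1")
  expect_s4_class(a, "AssocSet")
  expect_equal(nVariants(a), 3L)
  expect_equal(loadReport(a)$drop_count, 0L)
  expect_equal(variantIds(a), c("rs1", "rs2", "rs3"))
})

test_that("rows violating record invariants are dropped and counted", {
  path <- writeSumstatFile(list(
    recRow(variant_id = "rs1"),
    recRow(variant_id = "rs2", pos = 200, se = 0),
    recRow(variant_id = "rs3", pos = 300, pval = 0.5)))  # p inconsistent
  a <- readSumstats(path, traitId = "t1")
  expect_equal(nVariants(a), 1L)
  rep <- loadReport(a)
  expect_equal(rep$drop_count, 2L)
  expect_equal(unname(rep$drop_reasons["bad_se"]), 1L)
  expect_equal(unname(rep$drop_reasons["p_inconsistent"]), 1L)
})

test_that("lower-case alleles are normalized to upper case on load", {
  path <- writeSumstatFile(list(
    recRow(variant_id = "rs1", effect_allele = "a", other_allele = "g")))
  a <- readSumstats(path, traitId = "t1")
  expect_equal(records(a)$effect_allele, "A")
  expect_equal(records(a)$other_allele, "G")
})

test_that("missing mandatory columns and empty inputs are errors", {
  path <- writeSumstatFile(list(recRow()))
  tab <- utils::read.delim(path)
  tab$SE <- NULL
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readSumstats(path2, "t"), "missing column")
  path3 <- writeSumstatFile(list(recRow(se = -1)))
  expect_error(readSumstats(path3, "t"), "empty-input")
})

test_that("write then read round-trips valid rows bit-identically", {
  set.seed(7)
  a <- assocFromZ(rnorm(20), traitId = "t1")
  path <- tempfile(fileext = ".tsv")
  writeSumstats(a, path)
  b <- readSumstats(path, traitId = "t1")
  expect_identical(records(a), records(b))
})

test_that("records must arrive sorted, unique and internally consistent", {
  expect_error(AssocSet(rbind(recRow(), recRow()), "t"), "unique")
  r <- recRow(se = 0.05, beta = 0.1, pval = 0.9)
  expect_error(AssocSet(r, "t"), "inconsistent")
  a <- AssocSet(rbind(recRow(variant_id = "rs2", pos = 500),
                      recRow(variant_id = "rs1", pos = 100)), "t")
  expect_equal(records(a)$pos, c(100, 500))  # constructor sorts
})

test_that("harmonization keeps aligned alleles, flips swaps, drops ambiguous palindromes", {
  ex <- AssocSet(rbind(
    recRow(variant_id = "rs1", pos = 100, effect_allele = "A",
           other_allele = "G", beta = 0.1, eaf = 0.3,
           pval = twoSidedP(2)),
    recRow(variant_id = "rs2", pos = 200, effect_allele = "A",
           other_allele = "G", beta = 0.1, eaf = 0.3,
           pval = twoSidedP(2)),
    recRow(variant_id = "rs3", pos = 300, effect_allele = "A",
           other_allele = "T", beta = 0.1, eaf = 0.50,
           pval = twoSidedP(2))), "exp")
  ou <- AssocSet(rbind(
    recRow(variant_id = "rs1", pos = 100, effect_allele = "A",
           other_allele = "G", beta = 0.05, eaf = 0.3,
           pval = twoSidedP(1)),
    recRow(variant_id = "rs2", pos = 200, effect_allele = "G",
           other_allele = "A", beta = 0.05, eaf = 0.3,
           pval = twoSidedP(1)),
    recRow(variant_id = "rs3", pos = 300, effect_allele = "A",
           other_allele = "T", beta = 0.05, eaf = 0.50,
           pval = twoSidedP(1))), "out")
  h <- harmonizeSumstats(ex, ou)
  expect_equal(h$variant_id, c("rs1", "rs2"))  # palindrome dropped
  expect_equal(h$beta_out[h$variant_id == "rs1"], 0.05)   # aligned
  expect_equal(h$beta_out[h$variant_id == "rs2"], -0.05)  # swap flips
  expect_equal(h$eaf_out[h$variant_id == "rs2"], 0.7)
  expect_equal(attr(h, "report")$n_palindromic_dropped, 1L)
})

test_that("harmonization is an involution and symmetric in the MR product", {
  set.seed(11)
  m <- 15
  alleles <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  pick <- sample(4, m, replace = TRUE)
  mk <- function(traitId, flip) {
    z <- rnorm(m)
    eaf <- runif(m, 0.05, 0.95)
    rec <- do.call(rbind, lapply(seq_len(m), function(i) {
      al <- alleles[[pick[i]]]
      if (flip[i]) al <- rev(al)
      recRow(variant_id = paste0("rs", i), pos = i * 1000,
             effect_allele = al[1], other_allele = al[2],
             eaf = if (flip[i]) 1 - eaf[i] else eaf[i],
             beta = if (flip[i]) -z[i] * 0.05 else z[i] * 0.05,
             pval = twoSidedP(z[i]))
    }))
    AssocSet(rec, traitId)
  }
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ex <- mk("exp", rep(FALSE, m))
  ou <- mk("out", flip)
  h1 <- harmonizeSumstats(ex, ou)
  ## rebuild the outcome from the harmonized columns and re-harmonize:
  ## nothing may change (involution)
  ou2 <- AssocSet(
    data.frame(variant_id = h1$variant_id, chrom = h1$chrom,
               pos = h1$pos, effect_allele = h1$effect_allele,
               other_allele = h1$other_allele, eaf = h1$eaf_out,
               beta = h1$beta_out, se = h1$se_out, pval = h1$pval_out,
               n = h1$n_out), "out")
  h2 <- harmonizeSumstats(ex, ou2)
  keep <- intersect(h1$variant_id, h2$variant_id)
  expect_equal(h2[match(keep, h2$variant_id), c("beta_out", "eaf_out")],
               h1[match(keep, h1$variant_id), c("beta_out", "eaf_out")])
  ## direction symmetry: the MR-relevant product beta_exp * beta_out is
  ## invariant under swapping the roles of the two traits
  hba <- harmonizeSumstats(ou, ex)
  keep <- intersect(h1$variant_id, hba$variant_id)
  expect_equal(h1$beta_exp[match(keep, h1$variant_id)] *
                 h1$beta_out[match(keep, h1$variant_id)],
               hba$beta_exp[match(keep, hba$variant_id)] *
                 hba$beta_out[match(keep, hba$variant_id)])
})

test_that("harmonization fails on an empty intersection", {
  a <- assocFromZ(c(1, 2), ids = c("rs1", "rs2"))
  b <- assocFromZ(c(1, 2), ids = c("rs3", "rs4"))
  expect_error(harmonizeSumstats(a, b), "empty-intersection")
})

test_that("cis-window extraction is inclusive of both flanked endpoints", {
  a <- assocFromZ(rep(0.5, 4), pos = c(500, 1000, 1002000, 1002001),
                  ids = paste0("rs", 1:4))
  w <- genomicWindow("1", 1000, 2000)
  expect_equal(variantIds(extractCisWindow(a, w, flankBp = 1e6)),
               c("rs1", "rs2", "rs3"))
  expect_equal(variantIds(extractCisWindow(a, w, flankBp = 0)),
               "rs2")  # pos == start retained at flank 0
  off <- assocFromZ(0.5, pos = 1500, ids = "rs9")
  off@records$chrom <- "2"
  expect_equal(nVariants(extractCisWindow(off, w)), 0L)
})

test_that("two-sided p-values match the normal tail and never underflow to zero", {
  expect_equal(twoSidedP(0), 1)
  expect_equal(twoSidedP(1.959964), 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(twoSidedP(-2), twoSidedP(2))
  expect_gt(twoSidedP(40), 0)
  expect_gt(twoSidedP(400), 0)
})
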
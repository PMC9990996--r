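## Two-sample MR estimators and the transcriptome-wide scan.

.mrResult <- function(exposureId, outcomeId, method, nSnps, beta, se,
                      threshold = NA_real_, notes = character(0)) {
  pval <- twoSidedP(beta / se)
  methods::new("MRResult", exposureId = as.character(exposureId),
               outcomeId = as.character(outcomeId), method = method,
               nSnps = as.integer(nSnps), beta = beta, se = se,
               pval = pval,
               passesBonferroni = if (is.na(threshold)) NA else pval < threshold,
               bonferroniThreshold = threshold, notes = notes)
}

#' Wald ratio estimator
#'
#' Single-instrument MR estimate: `beta = bOut / bExp` with the
#' first-order delta-method standard error `se = seOut / |bExp|`
#' (which ignores the exposure uncertainty; set `secondOrder = TRUE`
#' for the two-term delta correction). A weak-instrument note is
#' attached when `|bExp / seExp| < 1`.
#'
#' @param bExp,seExp exposure effect and standard error (`bExp != 0`).
#' @param bOut,seOut outcome effect and standard error.
#' @param exposureId,outcomeId identifiers carried into the result.
#' @param bonferroniThreshold optional family-wise threshold.
#' @param secondOrder use the second-order delta-method se; default
#'   `FALSE`.
#' @return an [MRResult-class] with `method = "wald"`.
#' @export
waldRatio <- function(bExp, seExp, bOut, seOut, exposureId = "exposure",
                      outcomeId = "outcome",
                      bonferroniThreshold = NA_real_, secondOrder = FALSE) {
  if (bExp == 0) stop("undefined-ratio error: exposure beta is zero")
  stopifnot(seExp > 0, seOut > 0)
  beta <- bOut / bExp
  se <- if (secondOrder) {
    sqrt(seOut^2 / bExp^2 + bOut^2 * seExp^2 / bExp^4)
  } else {
    seOut / abs(bExp)
  }
  notes <- if (abs(bExp / seExp) < 1) "weak-instrument warning: |z_exp| < 1"
           else character(0)
  .mrResult(exposureId, outcomeId, "wald", 1L, beta, se,
            bonferroniThreshold, notes)
}

#' Fixed-effect inverse-variance-weighted estimator
#'
#' Combines per-instrument ratio estimates with weights
#' \eqn{w_i = se_i^{-2}}: `beta = sum(w*b)/sum(w)`,
#' `se = 1/sqrt(sum(w))`. With a single estimate the output equals that
#' estimate exactly. Instruments are assumed independent (post-clumping
#' at r-squared < 0.01).
#'
#' @param betas,ses per-instrument ratio estimates and standard errors.
#' @param exposureId,outcomeId identifiers carried into the result.
#' @param bonferroniThreshold optional family-wise threshold.
#' @return an [MRResult-class] with `method = "ivw"`.
#' @export
ivwEstimate <- function(betas, ses, exposureId = "exposure",
                        outcomeId = "outcome",
                        bonferroniThreshold = NA_real_) {
  if (length(betas) == 0L) stop("ivw requires at least one estimate")
  stopifnot(length(betas) == length(ses), all(ses > 0))
  w <- ses^-2
  .mrResult(exposureId, outcomeId, "ivw", length(betas),
            sum(w * betas) / sum(w), 1 / sqrt(sum(w)),
            bonferroniThreshold)
}

#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests in the family (>= 1).
#' @param alpha family-wise error rate; default 0.05.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(7443)  # 6.72e-06
#' bonferroniThreshold(700)   # 7.14e-05
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(nTests >= 1, alpha > 0, alpha < 1)
  alpha / nTests
}

## MR for one harmonized pair table restricted to the given instruments
.mrFromPairs <- function(pairs, instruments, exposureId, outcomeId,
                         threshold = NA_real_) {
  p <- pairs[pairs$variant_id %in% instruments, , drop = FALSE]
  if (nrow(p) == 0L) return(NULL)
  if (any(p$beta_exp == 0)) p <- p[p$beta_exp != 0, , drop = FALSE]
  if (nrow(p) == 0L) return(NULL)
  if (nrow(p) == 1L) {
    waldRatio(p$beta_exp, p$se_exp, p$beta_out, p$se_out,
              exposureId, outcomeId, threshold)
  } else {
    ivwEstimate(p$beta_out / p$beta_exp, p$se_out / abs(p$beta_exp),
                exposureId, outcomeId, threshold)
  }
}

#' Transcriptome-wide MR scan
#'
#' For each exposure (a gene's cis-QTL statistics): clump to obtain
#' independent instruments at `pInstrument`, harmonize against the
#' outcome, and estimate the causal effect with the Wald ratio (one
#' instrument) or fixed-effect IVW over per-SNP ratios (two or more).
#' The Bonferroni family is the number of exposures that actually
#' yielded an instrumented, harmonizable estimate for this outcome.
#' Exposures without usable instruments are skipped and recorded.
#'
#' @param exposures named list of [AssocSet-class] objects (one per
#'   gene).
#' @param outcome the outcome [AssocSet-class].
#' @param ld an [LDMatrix-class] covering all exposure variants, or a
#'   named list of per-exposure LD matrices.
#' @param pInstrument instrument p-value threshold; default 5e-8.
#' @param r2Thresh clumping r-squared threshold; default 0.01.
#' @param windowKb clumping window; default 1000.
#' @param alpha family-wise error rate for the Bonferroni threshold;
#'   default 0.05.
#' @return data.frame of MR results sorted by p-value (columns as
#'   [as.data.frame.MRResult()]), with attributes `"skipped"` (named
#'   reasons for dropped exposures) and `"n_tests"`.
#' @export
transcriptomeScan <- function(exposures, outcome, ld, pInstrument = 5e-8,
                              r2Thresh = 0.01, windowKb = 1000,
                              alpha = 0.05) {
  stopifnot(length(exposures) >= 1L, !is.null(names(exposures)))
  ldFor <- function(id) if (methods::is(ld, "LDMatrix")) ld else ld[[id]]
  prepared <- list()
  skipped <- character(0)
  for (id in names(exposures)) {
    cl <- clumpVariants(exposures[[id]], ldFor(id), pIndex = pInstrument,
                        r2Thresh = r2Thresh, windowKb = windowKb)
    if (length(indexVariants(cl)) == 0L) {
      skipped[id] <- "no instrument at pInstrument"
      next
    }
    pairs <- tryCatch(harmonizeSumstats(exposures[[id]], outcome),
                      error = function(e) NULL)
    if (is.null(pairs) ||
        !any(indexVariants(cl) %in% pairs$variant_id)) {
      skipped[id] <- "no harmonizable instrument"
      next
    }
    prepared[[id]] <- list(pairs = pairs, instruments = indexVariants(cl))
  }
  nTests <- length(prepared)
  if (nTests == 0L) {
    out <- data.frame()
    attr(out, "skipped") <- skipped
    attr(out, "n_tests") <- 0L
    return(out)
  }
  threshold <- bonferroniThreshold(nTests, alpha)
  rows <- list()
  for (id in names(prepared)) {
    res <- .mrFromPairs(prepared[[id]]$pairs, prepared[[id]]$instruments,
                        id, traitId(outcome), threshold)
    if (is.null(res)) {
      skipped[id] <- "all instrument exposure betas zero"
      next
    }
    rows[[id]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pval, out$exposure_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_tests") <- nTests
  out
}
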
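## Pairwise Bayesian colocalization via Wakefield approximate Bayes
## factors.

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's asymptotic Bayes factor for a normal effect prior
#' N(0, W^2) against the point null, written as a log shrinkage weight:
#' with \eqn{r = W^2/(se^2 + W^2)} and \eqn{z = beta/se},
#' \deqn{\log ABF = \tfrac12 \log(1 - r) + r z^2 / 2.}
#' Vectorized over `beta`/`se`.
#'
#' @param beta,se marginal effect estimate(s) and standard error(s)
#'   (`se > 0`).
#' @param priorSd prior SD `W >= 0` of the true effect; `W = 0` gives
#'   log ABF 0 (Bayes factor 1).
#' @return numeric vector of log Bayes factors.
#' @export
logABF <- function(beta, se, priorSd) {
  stopifnot(all(se > 0), priorSd >= 0)
  r <- priorSd^2 / (se^2 + priorSd^2)
  z <- beta / se
  0.5 * log1p(-r) + r * z^2 / 2
}

#' Default effect-scale prior SD for a trait
#'
#' @param traitType `"quantitative"` or `"binary"`.
#' @param sdY phenotype SD for quantitative traits; default 1 (and `NA`
#'   is treated as 1).
#' @return `0.15 * sdY` for quantitative traits, `0.2` (log-odds scale)
#'   for binary traits.
#' @export
priorSdForTrait <- function(traitType, sdY = 1) {
  stopifnot(traitType %in% c("quantitative", "binary"))
  if (traitType == "binary") return(0.2)
  if (is.na(sdY)) sdY <- 1
  0.15 * sdY
}

.abfVector <- function(assoc, priorSd = NULL) {
  if (is.null(priorSd)) priorSd <- priorSdForTrait(traitType(assoc), sdY(assoc))
  rec <- records(assoc)
  stats::setNames(logABF(rec$beta, rec$se, priorSd), rec$variant_id)
}

#' Pairwise colocalization over a cis-region
#'
#' Computes posterior probabilities of the five causal configurations
#' (H0 none, H1 trait 1 only, H2 trait 2 only, H3 two distinct causal
#' variants, H4 one shared causal variant) from per-variant log ABFs
#' \eqn{\ell^1, \ell^2} over the shared variants:
#' \deqn{L_0 = 1,\quad L_1 = p_1 \sum_i e^{\ell^1_i},\quad
#'       L_2 = p_2 \sum_i e^{\ell^2_i},}
#' \deqn{L_3 = p_1 p_2 \Big[\sum_i e^{\ell^1_i}\sum_j e^{\ell^2_j}
#'       - \sum_i e^{\ell^1_i + \ell^2_i}\Big],\quad
#'       L_4 = p_{12} \sum_i e^{\ell^1_i + \ell^2_i},}
#' all in log-sum-exp arithmetic, then normalizes. Variants are matched
#' on `variant_id` (ABFs depend on z-squared only, so allele alignment
#' cannot change the posteriors); variants missing in either trait are
#' dropped.
#'
#' @param assoc1,assoc2 [AssocSet-class] objects for the two traits.
#' @param priors a [colocPriors()] list; defaults `p1 = p2 = 1e-4`,
#'   `p12 = 1e-5`.
#' @param priorSd1,priorSd2 effect priors; default from
#'   [priorSdForTrait()] using each trait's type and `sdY`.
#' @return a [ColocResult-class].
#' @export
colocABF <- function(assoc1, assoc2, priors = colocPriors(),
                     priorSd1 = NULL, priorSd2 = NULL) {
  l1 <- .abfVector(assoc1, priorSd1)
  l2 <- .abfVector(assoc2, priorSd2)
  shared <- intersect(names(l1), names(l2))
  if (length(shared) == 0L)
    stop("empty-intersection error: no shared variants for colocalization")
  l1 <- l1[shared]
  l2 <- l2[shared]
  S1 <- .logSumExp(l1)
  S2 <- .logSumExp(l2)
  D12 <- .logSumExp(l1 + l2)
  logL <- c(
    H0 = 0,
    H1 = log(priors$p1) + S1,
    H2 = log(priors$p2) + S2,
    H3 = if (length(shared) == 1L) -Inf else
      log(priors$p1) + log(priors$p2) + .logDiffExp(S1 + S2, D12),
    H4 = log(priors$p12) + D12)
  pp <- exp(logL - .logSumExp(logL))
  pp <- pp / sum(pp)
  methods::new("ColocResult", pp = stats::setNames(pp, paste0("PP.", names(logL))),
               nSnps = length(shared), priors = priors)
}
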
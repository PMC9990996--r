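## Synthetic reference panels and multi-trait marginal summary
## statistics with known causal structure.

#' AR(1) LD matrix
#'
#' Builds the LD matrix \eqn{r_{ij} = \rho^{|i-j|}} over `m` variants
#' (positive definite by construction for `0 <= rho < 1`).
#'
#' @param m number of variants.
#' @param ldRho decay parameter in \[0, 1).
#' @param variantIds optional identifiers; default `v1..vm`.
#' @return an [LDMatrix-class].
#' @export
makeLDMatrix <- function(m, ldRho, variantIds = NULL) {
  stopifnot(m >= 1, ldRho >= 0, ldRho < 1)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(m))
  LDMatrix(.ar1Matrix(m, ldRho), variantIds)
}

#' Simulate a reference genotype panel
#'
#' Draws two haplotypes per individual by Gaussian-copula thresholding:
#' each haplotype is a latent MVN(0, ld) vector thresholded at the
#' per-variant allele-frequency quantile; the dosage is the haplotype
#' sum. Empirical dosage correlations converge to a monotone transform
#' of the latent LD as the panel grows.
#'
#' @param nRef number of individuals (>= 2).
#' @param ld an [LDMatrix-class] (the latent haplotype correlation).
#' @param mafs per-variant allele frequencies in (0, 1).
#' @return integer dosage matrix, `nRef` x `nVariants(ld)`, entries in
#'   \{0, 1, 2\}, columns named by variant id.
#' @export
simulateReferencePanel <- function(nRef, ld, mafs) {
  m <- nVariants(ld)
  stopifnot(nRef >= 2, length(mafs) == m, all(mafs > 0), all(mafs < 1))
  U <- chol(corMatrix(ld))
  thr <- stats::qnorm(mafs)
  hap <- function() {
    latent <- matrix(stats::rnorm(nRef * m), nRef, m) %*% U
    t(t(latent) < thr) * 1L
  }
  dos <- hap() + hap()
  colnames(dos) <- variantIds(ld)
  dos
}

#' Simulate marginal summary statistics for a scenario
#'
#' Draws each trait's marginal z-score vector from
#' \eqn{z \sim MVN(\sqrt{n}\, R\, \tilde b,\; R)} where \eqn{\tilde b}
#' is the standardized causal-effect vector, then back-transforms to
#' the beta/se scale with \eqn{se_j = 1/\sqrt{2\,maf_j(1-maf_j)\,n}}
#' and \eqn{beta_j = z_j\, se_j}. Binary traits use the effective
#' sample size \eqn{4/(1/n_{cases}+1/n_{controls})} on the log-odds
#' scale. The vertical-pleiotropy (mediation) scenario replaces the
#' last trait's causal effects by `mediationTheta` times the first
#' trait's. Optional per-trait coverage truncation (position window
#' and/or p-value filter) is applied last, emulating truncated QTL
#' release formats. The causal truth is recorded in the result.
#'
#' @param scenario a [ScenarioConfig-class].
#' @param includePanel also draw a reference panel of `nRef`
#'   individuals; default `FALSE`.
#' @param nRef panel size when `includePanel = TRUE`.
#' @return a [SimulatedRegion-class] (`simAssoc(x)` for the per-trait
#'   [AssocSet-class] list, `simTruth(x)` for the causal assignments,
#'   `simLD(x)` for the true LD).
#' @export
simulateSummaryStats <- function(scenario, includePanel = FALSE,
                                 nRef = 500) {
  stopifnot(methods::is(scenario, "ScenarioConfig"))
  methods::validObject(scenario)
  if (!is.na(scenario@seed)) set.seed(scenario@seed)
  m <- scenario@m
  ids <- paste0("v", seq_len(m))
  pos <- 1 + (seq_len(m) - 1) * 1000  # 1 kb grid on chromosome 1
  maf <- stats::runif(m, scenario@mafRange[1], scenario@mafRange[2])
  R <- .ar1Matrix(m, scenario@ldRho)
  U <- .ar1Chol(m, scenario@ldRho)
  ld <- LDMatrix(R, ids)

  traits <- scenario@traits
  theta <- scenario@mediationTheta
  if (!is.na(theta) && length(traits) >= 2L) {
    first <- traits[[1L]]
    last <- length(traits)
    traits[[last]]$causal_pos <- first$causal_pos
    traits[[last]]$causal_beta <- theta * first$causal_beta
  }

  assoc <- list()
  truth <- list(maf = stats::setNames(maf, ids),
                mediation_theta = theta, traits = list())
  for (tr in traits) {
    nEff <- .effectiveN(tr)
    sdy <- tr$sd_y %||% 1
    btilde <- numeric(m)
    if (length(tr$causal_pos))
      btilde[tr$causal_pos] <- tr$causal_beta / sdy
    mu <- if (all(btilde == 0)) numeric(m)
          else sqrt(nEff) * drop(R %*% btilde)
    z <- .mvnDraw(mu, U)
    se <- 1 / sqrt(2 * maf * (1 - maf) * nEff)
    rec <- data.frame(
      variant_id = ids, chrom = "1", pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = z * se, se = se, pval = twoSidedP(z),
      n = if (!is.null(tr$n_cases)) tr$n_cases + tr$n_controls else tr$n,
      stringsAsFactors = FALSE)
    if (!is.null(tr$coverage)) {
      cov <- tr$coverage
      keep <- rep(TRUE, m)
      if (!is.null(cov$center_pos) && !is.null(cov$window_bp))
        keep <- keep & abs(rec$pos - cov$center_pos) <= cov$window_bp
      if (!is.null(cov$p_max)) keep <- keep & rec$pval <= cov$p_max
      rec <- rec[keep, , drop = FALSE]
    }
    tt <- tr$trait_type %||% "quantitative"
    assoc[[tr$trait_id]] <- AssocSet(rec, traitId = tr$trait_id,
                                     traitType = tt, sdY = sdy)
    truth$traits[[tr$trait_id]] <- list(
      causal_idx = tr$causal_pos,
      causal_ids = ids[tr$causal_pos],
      causal_beta_standardized = if (length(tr$causal_pos))
        tr$causal_beta / sdy else numeric(0),
      n_eff = nEff)
  }
  panel <- if (includePanel) simulateReferencePanel(nRef, ld, maf) else NULL
  methods::new("SimulatedRegion", ld = ld, panel = panel, assoc = assoc,
               truth = truth)
}

#' Canonical simulation scenarios
#'
#' Named [ScenarioConfig-class] objects covering the causal structures
#' the pipeline must distinguish. Defaults emulate the study design the
#' package targets: brain-scale eQTL exposure (n = 1194), blood-scale
#' eQTL (n = 31684), GWAS outcomes of n = 50000, cis-regions of m = 200
#' variants on an AR(1) LD backbone with rho = 0.9, and standardized
#' causal effects chosen so the causal variant's expected |z| is ~9
#' (comfortably past the 5e-8 instrument threshold).
#'
#' Scenarios: `h4_shared` (eQTL and GWAS share one causal variant),
#' `h3_distinct` (two distinct causal variants with r-squared < 0.01),
#' `three_way_shared` (expression, methylation and trait share one
#' variant), `two_eqtl_signals` (two independent eQTL signals, only the
#' first shared with methylation and trait), `null` (no causal variants
#' anywhere), `mediation` (vertical pleiotropy with causal ratio
#' theta = 0.3 through a blood-scale exposure), and `truncated_mqtl`
#' (three-way sharing with the methylation coverage truncated to a
#' 100 kb window and p < 1e-3, emulating truncated mQTL releases).
#'
#' @param seed seed stored in every scenario (`NA` to inherit the
#'   caller's RNG state).
#' @return named list of `ScenarioConfig` objects.
#' @export
scenarioLibrary <- function(seed = NA_real_) {
  nBrain <- 1194
  nBlood <- 31684
  nGwas <- 50000
  bE <- 0.26   # sqrt(1194) * 0.26 ~ 9.0
  bG <- 0.04   # sqrt(50000) * 0.04 ~ 8.9
  eqtl <- function(pos, beta = bE, n = nBrain, id = "eqtl")
    list(trait_id = id, trait_type = "quantitative", n = n,
         causal_pos = pos, causal_beta = beta)
  mqtl <- function(pos, beta = bE, coverage = NULL)
    list(trait_id = "mqtl", trait_type = "quantitative", n = nBrain,
         causal_pos = pos, causal_beta = beta, coverage = coverage)
  gwas <- function(pos, beta = bG)
    list(trait_id = "gwas", trait_type = "quantitative", n = nGwas,
         causal_pos = pos, causal_beta = beta)
  list(
    h4_shared = scenarioConfig(200, 0.9, list(eqtl(100), gwas(100)),
                               seed = seed),
    h3_distinct = scenarioConfig(200, 0.9, list(eqtl(50), gwas(150)),
                                 seed = seed),
    three_way_shared = scenarioConfig(
      200, 0.9, list(eqtl(100), mqtl(100), gwas(100)), seed = seed),
    two_eqtl_signals = scenarioConfig(
      200, 0.9, list(eqtl(c(50, 150), c(bE, bE)), mqtl(50), gwas(50)),
      seed = seed),
    null = scenarioConfig(
      200, 0.9, list(eqtl(integer(0), numeric(0)),
                     gwas(integer(0), numeric(0))), seed = seed),
    mediation = scenarioConfig(
      200, 0.9, list(eqtl(100, 0.5, n = nBlood), gwas(100)),
      mediationTheta = 0.3, seed = seed),
    truncated_mqtl = scenarioConfig(
      200, 0.9,
      list(eqtl(100), mqtl(100, coverage = list(center_pos = 99001,
                                                window_bp = 50000,
                                                p_max = 1e-3)),
           gwas(100)),
      seed = seed)
  )
}
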
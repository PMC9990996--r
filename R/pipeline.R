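## End-to-end orchestration: configuration validation, the full scan
## (instruments -> MR -> colocalization -> optional multi-trait
## colocalization -> clustering), and the phenome-wide scan.

#' Validate and assemble a run configuration
#'
#' All thresholds default to the values the pipeline is designed
#' around: instrument p = 5e-8, clump r-squared = 0.01, colocalization
#' PPA = 0.8, replication heuristic p = 0.05, alpha = 0.05, cis flank
#' 1 Mb, CpG window 100 kb. Out-of-range values fail validation before
#' any stage executes.
#'
#' @param exposures named list of exposure [AssocSet-class] objects.
#' @param outcomes named list of outcome [AssocSet-class] objects.
#' @param ld an [LDMatrix-class] or named per-exposure list.
#' @param mqtl optional named list (per gene) of named lists (per CpG)
#'   of methylation [AssocSet-class] objects.
#' @param geneCoords optional named list of [GenomicWindow-class]
#'   objects (required for the moloc stage).
#' @param cpgCoords optional CpG coordinate data.frame
#'   ([readFeatureCoords()] format).
#' @param phewasOutcomes optional named list of outcome sets for
#'   [runPhewas()].
#' @param pInstrument,clumpR2,windowKb,ppaThreshold,heuristicP,alpha
#'   thresholds (see description).
#' @param cisFlankBp,cpgWindowBp window sizes in bp.
#' @param molocPriors per-cardinality sharing priors.
#' @param seed integer seed controlling every stochastic step of a run.
#' @param outputDir optional directory; when set, every intermediate
#'   table is persisted as TSV/JSON.
#' @return validated config (class `"omicsMRConfig"`).
#' @export
runConfig <- function(exposures, outcomes, ld, mqtl = NULL,
                      geneCoords = NULL, cpgCoords = NULL,
                      phewasOutcomes = NULL, pInstrument = 5e-8,
                      clumpR2 = 0.01, windowKb = 1000,
                      ppaThreshold = 0.8, heuristicP = 0.05,
                      alpha = 0.05, cisFlankBp = 1e6, cpgWindowBp = 1e5,
                      molocPriors = c(1e-4, 1e-6, 1e-7), seed = 1,
                      outputDir = NULL) {
  bad <- function(msg) stop("config validation error: ", msg)
  if (length(exposures) == 0L || is.null(names(exposures)))
    bad("exposures must be a non-empty named list")
  if (length(outcomes) == 0L || is.null(names(outcomes)))
    bad("outcomes must be a non-empty named list")
  inUnit <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x <= 1
  if (!inUnit(pInstrument)) bad("pInstrument must lie in (0, 1]")
  if (!inUnit(clumpR2)) bad("clumpR2 must lie in (0, 1]")
  if (!inUnit(ppaThreshold)) bad("ppaThreshold must lie in (0, 1]")
  if (!inUnit(heuristicP)) bad("heuristicP must lie in (0, 1]")
  if (!inUnit(alpha) || alpha >= 1) bad("alpha must lie in (0, 1)")
  if (cisFlankBp < 0 || cpgWindowBp < 0) bad("windows must be >= 0")
  if (windowKb <= 0) bad("windowKb must be > 0")
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 mqtl = mqtl, geneCoords = geneCoords,
                 cpgCoords = cpgCoords, phewasOutcomes = phewasOutcomes,
                 pInstrument = pInstrument, clumpR2 = clumpR2,
                 windowKb = windowKb, ppaThreshold = ppaThreshold,
                 heuristicP = heuristicP, alpha = alpha,
                 cisFlankBp = cisFlankBp, cpgWindowBp = cpgWindowBp,
                 molocPriors = molocPriors, seed = as.integer(seed),
                 outputDir = outputDir),
            class = "omicsMRConfig")
}

.persist <- function(config, name, obj) {
  dir <- config$outputDir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Run the full multi-omic MR scan
#'
#' Executes the pipeline stage by stage: instrument selection (clumping
#' per exposure), MR scan per outcome with Bonferroni correction over
#' the instrumented exposures, colocalization of every
#' Bonferroni-passing effect, optional multi-trait colocalization with
#' methylation (with conditional decomposition of multi-signal loci),
#' and cross-trait clustering of the passing genes' effects. Every
#' stage's output is returned (and persisted under `outputDir` when
#' configured); a stage failure aborts with a stage-tagged error after
#' persisting the completed stages. A rerun with the same config and
#' seed reproduces the tables exactly.
#'
#' @param config an [runConfig()] object.
#' @return list with `mr` (all MR results), `coloc` (per passing
#'   effect: `pp_h4`, `passes_ppa`), `hits` (effects passing both
#'   Bonferroni and the PPA threshold), `moloc` (per-gene best
#'   multi-trait results, when methylation data configured),
#'   `clustering` (when >= 2 passing genes), and `report` (per-stage
#'   counts and thresholds).
#' @export
runScan <- function(config) {
  stopifnot(inherits(config, "omicsMRConfig"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ldFor <- function(id) if (methods::is(config$ld, "LDMatrix")) config$ld
                        else config$ld[[id]]

  mrAll <- list()
  report <- list(seed = config$seed,
                 thresholds = config[c("pInstrument", "clumpR2",
                                       "ppaThreshold", "alpha")],
                 n_exposures = length(config$exposures),
                 n_outcomes = length(config$outcomes))
  stage("mr_scan", {
    for (oid in names(config$outcomes)) {
      res <- transcriptomeScan(config$exposures, config$outcomes[[oid]],
                               config$ld, pInstrument = config$pInstrument,
                               r2Thresh = config$clumpR2,
                               windowKb = config$windowKb,
                               alpha = config$alpha)
      if (nrow(res)) mrAll[[oid]] <- res
      report$mr_counts[[oid]] <- list(
        tested = attr(res, "n_tests"),
        skipped = length(attr(res, "skipped")),
        bonferroni_passing = if (nrow(res)) sum(res$passes_bonferroni)
                             else 0L)
    }
  })
  mrTab <- if (length(mrAll)) do.call(rbind, c(mrAll, make.row.names = FALSE))
           else data.frame()
  .persist(config, "mr_scan.tsv", mrTab)

  colocTab <- data.frame()
  stage("coloc", {
    passing <- mrTab[!is.na(mrTab$passes_bonferroni) &
                       mrTab$passes_bonferroni, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(passing))) {
      gid <- passing$exposure_id[i]
      oid <- passing$outcome_id[i]
      cres <- tryCatch(
        colocABF(config$exposures[[gid]], config$outcomes[[oid]]),
        error = function(e) NULL)
      if (is.null(cres)) next
      pp4 <- unname(posteriorProbs(cres)["PP.H4"])
      rows[[length(rows) + 1L]] <- data.frame(
        exposure_id = gid, outcome_id = oid, n_snps = cres@nSnps,
        pp_h4 = pp4, passes_ppa = pp4 > config$ppaThreshold,
        stringsAsFactors = FALSE)
    }
    colocTab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  })
  .persist(config, "coloc.tsv", colocTab)

  hits <- if (nrow(colocTab))
    merge(mrTab, colocTab[colocTab$passes_ppa, , drop = FALSE],
          by = c("exposure_id", "outcome_id")) else data.frame()
  report$n_bonferroni_passing <- if (nrow(mrTab))
    sum(mrTab$passes_bonferroni, na.rm = TRUE) else 0L
  report$n_hits <- nrow(hits)
  report$hit_genes <- unique(hits$exposure_id)
  .persist(config, "hits.tsv", hits)

  molocOut <- NULL
  if (!is.null(config$mqtl)) {
    stage("moloc", {
      molocOut <- list()
      for (gid in intersect(unique(hits$exposure_id), names(config$mqtl))) {
        gw <- config$geneCoords[[gid]]
        if (is.null(gw)) next
        for (oid in hits$outcome_id[hits$exposure_id == gid]) {
          molocOut[[paste(gid, oid, sep = ".")]] <- decomposeAndMoloc(
            gid, config$exposures[[gid]], config$mqtl[[gid]],
            config$outcomes[[oid]], ldFor(gid), gw, config$cpgCoords,
            pIndex = config$pInstrument, r2Thresh = config$clumpR2,
            windowKb = config$windowKb, windowBp = config$cpgWindowBp,
            priors = config$molocPriors)
        }
      }
      molocTab <- do.call(rbind, unlist(lapply(molocOut, function(sig)
        lapply(sig, `[[`, "table")), recursive = FALSE))
      report$n_moloc_loci <- if (!is.null(molocTab) && nrow(molocTab))
        length(unique(molocTab$gene_id[molocTab$ppa_full >
                                         config$ppaThreshold])) else 0L
      .persist(config, "moloc.tsv",
               if (is.null(molocTab)) data.frame() else molocTab)
    })
  }

  clustering <- NULL
  stage("clustering", {
    genes <- unique(hits$exposure_id)
    if (length(genes) >= 2L && nrow(mrTab)) {
      em <- buildEffectMatrix(
        mrTab[mrTab$exposure_id %in% genes,
              c("exposure_id", "outcome_id", "beta")])
      clustering <- list(effectMatrix = em,
                         cluster = euclideanCluster(em))
      .persist(config, "effect_matrix.tsv",
               data.frame(gene_id = rownames(effectValues(em)),
                          effectValues(em), check.names = FALSE))
    }
  })
  .persist(config, "report.json", report)
  list(mr = mrTab, coloc = colocTab, hits = hits, moloc = molocOut,
       clustering = clustering, report = report)
}

#' Run a phenome-wide MR scan for one gene
#'
#' Scans the gene's instruments against the configured outcome
#' catalogue ([phewasScan()]) at the phenome-wide Bonferroni threshold
#' `alpha / n_outcomes`, and returns the flagged table together with
#' bi-directional plot data (signed -log10 p per outcome).
#'
#' @param config an [runConfig()] object with `phewasOutcomes` set.
#' @param geneId which exposure to scan.
#' @param doColoc also colocalize each outcome; default `FALSE`.
#' @return list with `table`, `bonferroniThreshold`, `pleiotropyCount`,
#'   `skipped` and `plotData` (outcome, signed log10 p, flagged).
#' @export
runPhewas <- function(config, geneId, doColoc = FALSE) {
  stopifnot(inherits(config, "omicsMRConfig"))
  if (is.null(config$phewasOutcomes) ||
      length(config$phewasOutcomes) == 0L)
    stop("config validation error: no phenome-wide outcomes configured")
  if (!geneId %in% names(config$exposures))
    stop("config validation error: unknown gene '", geneId, "'")
  set.seed(config$seed)
  ld <- if (methods::is(config$ld, "LDMatrix")) config$ld
        else config$ld[[geneId]]
  scan <- phewasScan(config$exposures[[geneId]], config$phewasOutcomes,
                     ld, pInstrument = config$pInstrument,
                     r2Thresh = config$clumpR2,
                     windowKb = config$windowKb, alpha = config$alpha,
                     doColoc = doColoc)
  plotData <- if (nrow(scan$table))
    data.frame(outcome_id = scan$table$outcome_id,
               signed_log10p = -log10(scan$table$pval) *
                 sign(scan$table$beta),
               flagged = scan$table$flagged, stringsAsFactors = FALSE)
    else data.frame()
  .persist(config, paste0("phewas_", geneId, ".tsv"), scan$table)
  c(scan, list(plotData = plotData))
}
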
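## Base-graphics visualizations of scan outputs.

#' Heatmap of the clustered gene-by-trait effect matrix
#'
#' Draws the per-trait standardized MR betas with rows and columns in
#' cluster-leaf order; missing cells are shown blank.
#'
#' @param effMat an [EffectMatrix-class].
#' @param cluster optional [euclideanCluster()] result; computed when
#'   omitted.
#' @param ... passed to [graphics::image()].
#' @return the plotted matrix, invisibly.
#' @export
plotEffectHeatmap <- function(effMat, cluster = NULL, ...) {
  if (is.null(cluster)) cluster <- euclideanCluster(effMat)
  v <- effectValues(effMat)
  msk <- effectMask(effMat)
  v[!msk] <- NA
  v <- v[cluster$rowOrder, cluster$colOrder, drop = FALSE]
  pal <- grDevices::hcl.colors(51, "Blue-Red 3")
  lim <- max(abs(v), na.rm = TRUE)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v), col = pal,
                  zlim = c(-lim, lim), axes = FALSE, xlab = "", ylab = "",
                  ...)
  graphics::axis(1, seq_len(ncol(v)), colnames(v), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(v)), rownames(v), las = 2, cex.axis = 0.7)
  invisible(v)
}

#' Bi-directional phenome-wide association plot
#'
#' Signed -log10 p per outcome (positive effects up, negative down)
#' with the phenome-wide Bonferroni threshold drawn on both sides.
#'
#' @param phewas result of [phewasScan()] or [runPhewas()].
#' @param ... passed to [graphics::plot()].
#' @return the plot data, invisibly.
#' @export
plotPhewas <- function(phewas, ...) {
  tab <- phewas$table
  stopifnot(nrow(tab) > 0L)
  y <- -log10(tab$pval) * sign(tab$beta)
  thr <- -log10(phewas$bonferroniThreshold)
  graphics::plot(seq_along(y), y, pch = 19,
                 col = ifelse(tab$flagged, "firebrick", "grey50"),
                 xlab = "outcome", ylab = "signed -log10 p", ...)
  graphics::abline(h = c(-thr, thr), lty = 2, col = "grey30")
  graphics::abline(h = 0, col = "grey80")
  invisible(data.frame(outcome_id = tab$outcome_id, signed_log10p = y,
                       flagged = tab$flagged))
}
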
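#' @export
print.phenoz <- function(x, ...) {
  cat("Harmonized phenotype Z matrix (phenoz fit)\n")
  cat(sprintf("  %d lines x %d assays, %d unmeasured cells\n",
              nrow(x$z), ncol(x$z), sum(!x$mask)))
  cat(sprintf("  bootstrap: B = %d, common n = %d; BH scope: %s; |z| cap = %g\n",
              x$params$B, x$params$n_boot, x$params$family_scope, x$params$z_cap))
  tally <- table(factor(x$tier[x$mask], levels = .tier_levels))
  cat("  tiers:", paste(sprintf("%s=%d", names(tally), as.integer(tally)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a harmonized fit
#'
#' @param object a `phenoz` fit.
#' @param n_top number of strongest adjusted effects to list.
#' @param ... unused.
#' @return a `summary.phenoz` list with the per-assay tier tally and the
#'   strongest effects.
#' @export
summary.phenoz <- function(object, n_top = 10, ...) {
  tiers_by_assay <- t(apply(object$tier, 2, function(col) {
    table(factor(col[!is.na(col)], levels = .tier_levels))
  }))
  ord <- order(-abs(object$z_adj), na.last = TRUE)
  idx <- head(ord[!is.na(object$z_adj[ord])], n_top)
  rc <- arrayInd(idx, dim(object$z_adj))
  top <- data.frame(
    line = rownames(object$z_adj)[rc[, 1]],
    assay = colnames(object$z_adj)[rc[, 2]],
    z = object$z[idx], z_adj = object$z_adj[idx],
    p_adj = object$p_adj[idx], tier = object$tier[idx],
    stringsAsFactors = FALSE)
  structure(list(tiers_by_assay = tiers_by_assay, top = top,
                 params = object$params), class = "summary.phenoz")
}

#' @export
print.summary.phenoz <- function(x, ...) {
  cat("Per-assay FDR tier counts:\n")
  print(x$tiers_by_assay)
  cat("\nStrongest adjusted effects:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract the effect matrix from a harmonized fit
#'
#' @param object a `phenoz` fit.
#' @param type `"adjusted"` (default) or `"raw"` Z matrix.
#' @param genes if `TRUE`, return the allele-averaged gene-level matrix.
#' @param ... unused.
#' @return a numeric matrix (lines or genes by assays).
#' @export
coef.phenoz <- function(object, type = c("adjusted", "raw"), genes = FALSE, ...) {
  type <- match.arg(type)
  m <- if (type == "adjusted") object$z_adj else object$z
  if (genes) average_alleles(object, what = type) else m
}

#' Heatmap of a harmonized fit
#'
#' Draws the adjusted-Z matrix as a red/blue diverging heatmap (red =
#' increased response relative to the reference, blue = decreased, white =
#' near zero, grey = not measured), with rows optionally ordered by
#' Ward/Euclidean clustering.
#'
#' @param x a `phenoz` fit.
#' @param cluster_rows order rows by [cluster_ward_euclidean()] (default
#'   TRUE when the matrix has >= 3 rows).
#' @param threshold if `TRUE`, cells below the lowest FDR tier are blanked to
#'   white, reproducing a tier-thresholded integrated heatmap.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the row order used.
#' @export
plot.phenoz <- function(x, cluster_rows = nrow(x$z_adj) >= 3, threshold = FALSE, ...) {
  m <- x$z_adj
  if (threshold) m[x$tier == "ns"] <- 0
  ord <- seq_len(nrow(m))
  if (cluster_rows) ord <- cluster_ward_euclidean(m)$order
  m <- m[ord, , drop = FALSE]
  cap <- x$params$z_cap
  pal <- colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(255)
  filled <- m
  filled[is.na(filled)] <- 0
  op <- par(mar = c(7, 7, 2, 1)); on.exit(par(op))
  image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(filled),
        zlim = c(-cap, cap), col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  if (any(is.na(m))) {  # overlay unmeasured cells in grey
    na_idx <- which(is.na(m), arr.ind = TRUE)
    graphics::rect(na_idx[, 2] - 0.5, na_idx[, 1] - 0.5,
                   na_idx[, 2] + 0.5, na_idx[, 1] + 0.5,
                   col = "grey70", border = NA)
  }
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.7)
  axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2, cex.axis = 0.6)
  box()
  invisible(ord)
}
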
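#' Hierarchical clustering recipes for integrated phenotype heatmaps
#'
#' Two agglomerative recipes are provided, matching the two heatmap styles
#' used for integrated mutant-phenotype matrices:
#'
#' * [cluster_ward_euclidean()]: Ward's minimum-variance linkage on Euclidean
#'   distances (`stats::hclust(method = "ward.D2")`), for clustering lines by
#'   their full adjusted-Z profile.  Unmeasured cells are set to 0 first -
#'   the semantically neutral "no difference from wild type" adjusted Z.
#' * [cluster_complete_pearson()]: complete linkage on `1 - r` distances,
#'   with Pearson `r` computed over pairwise-complete columns, for grouping
#'   lines by the *shape* of their response profile regardless of magnitude.
#'
#' Both return ordinary [stats::hclust] trees (heights nondecreasing, n-1
#' merges) tagged with `attr(, "metric")` and `attr(, "linkage")`, so all of
#' base R's dendrogram tooling applies.
#'
#' @name phenoclust
NULL

.as_cluster_matrix <- function(x) {
  if (inherits(x, "phenoz")) x <- x$z_adj
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  x
}

#' @rdname phenoclust
#' @param x a numeric matrix (rows are clustered) or a `phenoz` fit (its
#'   adjusted-Z matrix is used).
#' @param impute_missing replace unmeasured (`NA`) cells by 0 before
#'   computing Euclidean distances (default TRUE).
#' @return an [stats::hclust] object.
#' @examples
#' m <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
#' cluster_ward_euclidean(m)$merge
#' @export
cluster_ward_euclidean <- function(x, impute_missing = TRUE) {
  x <- .as_cluster_matrix(x)
  .assert(nrow(x) >= 2L, "clustering needs at least 2 rows")
  if (impute_missing) x[is.na(x)] <- 0
  .assert(all(is.finite(x)), "matrix must be numeric after the missing-data policy")
  hc <- hclust(dist(x), method = "ward.D2")
  attr(hc, "metric") <- "euclidean"; attr(hc, "linkage") <- "ward"
  hc
}

#' @rdname phenoclust
#' @export
cluster_complete_pearson <- function(x) {
  x <- .as_cluster_matrix(x)
  .assert(nrow(x) >= 2L, "clustering needs at least 2 rows")
  rv <- apply(x, 1, function(r) var(r[!is.na(r)]))
  if (any(!is.finite(rv) | rv == 0)) {
    bad <- rownames(x)[which(!is.finite(rv) | rv == 0)]
    stop("zero-variance row(s) have no defined correlation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  overlap <- tcrossprod(!is.na(x))
  if (any(overlap[upper.tri(overlap)] < 3)) {
    stop("every pair of rows needs >= 3 overlapping non-missing values",
         call. = FALSE)
  }
  r <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  hc <- hclust(as.dist(1 - r), method = "complete")
  attr(hc, "metric") <- "1-pearson"; attr(hc, "linkage") <- "complete"
  hc
}

.quote_newick <- function(lab) {
  needs <- grepl("[][ \t(),:;']", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Export a dendrogram as a Newick string
#'
#' Writes an [stats::hclust] tree in Newick format with ultrametric branch
#' lengths: every node sits at half its merge height, so two leaves merging
#' at height `h` are written `(A:h/2,B:h/2);`.  Leaf labels containing
#' spaces or Newick metacharacters are single-quoted per the Newick
#' convention.
#'
#' @param hc an [stats::hclust] object.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string (terminated by `;`).
#' @examples
#' export_newick(cluster_ward_euclidean(matrix(rnorm(20), 4, 5)))
#' @export
export_newick <- function(hc, digits = 8) {
  .assert(inherits(hc, "hclust"), "hc must be an hclust object")
  labs <- .quote_newick(if (is.null(hc$labels)) as.character(seq_along(hc$order))
                        else hc$labels)
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node <- function(k) {  # k: merge row; returns (string, height)
    parts <- character(2); hts <- numeric(2)
    for (j in 1:2) {
      ch <- hc$merge[k, j]
      if (ch < 0) {
        parts[j] <- labs[-ch]; hts[j] <- 0
      } else {
        sub <- node(ch)
        parts[j] <- sub$str; hts[j] <- sub$height
      }
    }
    h <- hc$height[k] / 2  # ultrametric depth of this node's leaves
    str <- sprintf("(%s:%s,%s:%s)", parts[1], fmt(h - hts[1]),
                   parts[2], fmt(h - hts[2]))
    list(str = str, height = h)
  }
  paste0(node(nrow(hc$merge))$str, ";")
}
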
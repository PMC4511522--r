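#' Z / p transforms used by the sign-preserving BH adjustment
#'
#' `z_to_p()` maps a signed Z statistic to its two-sided standard-normal
#' p-value, `p = 2(1 - Phi(|z|))`.  `p_to_adjusted_z()` maps an adjusted
#' p-value back to a signed Z, `z = sign * Phi^-1(1 - p/2)`, clamped to
#' `[-z_cap, z_cap]`; `p = 1` maps to 0 and an underflowed `p = 0` to
#' `sign * z_cap`.  The two are exact inverses (up to the cap), which is what
#' makes thresholding adjusted Z values equivalent to BH thresholding
#' p-values.
#'
#' @param z finite signed Z statistic(s).
#' @param p_adj adjusted two-sided p-value(s) in `[0, 1]`.
#' @param sign sign(s) to restore (`-1`, `0`, `+1`); recycled.
#' @param z_cap cap on `|z|` (default 8).
#' @return numeric vector.
#' @examples
#' z_to_p(1.959964)           # ~0.05
#' p_to_adjusted_z(0.05, 1)   # ~1.96
#' @export
z_to_p <- function(z) {
  .assert(all(is.finite(z) | is.na(z)), "z must be finite (or NA for unmeasured)")
  2 * pnorm(-abs(z))
}

#' @rdname z_to_p
#' @export
p_to_adjusted_z <- function(p_adj, sign, z_cap = .Z_CAP_DEFAULT) {
  .assert(all(is.na(p_adj) | (p_adj >= 0 & p_adj <= 1)), "p_adj must lie in [0, 1]")
  z <- qnorm(1 - p_adj / 2)
  z[!is.na(p_adj) & p_adj == 0] <- z_cap  # underflow maps to the cap
  pmin(z, z_cap) * base::sign(sign)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up BH false-discovery-rate adjustment of a vector of two-sided
#' p-values (delegates to [stats::p.adjust()]); `NA` entries (unmeasured
#' cells) are passed through untouched and do not count toward the family
#' size.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.9))
#' @export
bh_adjust <- function(p) {
  .assert(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# fast scalar adapters used inside the bootstrap loop (no data-frame
# construction); semantics identical to the exported contrast functions
.z_linear_fast <- function(x, y, z_cap) {
  nx <- length(x); ny <- length(y)
  est <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) return(if (est == 0) 0 else sign(est) * z_cap)
  max(min(est / se, z_cap), -z_cap)
}

.z_mw_fast <- function(x, y, z_cap) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  est <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 - nx * ny / 2
  ties <- tabulate(match(r, unique(r)))
  v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(0)
  max(min(est / sqrt(v), z_cap), -z_cap)
}

.z_mixed_fast <- function(x, y, bx, by, z_cap) {
  blocks <- c(bx, by)
  if (length(unique(blocks)) < 2L) return(.z_linear_fast(x, y, z_cap))
  fit <- .reml_block_contrast(c(x, y), rep(c(1, 0), c(length(x), length(y))), blocks)
  if (is.null(fit) || fit$se == 0) return(0)
  max(min(fit$estimate / fit$se, z_cap), -z_cap)
}

#' Bootstrap-commensurated Z score for one comparison
#'
#' The commensuration step: the mutant and reference condition cells are each
#' resampled with replacement to a common size `n_boot` (default 15), the
#' adapter's Z statistic is computed on every bootstrap data set, and the
#' arithmetic mean of the `B` bootstrap Z estimates is returned.  This puts
#' experiments with different native sample sizes on a common Z scale.
#'
#' @param x mutant-cell values; `y` reference-cell values.
#' @param adapter `"linear"`, `"mann_whitney"` or `"mixed"`; for `"mixed"`,
#'   `x_block`/`y_block` give the experiment-block label of every value and
#'   ride along with the resampled rows.
#' @param B number of bootstrap data sets (default 200).
#' @param n_boot common per-cell sample size (default 15).
#' @param seed RNG seed; identical `(data, B, seed)` give identical results.
#' @param x_block,y_block block labels, only used by the mixed adapter.
#' @param z_cap cap on `|z|`.
#' @return the mean bootstrap Z (scalar), or `NA` if either cell is empty
#'   (the unmeasured-cell marker).
#' @examples
#' bootstrap_z(rnorm(8, 1), rnorm(20), B = 50, seed = 3)
#' @export
bootstrap_z <- function(x, y, adapter = c("linear", "mann_whitney", "mixed"),
                        B = 200, n_boot = 15, seed = 1,
                        x_block = NULL, y_block = NULL, z_cap = .Z_CAP_DEFAULT) {
  adapter <- match.arg(adapter)
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  .assert(B >= 1 && n_boot >= 2, "need B >= 1 bootstrap sets of size n_boot >= 2")
  nx <- length(x); ny <- length(y)
  with_seed(seed, {
    if (adapter == "linear") {
      # vectorized over all B bootstrap sets at once
      xm <- matrix(x[sample.int(nx, n_boot * B, replace = TRUE)], n_boot, B)
      ym <- matrix(y[sample.int(ny, n_boot * B, replace = TRUE)], n_boot, B)
      mx <- colMeans(xm); my <- colMeans(ym)
      vx <- (colMeans(xm * xm) - mx^2) * n_boot / (n_boot - 1)
      vy <- (colMeans(ym * ym) - my^2) * n_boot / (n_boot - 1)
      est <- mx - my
      se <- sqrt((vx + vy) / n_boot)
      zb <- ifelse(se == 0, ifelse(est == 0, 0, sign(est) * z_cap),
                   pmin(pmax(est / se, -z_cap), z_cap))
      mean(zb)
    } else {
      zb <- numeric(B)
      for (b in seq_len(B)) {
        ix <- sample.int(nx, n_boot, replace = TRUE)
        iy <- sample.int(ny, n_boot, replace = TRUE)
        zb[b] <- if (adapter == "mann_whitney") {
          .z_mw_fast(x[ix], y[iy], z_cap)
        } else {
          .z_mixed_fast(x[ix], y[iy], x_block[ix], y_block[iy], z_cap)
        }
      }
      mean(zb)
    }
  })
}

.tier_levels <- c("ns", "fdr10", "fdr5", "fdr1")

.assign_tiers <- function(z_adj, cuts) {
  # cuts = c(fdr10, fdr5, fdr1) strictly increasing |z| cutpoints
  tier <- matrix(.tier_levels[1L], nrow(z_adj), ncol(z_adj),
                 dimnames = dimnames(z_adj))
  a <- abs(z_adj)
  tier[!is.na(a) & a > cuts[[1]]] <- "fdr10"
  tier[!is.na(a) & a > cuts[[2]]] <- "fdr5"
  tier[!is.na(a) & a > cuts[[3]]] <- "fdr1"
  tier[is.na(a)] <- NA_character_
  tier
}

#' Sign-preserving BH adjustment of a Z matrix
#'
#' Transforms a lines-by-assays matrix of signed Z scores to two-sided
#' p-values, applies Benjamini-Hochberg step-up correction within each family
#' (by default one family per assay column, i.e. per experiment; optionally
#' one global family), and transforms the adjusted p-values back to signed
#' adjusted Z scores.  Adjusted Z magnitudes never exceed the raw ones, ranks
#' within a family are preserved, and unmeasured (`NA`) cells stay `NA`.
#' FDR tiers are assigned from `|z_adj|`: above `tier_cuts` thresholds
#' (defaults 1.67 / 2 / 2.6, the usual guideline values for FDR < 10%, 5%
#' and 1%).
#'
#' @param z numeric matrix of raw signed Z scores (NA = not measured).
#' @param family_scope `"per_experiment"` (BH within each assay column,
#'   default) or `"global"` (one family over the whole matrix).
#' @param tier_cuts strictly increasing named vector
#'   `c(fdr10 = , fdr5 = , fdr1 = )` of `|z_adj|` cutpoints.
#' @param z_cap cap on adjusted `|z|`; an adjusted p of exactly 0 maps to the
#'   cap.
#' @return an `adjusted_z` list with matrices `z_adj`, `p`, `p_adj`, `tier`
#'   and logical `mask` (TRUE = measured).
#' @export
adjust_z_matrix <- function(z, family_scope = c("per_experiment", "global"),
                            tier_cuts = c(fdr10 = 1.67, fdr5 = 2, fdr1 = 2.6),
                            z_cap = .Z_CAP_DEFAULT) {
  family_scope <- match.arg(family_scope)
  z <- as.matrix(z)
  .assert(length(tier_cuts) == 3L && !is.unsorted(tier_cuts, strictly = TRUE),
          "tier_cuts must be three strictly increasing |z| cutpoints")
  p <- matrix(z_to_p(z), nrow(z), dimnames = dimnames(z))
  p_adj <- p
  if (family_scope == "global") {
    p_adj[] <- bh_adjust(as.vector(p))
  } else {
    for (j in seq_len(ncol(p))) {
      if (all(is.na(p[, j]))) {
        message("skipping empty family (assay column ", j, ")")
        next
      }
      p_adj[, j] <- bh_adjust(p[, j])
    }
  }
  z_adj <- matrix(p_to_adjusted_z(p_adj, sign(z), z_cap = z_cap),
                  nrow(z), dimnames = dimnames(z))
  structure(list(z_adj = z_adj, p = p, p_adj = p_adj,
                 tier = .assign_tiers(z_adj, tier_cuts),
                 mask = !is.na(z), family_scope = family_scope,
                 tier_cuts = tier_cuts, z_cap = z_cap),
            class = "adjusted_z")
}

# adapter routing by assay family
.family_adapter <- function(family) {
  switch(family,
    endpoint_continuous = "linear", burst_total = "linear",
    germination_curve = "linear", ordinal_score = "mann_whitney",
    timecourse_continuous = "mixed",
    stop("unknown assay family: ", family, call. = FALSE))
}

# slice an assay's analysis cells: endpoint timepoint and first arm
.assay_slice <- function(table, a) {
  s <- table[table$assay_id == a$assay_id & table$arm == a$arms[[1]], , drop = FALSE]
  if (length(a$timepoints) > 0L) {
    s <- s[!is.na(s$timepoint) & s$timepoint == a$endpoint_timepoint, , drop = FALSE]
  }
  s
}

#' Harmonize a multi-assay screen into an adjusted Z matrix
#'
#' The main fit: for every mutant line and every assay, computes the
#' bootstrap-commensurated Z score of the line-versus-reference comparison
#' ([bootstrap_z()], with the adapter chosen by assay family: pooled linear
#' contrast for continuous endpoints, burst totals and germination-curve
#' endpoints; tie-corrected Mann-Whitney for ordinal scores; random-intercept
#' mixed model for time courses, analysed at the assay's designated endpoint
#' timepoint), then applies the sign-preserving BH adjustment in Z-space and
#' assigns FDR tiers ([adjust_z_matrix()]).
#'
#' @param table a `phenotype_table` (from [simulate_phenotypes()] or
#'   [read_phenotype_csv()]).
#' @param assays list of [assay_design()] objects; defaults to the designs
#'   stored on a simulated table.
#' @param reference wild-type genotype label (default from the table's
#'   configuration, else `"Col-0"`).
#' @param B bootstrap replicates per cell (default 200).
#' @param n_boot common bootstrap sample size (default 15).
#' @param seed global seed; fanned out to one substream per line-assay cell,
#'   so results are reproducible and insensitive to row order.
#' @param z_cap cap on `|z|` (default 8).
#' @inheritParams adjust_z_matrix
#' @return a `phenoz` object: list with matrices `z` (raw mean-bootstrap Z),
#'   `z_adj`, `p`, `p_adj`, `tier`, logical `mask`, the `allele_map`, assay
#'   designs and fit parameters.  Methods: `print`, `summary`, `coef`,
#'   `plot`.
#' @examples
#' tab <- simulate_phenotypes(sim_config(list(
#'   assay_design("a", "endpoint_continuous")), n_lines = 4, seed = 2))
#' fit <- harmonize_z(tab, B = 25, seed = 2)
#' coef(fit)
#' @export
harmonize_z <- function(table, assays = NULL, reference = NULL,
                        B = 200, n_boot = 15, seed = 1,
                        family_scope = c("per_experiment", "global"),
                        tier_cuts = c(fdr10 = 1.67, fdr5 = 2, fdr1 = 2.6),
                        z_cap = .Z_CAP_DEFAULT) {
  family_scope <- match.arg(family_scope)
  cfg <- attr(table, "config")
  if (is.null(assays)) assays <- cfg$assays
  .assert(!is.null(assays), "no assay designs: pass `assays` or use a simulated table")
  if (is.null(reference)) reference <- if (!is.null(cfg)) cfg$reference else "Col-0"
  .assert(reference %in% table$allele_id, "reference genotype absent from the table")
  lines <- setdiff(unique(table$allele_id), reference)
  ids <- vapply(assays, `[[`, character(1), "assay_id")
  z <- matrix(NA_real_, length(lines), length(ids), dimnames = list(lines, ids))
  for (a in assays) {
    s <- .assay_slice(table, a)
    adapter <- .family_adapter(a$family)
    ref_rows <- s$allele_id == reference
    y <- s$value[ref_rows]; y_block <- s$block_id[ref_rows]
    for (ln in lines) {
      rows <- s$allele_id == ln
      if (!any(rows)) next  # not measured
      z[ln, a$assay_id] <- bootstrap_z(
        s$value[rows], y, adapter = adapter, B = B, n_boot = n_boot,
        seed = substream_seed(seed, paste0("boot/", a$assay_id, "/", ln)),
        x_block = s$block_id[rows], y_block = y_block, z_cap = z_cap)
    }
  }
  adj <- adjust_z_matrix(z, family_scope = family_scope,
                         tier_cuts = tier_cuts, z_cap = z_cap)
  allele_map <- if (!is.null(cfg)) cfg$allele_map else {
    gmap <- table$genotype[match(lines, table$allele_id)]
    setNames(gmap, lines)
  }
  structure(list(z = z, z_adj = adj$z_adj, p = adj$p, p_adj = adj$p_adj,
                 tier = adj$tier, mask = adj$mask, allele_map = allele_map,
                 assays = assays, reference = reference,
                 params = list(B = B, n_boot = n_boot, seed = seed,
                               z_cap = z_cap, family_scope = family_scope,
                               tier_cuts = tier_cuts),
                 call = match.call()),
            class = "phenoz")
}

#' Average allele-level values to gene level
#'
#' Collapses multiple independent insertion alleles of the same gene by the
#' arithmetic mean of their (adjusted) Z values per assay, ignoring
#' unmeasured cells; single-allele genes pass through unchanged.
#'
#' @param x a `phenoz` fit or a lines-by-assays numeric matrix.
#' @param allele_map named vector line -> gene (taken from the fit when `x`
#'   is a `phenoz`).
#' @param what for a `phenoz` fit, `"adjusted"` (default, the quantity shown
#'   in integrated heatmaps) or `"raw"` for a sensitivity analysis on
#'   unadjusted Z.
#' @return a genes-by-assays numeric matrix.
#' @export
average_alleles <- function(x, allele_map = NULL, what = c("adjusted", "raw")) {
  what <- match.arg(what)
  if (inherits(x, "phenoz")) {
    if (is.null(allele_map)) allele_map <- x$allele_map
    x <- if (what == "adjusted") x$z_adj else x$z
  }
  .assert(!is.null(allele_map) && all(rownames(x) %in% names(allele_map)),
          "allele_map must cover every row of the matrix")
  genes <- unique(unname(allele_map[rownames(x)]))
  out <- matrix(NA_real_, length(genes), ncol(x), dimnames = list(genes, colnames(x)))
  for (g in genes) {
    rows <- rownames(x)[allele_map[rownames(x)] == g]
    vals <- x[rows, , drop = FALSE]
    m <- colMeans(vals, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[g, ] <- m
  }
  out
}
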
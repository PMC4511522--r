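#' @section Contrast results:
#' Every adapter returns a one-row `contrast_result` data frame with columns
#' `genotype`, `assay_id`, `timepoint`, `estimate`, `se`, `z`, `p_two_sided`,
#' `df_note` and `note`.  The p-value is always the two-sided standard-normal
#' tail of the (capped) z, so `p_two_sided = 2 * (1 - pnorm(|z|))` holds to
#' machine precision and thresholding in Z-space is exactly equivalent to
#' thresholding p.
#' @name contrast-adapters
NULL

# default cap on |z|: avoids infinities from separation / p underflow
.Z_CAP_DEFAULT <- 8

.contrast_result <- function(estimate, se, z, note = "",
                             genotype = NA_character_, assay_id = NA_character_,
                             timepoint = NA_real_) {
  out <- data.frame(
    genotype = genotype, assay_id = assay_id, timepoint = timepoint,
    estimate = estimate, se = se, z = z,
    p_two_sided = 2 * pnorm(-abs(z)),
    df_note = "normal-approximated", note = note,
    stringsAsFactors = FALSE
  )
  class(out) <- c("contrast_result", class(out))
  out
}

#' Two-sample mean contrast as a signed Z statistic
#'
#' Ordinary pooled-variance two-sample contrast of a mutant group against the
#' wild-type reference, with the statistic referred to the standard normal
#' rather than a t distribution: the downstream harmonization treats every
#' assay's statistic as a Z score, and the bootstrap commensuration absorbs
#' small-sample conservatism.
#'
#' Degenerate data are flagged rather than erroring: if both groups are the
#' same constant, `z = 0` with `note = "degenerate: zero variance"`; if the
#' groups are perfectly separated constants, `z = sign(diff) * z_cap` with
#' `note = "separation"`.
#'
#' @param x numeric sample for the comparison genotype (>= 2 values).
#' @param y numeric sample for the reference genotype (>= 2 values).
#' @param z_cap cap on `|z|` (default 8).
#' @param ... metadata (`genotype`, `assay_id`, `timepoint`) stored on the
#'   result.
#' @return a one-row `contrast_result` data frame; `estimate` is
#'   `mean(x) - mean(y)` in assay units.
#' @examples
#' z_linear_contrast(rnorm(15, 1), rnorm(15, 0))
#' @export
z_linear_contrast <- function(x, y, z_cap = .Z_CAP_DEFAULT, ...) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: each group needs at least 2 observations", call. = FALSE)
  }
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  nx <- length(x); ny <- length(y)
  est <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    if (est == 0) return(.contrast_result(0, 0, 0, note = "degenerate: zero variance", ...))
    return(.contrast_result(est, 0, sign(est) * z_cap, note = "separation", ...))
  }
  z <- est / se
  z <- max(min(z, z_cap), -z_cap)
  .contrast_result(est, se, z, ...)
}

#' Mann-Whitney rank-sum contrast as a signed Z statistic
#'
#' Mann-Whitney U computed from midranks with the tie-corrected normal
#' approximation and no continuity correction, so `z` and `p` remain exactly
#' invertible through the standard normal.  `z > 0` means `x` is
#' stochastically larger than `y`.  Used for ordinal 0-3 disease-severity
#' scores, where ties are the norm.
#'
#' @param x,y numeric (or ordinal-coded) nonempty samples.
#' @inheritParams z_linear_contrast
#' @return one-row `contrast_result`; `estimate` is `U - n1*n2/2` (centred U)
#'   and `se` its tie-corrected null standard deviation, so `z = estimate/se`.
#' @examples
#' z_mann_whitney(c(1, 2, 3), c(4, 5, 6))  # z ~ -1.964
#' @export
z_mann_whitney <- function(x, y, z_cap = .Z_CAP_DEFAULT, ...) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("insufficient data: both samples must be nonempty", call. = FALSE)
  }
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  est <- u - nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) {
    return(.contrast_result(0, 0, 0, note = "degenerate: all values tied", ...))
  }
  se <- sqrt(v)
  z <- max(min(est / se, z_cap), -z_cap)
  .contrast_result(est, se, z, ...)
}

# Profiled-REML fit of y = b0 + b1*g + block intercept + error.
# The block-variance ratio lambda = sigma_b^2 / sigma_e^2 is profiled on a
# fixed log-spaced grid; for each lambda the GLS solution has a closed form in
# per-block sufficient statistics (Woodbury identity on I + lambda*J), so the
# whole profile costs O(grid * blocks) scalar operations.  Returns the
# genotype contrast and its standard error at the REML-optimal lambda.
.reml_block_contrast <- function(y, g, block,
                                 lambda_grid = c(0, 10^seq(-3, 3, length.out = 31))) {
  n <- length(y)
  bl <- match(block, unique(block))
  nb <- max(bl)
  nj <- tabulate(bl, nb)
  sgj <- as.numeric(rowsum(g, bl, reorder = FALSE))  # per-block sum of indicator
  tyj <- as.numeric(rowsum(y, bl, reorder = FALSE))  # per-block sum of response
  sg <- sum(g)
  sxy1 <- sum(y); sxy2 <- sum(g * y); syy <- sum(y * y)
  # Woodbury weights for every grid point at once: W[g, j] = lam_g/(1+lam_g*n_j)
  lnj <- outer(lambda_grid, nj)
  W <- lnj / (nj * (1 + lnj))
  W[, nj == 0] <- 0
  S <- W %*% cbind(nj * nj, nj * sgj, sgj * sgj, nj * tyj, sgj * tyj, tyj * tyj)
  a11 <- n - S[, 1]; a12 <- sg - S[, 2]; a22 <- sg - S[, 3]
  c1 <- sxy1 - S[, 4]; c2 <- sxy2 - S[, 5]; yy <- syy - S[, 6]
  det_a <- a11 * a22 - a12 * a12
  b2 <- (a11 * c2 - a12 * c1) / det_a     # genotype effect per grid point
  b1 <- (c1 - a12 * b2) / a11
  rss <- pmax(yy - (c1 * b1 + c2 * b2), .Machine$double.eps)
  crit <- rep(Inf, length(lambda_grid))
  ok <- is.finite(det_a) & det_a > 0 & is.finite(rss)
  crit[ok] <- rowSums(log1p(lnj))[ok] + log(det_a[ok]) + (n - 2) * log(rss[ok])
  if (all(!is.finite(crit))) return(NULL)
  i <- which.min(crit)
  sigma2 <- rss[i] / (n - 2)
  list(crit = crit[i], estimate = b2[i],
       se = sqrt(sigma2 * a11[i] / det_a[i]), lambda = lambda_grid[i])
}

#' Timecourse genotype contrast from a random-intercept mixed model
#'
#' Compares a genotype to the wild-type reference at a single timepoint of a
#' multi-experiment time course, using a linear mixed model with a random
#' intercept per experiment block (time courses are analysed one timepoint at
#' a time so every timepoint has power comparable to an endpoint assay).  The
#' block-variance ratio is estimated by profiling the restricted likelihood on
#' a fixed log-spaced grid, which is deterministic and exact for a single
#' random intercept; `z = estimate/se` is referred to the standard normal.
#'
#' With a single experiment block there is nothing to profile and the fit
#' degrades gracefully to [z_linear_contrast()] with a warning.
#'
#' @param value numeric response at the timepoint.
#' @param genotype factor/character with exactly two levels present,
#'   including `reference`.
#' @param block experiment-replicate identifier, parallel to `value`.
#' @param reference reference genotype label (default `"Col-0"`).
#' @inheritParams z_linear_contrast
#' @return one-row `contrast_result`; `estimate` is the genotype-minus-
#'   reference contrast in assay units.
#' @export
z_mixed_timecourse <- function(value, genotype, block, reference = "Col-0",
                               z_cap = .Z_CAP_DEFAULT, ...) {
  .assert(all(is.finite(value)), "values must be finite")
  genotype <- as.character(genotype)
  levs <- unique(genotype)
  .assert(reference %in% levs, sprintf("reference genotype '%s' absent from slice", reference))
  .assert(length(levs) == 2L, "slice must contain exactly the reference and one genotype")
  g <- as.numeric(genotype != reference)
  if (sum(g) < 2 || sum(1 - g) < 2) {
    stop("insufficient data: each genotype needs at least 2 observations", call. = FALSE)
  }
  blocks <- unique(block)
  if (length(blocks) < 2L) {
    warning("single experiment block: falling back to the unblocked linear contrast")
    return(z_linear_contrast(value[g == 1], value[g == 0], z_cap = z_cap, ...))
  }
  fit <- .reml_block_contrast(value, g, block)
  if (is.null(fit) || fit$se == 0) {
    return(.contrast_result(0, 0, 0, note = "degenerate: no residual variation", ...))
  }
  z <- max(min(fit$estimate / fit$se, z_cap), -z_cap)
  .contrast_result(fit$estimate, fit$se, z, ...)
}

#' Single-step max-|Z| family-wise adjustment
#'
#' Adjusts a family of correlated Z statistics for multiple comparisons with
#' the single-step max-|Z| method (the multivariate-normal analogue of
#' Dunnett/Tukey adjustments used for figure star annotations):
#' `p_adj[i] = P(max_j |Z_j| >= |z_i|)` under a joint standard normal with the
#' supplied correlation matrix, evaluated by Monte Carlo with a fixed seed.
#'
#' @param z numeric vector of observed Z statistics (one per contrast).
#' @param correlation contrast correlation matrix (positive semidefinite);
#'   defaults to the identity (independent contrasts).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed fixed RNG seed for the draws (default 1); the caller's RNG
#'   state is untouched.
#' @return a `family_adjustment` list with elements `z`, `p_raw`,
#'   `p_adjusted` (elementwise `>= p_raw`, in `[0, 1]`) and `correlation`.
#' @examples
#' single_step_adjust(c(2.1, -0.3, 1.4))$p_adjusted
#' @export
single_step_adjust <- function(z, correlation = NULL, n_mc = 1e5, seed = 1) {
  if (inherits(z, "data.frame")) z <- z$z
  k <- length(z)
  .assert(k >= 1L && all(is.finite(z)), "z must be a nonempty finite vector")
  if (is.null(correlation)) correlation <- diag(k)
  correlation <- as.matrix(correlation)
  .assert(nrow(correlation) == k && ncol(correlation) == k,
          "correlation must be k x k for k contrasts")
  .assert(max(abs(correlation - t(correlation))) < 1e-8, "correlation must be symmetric")
  ev <- eigen((correlation + t(correlation)) / 2, symmetric = TRUE)
  .assert(min(ev$values) > -1e-8 * max(abs(ev$values), 1),
          "correlation matrix is not positive semidefinite")
  p_raw <- 2 * pnorm(-abs(z))
  if (k == 1L) {
    p_adj <- p_raw  # a family of one needs no adjustment
  } else {
    fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
    maxabs <- with_seed(seed, {
      draws <- matrix(rnorm(n_mc * k), n_mc, k) %*% t(fac)
      do.call(pmax, lapply(seq_len(k), function(j) abs(draws[, j])))
    })
    p_adj <- vapply(abs(z), function(a) mean(maxabs >= a), numeric(1))
    p_adj <- pmin(pmax(p_adj, p_raw), 1)  # single-step never de-adjusts
  }
  structure(list(z = z, p_raw = p_raw, p_adjusted = p_adj,
                 correlation = correlation, n_mc = n_mc, seed = seed),
            class = "family_adjustment")
}
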
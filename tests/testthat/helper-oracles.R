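# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results from first principles (naive O(n^3) agglomeration,
# exhaustive rank enumeration) and never call the package's own code paths.

# Naive Ward agglomeration from cluster centroids: merge cost
# |A||B|/(|A|+|B|) * ||c_A - c_B||^2, reported height sqrt(2 * cost)
# (the Euclidean-input Ward convention).  Returns merge heights and the full
# cophenetic matrix, which pins both topology and heights.
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  height <- numeric(n - 1)
  coph <- matrix(0, n, n)
  cost <- function(A, B) {
    cA <- colMeans(x[A, , drop = FALSE]); cB <- colMeans(x[B, , drop = FALSE])
    length(A) * length(B) / (length(A) + length(B)) * sum((cA - cB)^2)
  }
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(active) - 1)) for (j in (i + 1):length(active)) {
      cc <- cost(clusters[[active[i]]], clusters[[active[j]]])
      if (is.null(best) || cc < best$c - 1e-12) best <- list(c = cc, i = i, j = j)
    }
    ai <- active[best$i]; aj <- active[best$j]
    h <- sqrt(2 * best$c)
    for (a in clusters[[ai]]) for (b in clusters[[aj]]) coph[a, b] <- coph[b, a] <- h
    height[step] <- h
    clusters[[ai]] <- c(clusters[[ai]], clusters[[aj]])
    active <- active[-best$j]
  }
  list(height = height, coph = coph)
}

# Naive complete-linkage agglomeration on an arbitrary distance matrix.
complete_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  height <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(active) - 1)) for (j in (i + 1):length(active)) {
      cc <- max(d[clusters[[active[i]]], clusters[[active[j]]]])
      if (is.null(best) || cc < best$c - 1e-12) best <- list(c = cc, i = i, j = j)
    }
    ai <- active[best$i]; aj <- active[best$j]
    for (a in clusters[[ai]]) for (b in clusters[[aj]]) coph[a, b] <- coph[b, a] <- best$c
    height[step] <- best$c
    clusters[[ai]] <- c(clusters[[ai]], clusters[[aj]])
    active <- active[-best$j]
  }
  list(height = height, coph = coph)
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank assignments
# (choose(n1+n2, n1) splits): P(|U - n1*n2/2| >= |u_obs - n1*n2/2|).
mw_exact_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, function(idx) sum(seq_len(n)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Exact two-sided p from the null U distribution (tie-free), for sweeping
# all group sizes without combinatorial blow-up.
mw_exact_p <- function(u, n1, n2) {
  uu <- 0:(n1 * n2)
  mu <- n1 * n2 / 2
  sum(stats::dwilcox(uu[abs(uu - mu) >= abs(u - mu)], n1, n2))
}

# Small six-assay screen covering every measurement family; used by the
# calibration and recovery suites.
six_assay_config <- function(n_lines, seed, effect_matrix = NULL) {
  sim_config(list(
    assay_design("e1", "endpoint_continuous"),
    assay_design("e2", "endpoint_continuous", noise_sd = 2),
    assay_design("tc", "timecourse_continuous"),
    assay_design("os", "ordinal_score"),
    assay_design("gc", "germination_curve"),
    assay_design("bt", "burst_total", noise_sd = 20)),
    n_lines = n_lines, seed = seed, effect_matrix = effect_matrix)
}
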
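test_that("Ward/Euclidean clustering honours obvious geometry", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5), d = c(9, 1))
  hc <- cluster_ward_euclidean(x)
  expect_equal(hc$height[1], 0)                      # identical rows merge first
  expect_setequal(hc$merge[1, ], c(-1, -2))
  line <- cbind(c(0, 1, 10))
  hc2 <- cluster_ward_euclidean(line)
  expect_setequal(hc2$merge[1, ], c(-1, -2))         # {0,1} join before 10
  expect_error(cluster_ward_euclidean(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("Ward/Euclidean heights match the brute-force oracle", {
  set.seed(83)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 8, 5)
    hc <- cluster_ward_euclidean(x)
    o <- ward_oracle(x)
    expect_equal(sort(hc$height), sort(o$height), tolerance = 1e-8)
    expect_equal(unname(as.matrix(stats::cophenetic(hc))), o$coph, tolerance = 1e-8)
  }
})

test_that("complete/1-Pearson clustering matches the brute-force oracle", {
  set.seed(89)
  for (i in 1:5) {
    x <- matrix(rnorm(48), 8, 6)
    hc <- cluster_complete_pearson(x)
    d <- 1 - cor(t(x))
    o <- complete_oracle(as.dist(d))
    expect_equal(sort(hc$height), sort(o$height), tolerance = 1e-8)
    expect_equal(unname(as.matrix(stats::cophenetic(hc))), o$coph, tolerance = 1e-8)
  }
})

test_that("Pearson distance is invariant to affine rescaling and maximal for anti-correlation", {
  set.seed(97)
  x <- rnorm(6)
  m <- rbind(a = x, b = 2 * x + 3, c = x + rnorm(6, 0, 2))
  hc <- cluster_complete_pearson(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)   # perfectly correlated pair
  expect_setequal(hc$merge[1, ], c(-1, -2))
  m2 <- rbind(a = x, b = -x, c = x + rnorm(6, 0, 0.6))
  hc2 <- cluster_complete_pearson(m2)
  expect_equal(max(hc2$height), 2, tolerance = 1e-12)  # x vs -x merges last at d = 2
  expect_error(cluster_complete_pearson(rbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance row.*a")
  thin <- rbind(a = c(1, 2, NA, NA, NA), b = c(NA, NA, 1, 2, 3), c = rnorm(5))
  expect_error(cluster_complete_pearson(thin), "overlapping")
})

test_that("clusterings are invariant to row permutation up to relabelling", {
  set.seed(103)
  x <- matrix(rnorm(35), 7, 5, dimnames = list(letters[1:7], NULL))
  perm <- sample(7)
  for (f in list(cluster_ward_euclidean, cluster_complete_pearson)) {
    h1 <- f(x); h2 <- f(x[perm, ])
    expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-10)
    c1 <- as.matrix(stats::cophenetic(h1)); c2 <- as.matrix(stats::cophenetic(h2))
    expect_equal(c1[letters[1:7], letters[1:7]], c2[letters[1:7], letters[1:7]],
                 tolerance = 1e-10)
  }
})

test_that("missing cells follow the stated policy in both recipes", {
  x <- matrix(rnorm(24), 4, 6, dimnames = list(letters[1:4], NULL))
  x[2, 3] <- NA
  x0 <- x; x0[is.na(x0)] <- 0
  expect_equal(cluster_ward_euclidean(x)$height,
               hclust(dist(x0), "ward.D2")$height)    # NA treated as neutral 0
  expect_silent(cluster_complete_pearson(x))          # pairwise-complete columns
})

test_that("Newick export writes ultrametric half-height branches and quotes labels", {
  x <- rbind("line one" = c(0, 0), "line:two" = c(3, 4))
  hc <- cluster_ward_euclidean(x)
  nwk <- export_newick(hc)
  h <- hc$height[1]
  expect_match(nwk, sprintf("'line one':%s", format(h / 2, digits = 8)), fixed = TRUE)
  expect_match(nwk, "'line:two'", fixed = TRUE)
  expect_match(nwk, ";$")
})

test_that("Newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  set.seed(107)
  x <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("ln", 1:6), NULL))
  hc <- cluster_ward_euclidean(x)
  tr <- ape::read.tree(text = export_newick(hc))
  expect_setequal(tr$tip.label, rownames(x))
  # leaf depths equal half the root merge height (ultrametric convention)
  depths <- ape::node.depth.edgelength(tr)[seq_len(6)]
  expect_equal(unname(depths), rep(max(hc$height) / 2, 6), tolerance = 1e-6)
  # export -> parse -> export is idempotent
  hc_cmp <- ape::as.phylo(hc)
  expect_equal(suppressWarnings(as.numeric(ape::dist.topo(tr, hc_cmp))), 0,
               tolerance = 1e-9)
})

test_that("planted two-block phenotype structure is recovered at ARI >= 0.9", {
  # 16 lines in two blocks; within-block effect correlation 0.9, across 0
  aris <- numeric(50)
  for (s in 1:50) {
    set.seed(4000 + s)
    n_per <- 8; n_assay <- 8
    template <- matrix(rnorm(2 * n_assay, 0, 2), 2, n_assay)
    z <- rbind(
      t(replicate(n_per, sqrt(0.9) * template[1, ] + sqrt(0.1) * rnorm(n_assay))),
      t(replicate(n_per, sqrt(0.9) * template[2, ] + sqrt(0.1) * rnorm(n_assay))))
    rownames(z) <- paste0("l", 1:(2 * n_per))
    cl <- stats::cutree(cluster_complete_pearson(z), k = 2)
    aris[s] <- phenoz:::adjusted_rand_index(cl, rep(1:2, each = n_per))
  }
  expect_gte(mean(aris), 0.9)
})

test_that("the internal adjusted Rand index matches mclust", {
  skip_if_not_installed("mclust")
  set.seed(109)
  for (i in 1:10) {
    a <- sample(1:3, 40, TRUE); b <- sample(1:4, 40, TRUE)
    expect_equal(phenoz:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
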
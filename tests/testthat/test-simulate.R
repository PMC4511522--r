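test_that("identical configurations give byte-identical tables", {
  cfg <- six_assay_config(n_lines = 4, seed = 11)
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))
})

test_that("adding an assay leaves other assays' draws untouched", {
  a1 <- assay_design("alpha", "endpoint_continuous")
  a2 <- assay_design("beta", "burst_total")
  t1 <- simulate_phenotypes(sim_config(list(a1), n_lines = 3, seed = 5))
  t2 <- simulate_phenotypes(sim_config(list(a1, a2), n_lines = 3, seed = 5))
  keep <- t2$assay_id == "alpha"
  expect_equal(t2$value[keep], t1$value)
})

test_that("null configuration centres every cell at the baseline, tighter as n grows", {
  dev_for <- function(n) {
    cfg <- sim_config(list(assay_design("e", "endpoint_continuous", noise_sd = 1,
                                        n_blocks = 1, baseline = 10)),
                      n_lines = 3, block_sd = 0, n_per_cell = n, seed = 21)
    tab <- simulate_phenotypes(cfg)
    means <- tapply(tab$value, tab$allele_id, mean)
    max(abs(means - 10))
  }
  d_small <- dev_for(10)
  d_large <- dev_for(4000)
  expect_lt(d_small, 1.5)            # ~4.5 SE at n = 10
  expect_lt(d_large, d_small)        # deviation shrinks with replication
  expect_lt(d_large, 0.08)           # ~5 SE at n = 4000
})

test_that("family-specific value constraints hold", {
  cfg <- six_assay_config(n_lines = 5, seed = 31)
  tab <- simulate_phenotypes(cfg)
  ord <- tab$value[tab$assay_id == "os"]
  expect_true(all(ord %in% 0:3))
  germ <- tab[tab$assay_id == "gc", ]
  expect_true(all(germ$value >= 0 & germ$value <= 100))
  # monotone nondecreasing within each dish
  key <- interaction(germ$allele_id, germ$block_id, germ$replicate, drop = TRUE)
  mono <- vapply(split(germ[order(germ$timepoint), ], key[order(germ$timepoint)]),
                 function(d) !is.unsorted(d$value), logical(1))
  expect_true(all(mono))
})

test_that("unknown assay family is rejected at declaration time", {
  expect_error(assay_design("x", "fluorometric_magic"), "unknown assay family")
})

test_that("masking removes exactly the named cells and protects the reference", {
  cfg <- six_assay_config(n_lines = 4, seed = 41)
  tab <- simulate_phenotypes(cfg)
  expect_identical(mask_cells(tab, NULL), tab)
  expect_identical(nrow(mask_cells(tab, data.frame(allele_id = character(),
                                                   assay_id = character()))),
                   nrow(tab))
  line <- setdiff(unique(tab$allele_id), "Col-0")[1]
  n_cell <- sum(tab$allele_id == line & tab$assay_id == "e1")
  masked <- mask_cells(tab, data.frame(allele_id = line, assay_id = "e1"))
  expect_equal(nrow(masked), nrow(tab) - n_cell)
  expect_false(any(masked$allele_id == line & masked$assay_id == "e1"))
  expect_error(mask_cells(tab, data.frame(allele_id = "Col-0", assay_id = "e1")),
               "reference")
})

test_that("planted effect signs are recovered by the downstream raw Z", {
  # |effect| = 1.5 planted with both signs; over 100 seeds the sign of the
  # bootstrap-commensurated Z must match the planted sign in >= 90% of cells
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    em <- matrix(c(1.5, -1.5, 0), 3, 1,
                 dimnames = list(c("gene01", "gene02", "gene03"), "e"))
    cfg <- sim_config(list(assay_design("e", "endpoint_continuous")),
                      n_lines = 4, effect_matrix = em, seed = 1000 + s)
    fit <- harmonize_z(simulate_phenotypes(cfg), B = 20, seed = s)
    planted <- sign(em[cfg$allele_map[rownames(fit$z)], "e"])
    nonnull <- planted != 0
    hits <- hits + sum(sign(fit$z[nonnull, 1]) == planted[nonnull])
    total <- total + sum(nonnull)
  }
  expect_gte(hits / total, 0.90)
})

test_that("a strong planted effect dominates null lines' Z scores", {
  # +2 sigma on one gene: its line's Z should be positive and exceed every
  # null line's |Z| in >= 95% of seeds
  wins <- 0L
  for (s in 1:100) {
    genes <- sprintf("gene%02d", 1:6)
    em <- matrix(0, 6, 1, dimnames = list(genes, "e"))
    em["gene03", "e"] <- 2
    cfg <- sim_config(list(assay_design("e", "endpoint_continuous")),
                      n_lines = 7, effect_matrix = em, seed = 2000 + s)
    tab <- simulate_phenotypes(cfg)
    fit <- harmonize_z(tab, B = 20, seed = s)
    amap <- attr(tab, "config")$allele_map
    target <- rownames(fit$z)[amap[rownames(fit$z)] == "gene03"]
    others <- setdiff(rownames(fit$z), target)
    if (all(fit$z[target, 1] > 0) && min(fit$z[target, 1]) > max(abs(fit$z[others, 1]))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / 100, 0.95)
})

test_that("fully null pipeline Z scores are approximately standard normal", {
  # 500 null line-level Z values drawn from independent screens (lines within
  # one screen share the wild-type reference cell, so marginal calibration is
  # what a pooled Kolmogorov-Smirnov check can assess)
  # native condition size = bootstrap target (15): commensuration is neutral;
  # with larger native cells it deliberately deflates |Z| toward n = 15 power.
  # Many small screens keep the shared-reference correlation from dominating.
  z <- unlist(lapply(1:250, function(s) {
    cfg <- sim_config(list(assay_design("e", "endpoint_continuous", n_blocks = 1)),
                      n_lines = 2, seed = 700 + s)
    harmonize_z(simulate_phenotypes(cfg), B = 50, seed = s)$z[, 1]
  }))
  expect_length(z, 500)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})
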
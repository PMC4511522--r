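test_that("linear contrast matches the textbook pooled statistic", {
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(15, 1); y <- rnorm(15)
    res <- z_linear_contrast(x, y)
    tt <- t.test(x, y, var.equal = TRUE)     # independent route to the same statistic
    expect_equal(res$z, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$estimate, mean(x) - mean(y), tolerance = 1e-12)
    expect_equal(res$p_two_sided, 2 * (1 - pnorm(abs(res$z))), tolerance = 1e-10)
  }
})

test_that("degenerate linear contrasts are flagged, not errors", {
  same <- z_linear_contrast(rep(2, 4), rep(2, 5))
  expect_equal(same$z, 0)
  expect_match(same$note, "degenerate")
  sep <- z_linear_contrast(rep(1, 4), rep(0, 4))
  expect_equal(sep$z, 8)                     # capped separation
  expect_match(sep$note, "separation")
  expect_error(z_linear_contrast(1, c(1, 2)), "insufficient data")
})

test_that("all adapters negate z exactly under group relabelling", {
  set.seed(7)
  x <- rnorm(12, 0.5); y <- rnorm(10)
  expect_equal(z_linear_contrast(x, y)$z, -z_linear_contrast(y, x)$z, tolerance = 1e-12)
  xs <- sample(0:3, 20, TRUE); ys <- sample(0:3, 15, TRUE)
  expect_equal(z_mann_whitney(xs, ys)$z, -z_mann_whitney(ys, xs)$z, tolerance = 1e-12)
  bl <- rep(c("b1", "b2", "b3"), each = 10)
  v <- rnorm(30) + rep(c(0, 1, -1), each = 10)
  g <- rep(rep(c("Col-0", "mut"), 5), 3)
  fwd <- z_mixed_timecourse(v, g, bl, reference = "Col-0")
  rev <- z_mixed_timecourse(v, ifelse(g == "Col-0", "mut", "Col-0"), bl,
                            reference = "Col-0")
  expect_equal(fwd$z, -rev$z, tolerance = 1e-10)
})

test_that("Mann-Whitney statistic matches enumeration on the canonical example", {
  res <- z_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$estimate, 0 - 4.5)        # U = 0, centred
  expect_equal(res$z, -4.5 / sqrt(5.25), tolerance = 1e-10)
  expect_equal(mw_exact_enum(c(1, 2, 3), c(4, 5, 6)), 0.1)  # full 20-split enumeration
  expect_equal(z_mann_whitney(c(3, 1, 2), c(3, 1, 2))$z, 0)  # same multiset
})

test_that("Mann-Whitney tie handling agrees with the classical normal approximation", {
  set.seed(13)
  for (i in 1:10) {
    x <- sample(0:3, 18, TRUE); y <- sample(0:3, 14, TRUE)
    res <- z_mann_whitney(x, y)
    if (res$se == 0) next
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(res$p_two_sided, wt$p.value, tolerance = 1e-8)
  }
  expect_equal(z_mann_whitney(rep(2, 6), rep(2, 9))$z, 0)   # all tied
})

test_that("mixed-model contrast collapses to the linear contrast without block variance", {
  set.seed(19)
  v <- rnorm(60); g <- rep(c("Col-0", "mut"), each = 30)
  bl <- rep(rep(c("b1", "b2", "b3"), each = 10), 2)
  mixed <- z_mixed_timecourse(v + (g == "mut") * 0.8, g, bl)
  lin <- z_linear_contrast(v[g == "mut"] + 0.8, v[g == "Col-0"])
  expect_equal(mixed$estimate, lin$estimate, tolerance = 0.05 * abs(lin$estimate))
  expect_lt(abs(mixed$z - lin$z) / abs(lin$z), 0.05)
})

test_that("balanced additive block shifts cancel from the mixed estimate", {
  set.seed(23)
  v <- rnorm(60); g <- rep(rep(c("Col-0", "mut"), each = 10), 3)
  bl <- rep(c("b1", "b2", "b3"), each = 20)
  base <- z_mixed_timecourse(v, g, bl)
  for (c_ in c(1, 10, 250)) {
    shifted <- v + c_ * (as.integer(factor(bl)) - 2)
    expect_equal(z_mixed_timecourse(shifted, g, bl)$estimate, base$estimate,
                 tolerance = 1e-8)
  }
})

test_that("single-block slices degrade to the linear contrast with a warning", {
  set.seed(29)
  v <- rnorm(20); g <- rep(c("Col-0", "mut"), each = 10)
  expect_warning(res <- z_mixed_timecourse(v, g, rep("b1", 20)), "single experiment block")
  expect_equal(res$z, z_linear_contrast(v[g == "mut"], v[g == "Col-0"])$z)
})

test_that("profiled REML agrees with lme4 on a blocked dataset", {
  skip_if_not_installed("lme4")
  set.seed(37)
  bl <- rep(c("b1", "b2", "b3", "b4"), each = 12)
  g <- rep(rep(c("Col-0", "mut"), each = 6), 4)
  v <- rnorm(48) + (g == "mut") * 0.7 + rep(rnorm(4, 0, 0.8), each = 12)
  mine <- z_mixed_timecourse(v, g, bl)
  lm4 <- lme4::lmer(v ~ gg + (1 | bl), data = data.frame(v = v, gg = factor(g, c("Col-0", "mut")), bl = bl))
  est <- lme4::fixef(lm4)[["ggmut"]]
  se <- sqrt(as.matrix(vcov(lm4))[2, 2])
  expect_equal(mine$estimate, est, tolerance = 0.01 * abs(est))
  expect_equal(mine$se, se, tolerance = 0.05 * se)
})

test_that("mixed-model type-I error at |z| > 1.96 is near nominal", {
  set.seed(43)
  rejections <- 0L
  for (i in 1:200) {
    bl <- rep(c("b1", "b2", "b3"), each = 10)
    g <- rep(rep(c("Col-0", "mut"), each = 5), 3)
    v <- rnorm(30) + rep(rnorm(3, 0, 0.7), each = 10)  # null genotype effect
    if (abs(z_mixed_timecourse(v, g, bl)$z) > 1.96) rejections <- rejections + 1L
  }
  rate <- rejections / 200
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("single-step max-|Z| adjustment has the right limits", {
  one <- single_step_adjust(2.1)
  expect_equal(one$p_adjusted, one$p_raw)            # family of one
  # independence: Sidak closed form as oracle
  z <- c(2.2, -1.1, 0.4, 2.9, -0.6)
  adj <- single_step_adjust(z, diag(5), n_mc = 2e5, seed = 9)
  sidak <- 1 - (1 - adj$p_raw)^5
  expect_equal(adj$p_adjusted, sidak, tolerance = 0.01)
  # perfect correlation: adjustment vanishes
  ones <- matrix(1, 4, 4)
  adj1 <- single_step_adjust(c(1.5, -2.0, 0.3, 2.4), ones, n_mc = 2e5, seed = 9)
  expect_equal(adj1$p_adjusted, adj1$p_raw, tolerance = 0.01)
  expect_true(all(adj$p_adjusted >= adj$p_raw))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)                 # not PSD
  expect_error(single_step_adjust(c(1, 2), bad), "positive semidefinite")
})

test_that("single-step adjustment reproduces multcomp's Dunnett-style p-values", {
  skip_if_not_installed("multcomp")
  set.seed(47)
  d <- data.frame(g = factor(rep(c("Col-0", "m1", "m2", "m3"), each = 12),
                             levels = c("Col-0", "m1", "m2", "m3")),
                  y = rnorm(48) + rep(c(0, 0.9, 0, -0.7), each = 12))
  fit <- stats::lm(y ~ g, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  rho <- stats::cov2cor(vcov(gl))
  mine <- single_step_adjust(unname(ref$test$tstat), rho, n_mc = 2e5, seed = 3)
  expect_equal(mine$p_adjusted, unname(as.numeric(ref$test$pvalues)), tolerance = 0.02)
})
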
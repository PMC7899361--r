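test_that("pearson_matrix reproduces hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  m <- cbind(a = x, b = 2 * x, c = rev(x), d = c(1, 3, 2, 4))
  r <- pearson_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.8) # product-moment formula by hand
  expect_equal(r, t(r))
  expect_equal(attr(r, "n"), 4L)

  expect_error(pearson_matrix(cbind(a = x, k = rep(2, 4))), "k")
  expect_error(pearson_matrix(cbind(a = c(1, NA, 3, 4), b = x)), "impute")
  expect_error(pearson_matrix(cbind(a = 1:3, b = 3:1)), "4 samples")
})

test_that("fisher_z matches the closed form and is an odd function", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-grid), -fisher_z(grid))
  # degenerate +/-1 inputs are clamped, not infinite
  expect_true(all(is.finite(fisher_z(c(-1, 1)))))
  expect_error(fisher_z(NaN), "finite")
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
})

test_that("r_diff evaluates the weighted z-difference with its symmetries", {
  expect_equal(r_diff(0.4, 0.4, 50, 50), 0)
  expect_equal(r_diff(0.5, 0, 50, 50), sqrt(23.5) * atanh(0.5))
  expect_equal(r_diff(0.5, 0, 50, 50), 2.663, tolerance = 1e-3)
  # swapping compartments with equal n negates the statistic
  expect_equal(r_diff(0.3, 0.8, 40, 40), -r_diff(0.8, 0.3, 40, 40))
  expect_error(r_diff(0.5, 0, 3, 50), "n - 3")
  expect_equal(r_diff(0.5, 0.2, 30, 60, weighted = FALSE),
               atanh(0.5) - atanh(0.2))
})

test_that("r_diff with equal n equals the textbook two-correlation z-test", {
  withr::with_seed(42, {
    r1 <- runif(2000, -0.99, 0.99)
    r2 <- runif(2000, -0.99, 0.99)
    n <- sample(4:500, 2000, replace = TRUE)
  })
  ours <- r_diff(r1, r2, n, n)
  textbook <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n - 3) + 1 / (n - 3))
  expect_equal(ours, textbook, tolerance = 1e-12)
})

test_that("diffcorr_pairs enumerates every unordered pair once", {
  paired <- null_paired(n = 12, m = 3, seed = 5)
  dc <- diffcorr_pairs(paired)
  expect_equal(nrow(dc), 3L) # C(3, 2)
  expect_s3_class(dc, "diffcorr_tbl")
  expect_setequal(pair_key(dc$metabolite_i, dc$metabolite_j),
                  c("M1|M2", "M1|M3", "M2|M3"))

  paired10 <- null_paired(n = 12, m = 10, seed = 6)
  dc10 <- diffcorr_pairs(paired10)
  expect_equal(nrow(dc10), choose(10, 2))
  expect_false(any(duplicated(pair_key(dc10$metabolite_i, dc10$metabolite_j))))
  # sign consistency with the weighted z-difference
  expect_equal(sign(dc10$r_diff),
               sign(sqrt(9 / 2) * dc10$z_plasma - sqrt(9 / 2) * dc10$z_jf))

  # self-comparison: identical compartments give r_diff exactly 0
  xp <- as.matrix(null_paired(n = 15, m = 4, seed = 7)$plasma[, -1])
  self <- diffcorr_pairs(make_paired(xp, xp))
  expect_equal(self$r_diff, rep(0, 6))
  expect_equal(self$r_plasma, self$r_jf)
})

test_that("zero-variance metabolites are dropped with a warning", {
  xp <- cbind(a = rexp(10), b = rexp(10), flat = rep(1, 10))
  xj <- cbind(a = rexp(10), b = rexp(10), flat = rexp(10))
  expect_warning(dc <- diffcorr_pairs(make_paired(xp, xj)), "flat")
  expect_equal(nrow(dc), 1L)
  expect_setequal(c(dc$metabolite_i, dc$metabolite_j), c("a", "b"))
})

test_that("permutation p-values honour the add-one floor and ceiling", {
  # observed statistic of 0: every permutation ties or exceeds, p = 1
  xp <- as.matrix(null_paired(n = 15, m = 4, seed = 8)$plasma[, -1])
  self <- permute_diffcorr(make_paired(xp, xp), B = 50, seed = 1)
  expect_equal(self$p_perm, rep(1, 6))

  # a constructed overwhelming effect: no permutation can reach it, p = 1/(B+1)
  withr::with_seed(9, {
    base <- rnorm(50)
    xp <- cbind(a = exp(base), b = exp(base + rnorm(50, sd = 0.05)))
    xj <- cbind(a = exp(base), b = exp(-base + rnorm(50, sd = 0.05)))
  })
  strong <- permute_diffcorr(make_paired(xp, xj), B = 1000, seed = 2)
  expect_equal(strong$p_perm, 1 / 1001)

  rand <- permute_diffcorr(null_paired(n = 10, m = 5, seed = 10), B = 19, seed = 3)
  expect_true(all(rand$p_perm >= 1 / 20 & rand$p_perm <= 1))
  expect_error(permute_diffcorr(null_paired(), B = 0), "positive integer")
})

test_that("permutation p-values are seed-stable in distribution", {
  paired <- null_paired(n = 30, m = 8, seed = 11)
  p1 <- permute_diffcorr(paired, B = 2000, seed = 100)$p_perm
  p2 <- permute_diffcorr(paired, B = 2000, seed = 200)$p_perm
  # two seeds agree to within Monte-Carlo error at B = 2000
  expect_lt(max(abs(p1 - p2)), 0.08)
  # and the same seed reproduces the p-values exactly
  p1b <- permute_diffcorr(paired, B = 2000, seed = 100)$p_perm
  expect_identical(p1, p1b)
})

test_that("paired permutation scheme swaps within subjects and validates pairing", {
  paired <- null_paired(n = 20, m = 5, seed = 12)
  res <- permute_diffcorr(paired, B = 99, scheme = "paired", seed = 4)
  expect_true(all(res$p_perm >= 1 / 100 & res$p_perm <= 1))

  broken <- paired
  broken$subjects_jf[1] <- "stranger"
  expect_error(permute_diffcorr(broken, B = 9, scheme = "paired", seed = 1),
               "stranger")
})

test_that("null r_diff values are approximately standard normal", {
  # independent metabolites, same distribution in both compartments
  co <- generate_cohort(synthetic_spec(
    seed = 21, n_subjects = 100,
    panel = c(glycerophospholipid = 101L),
    backbone_r = 0, n_differential = 0L,
    low_detection_metabolites = 0L, lod_missing_rate = 0
  ))
  conc <- co$concentrations[
    co$concentrations$sample_id %in% co$design$sample_id[co$design$stratum == "female"], ]
  dc <- diffcorr_pairs(assemble_paired(conc, co$design, "female"))
  expect_equal(nrow(dc), 5050L)
  ks <- unname(stats::ks.test(dc$r_diff, "pnorm")$statistic)
  expect_lt(ks, 0.05)
})

test_that("significance adjustment applies Bonferroni and BH correctly", {
  paired <- null_paired(n = 20, m = 11, seed = 13) # 55 pairs
  dc <- permute_diffcorr(paired, B = 1000, seed = 5)
  # floor 1/1001 ~ 1e-3 exceeds 0.05/55 ~ 9.1e-4: the tool must warn
  expect_warning(adj <- adjust_significance(dc, alpha = 0.05, method = "bonferroni"),
                 "floor")
  expect_equal(attr(adj, "diffcorr_meta")$adjusted_threshold, 0.05 / 55)
  expect_identical(adj$sig_nominal, adj$p_perm < 0.05)
  expect_identical(adj$sig_adjusted, adj$p_perm < 0.05 / 55)
  # adjusted significance implies nominal significance
  expect_true(all(!adj$sig_adjusted | adj$sig_nominal))

  bh <- adjust_significance(dc, alpha = 0.05, method = "bh")
  expect_identical(bh$sig_adjusted, p.adjust(dc$p_perm, "BH") <= 0.05)
  none <- adjust_significance(dc, alpha = 0.05, method = "none")
  expect_identical(none$sig_adjusted, none$sig_nominal)
  expect_error(adjust_significance(dc, method = "hochberg"), "one of")

  # a single pair needs no correction: threshold equals alpha
  one <- permute_diffcorr(null_paired(n = 10, m = 2, seed = 14), B = 100, seed = 6)
  one_adj <- adjust_significance(one, alpha = 0.05, method = "bonferroni")
  expect_equal(attr(one_adj, "diffcorr_meta")$adjusted_threshold, 0.05)
})

test_that("diffcorr tables round-trip through their delimited format", {
  paired <- null_paired(n = 15, m = 4, seed = 15)
  dc <- adjust_significance(permute_diffcorr(paired, B = 200, seed = 7),
                            method = "bh")
  f <- tempfile(fileext = ".tsv")
  write_diffcorr(dc, f)
  back <- read_diffcorr(f)
  expect_equal(tidy(back), tidy(dc))
  meta <- attr(back, "diffcorr_meta")
  expect_equal(meta$B, 200)
  expect_equal(meta$n_plasma, 15)
  expect_equal(meta$alpha, 0.05)
  expect_equal(meta$correction, "bh")
})
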
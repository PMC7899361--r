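test_that("the default panel matches the targeted assay composition", {
  spec <- synthetic_spec()
  expect_equal(sum(spec$panel), 186L)
  expect_equal(length(spec$metabolites), 186L)
  tally <- table(spec$classes$class)
  expect_equal(as.integer(tally[names(spec$panel)]),
               as.integer(unname(spec$panel)))
  expect_equal(length(spec$low_detection_ids), 19L)
  expect_equal(nrow(spec$differential_pairs), 10L)
  expect_true(all(abs(c(spec$differential_pairs$r_plasma,
                        spec$differential_pairs$r_jf)) < 1))
})

test_that("cohort generation is bit-reproducible and leaves the global RNG alone", {
  spec <- synthetic_spec(seed = 42, n_subjects = 8,
                         panel = c(`amino acid` = 5L, sphingolipid = 3L),
                         n_differential = 2L,
                         low_detection_metabolites = 1L)
  set.seed(1); before <- rnorm(1)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$concentrations, co2$concentrations)
  expect_identical(co1$design, co2$design)
  expect_identical(co1$truth, co2$truth)
  set.seed(1); expect_identical(rnorm(1), before)

  co3 <- generate_cohort(synthetic_spec(seed = 43, n_subjects = 8,
                                        panel = c(`amino acid` = 5L, sphingolipid = 3L),
                                        n_differential = 2L,
                                        low_detection_metabolites = 1L))
  expect_false(identical(co1$concentrations, co3$concentrations))
})

test_that("the cohort design has one sample per subject per compartment", {
  co <- generate_cohort(synthetic_spec(seed = 3, n_subjects = 12,
                                       panel = c(`amino acid` = 4L),
                                       backbone_r = 0.3,
                                       n_differential = 0L,
                                       low_detection_metabolites = 0L))
  d <- validate_cohort_design(co$design)
  expect_equal(nrow(d), 12L * 2L * 2L) # two strata, two compartments
  expect_setequal(unique(d$stratum), c("female", "male"))
  counts <- table(d$stratum, d$compartment)
  expect_true(all(counts == 12L))
  expect_true(all(co$design$age > 20 & co$design$age < 110))
  expect_true(all(co$design$bmi > 10 & co$design$bmi < 70))
  # every design row has concentrations and vice versa
  expect_setequal(d$sample_id, co$concentrations$sample_id)
})

test_that("nearest_psd clips negative eigenvalues and preserves PSD inputs", {
  psd <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(unclass(nearest_psd(psd)), psd, ignore_attr = TRUE)
  expect_equal(attr(nearest_psd(psd), "distance"), 0)

  # off-diagonal 1.2: eigenvalues (2.2, -0.2); clipping and rescaling gives
  # the unit matrix of all ones
  over <- matrix(c(1, 1.2, 1.2, 1), 2)
  fixed <- nearest_psd(over)
  expect_equal(unclass(fixed), matrix(c(1, 1, 1, 1), 2), ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_equal(unclass(nearest_psd(diag(3))), diag(3), ignore_attr = TRUE)
  expect_error(nearest_psd(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")

  withr::with_seed(5, {
    raw <- matrix(runif(49, -0.9, 0.9), 7)
    raw <- (raw + t(raw)) / 2
    diag(raw) <- 1
  })
  proj <- nearest_psd(raw)
  expect_gte(min(eigen(proj, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_equal(unname(diag(proj)), rep(1, 7))
})

test_that("planted low-detection metabolites fail the 80% filter (186 -> 167)", {
  co <- generate_cohort(synthetic_spec(seed = 7))
  female <- co$concentrations[
    co$concentrations$sample_id %in% co$design$sample_id[co$design$stratum == "female"], ]
  kept <- filter_by_detection(female, 0.8)
  expect_equal(ncol(kept) - 1L, 167L)
  expect_length(intersect(names(kept), co$truth$low_detection_ids), 0L)
  # planted differential pairs always survive the filter
  expect_true(all(c(co$truth$differential_pairs$metabolite_i,
                    co$truth$differential_pairs$metabolite_j) %in% names(kept)))
})

test_that("realized missingness tracks the censoring rate", {
  co <- generate_cohort(synthetic_spec(
    seed = 8, n_subjects = 500,
    panel = c(glycerophospholipid = 6L, `amino acid` = 6L),
    n_differential = 0L, low_detection_metabolites = 2L,
    lod_missing_rate = 0.07, low_detection_missing_rate = 0.35
  ))
  frac_missing <- 1 - detection_fraction(co$concentrations)$fraction_detected
  names(frac_missing) <- detection_fraction(co$concentrations)$metabolite
  low <- names(frac_missing) %in% co$truth$low_detection_ids
  expect_true(all(abs(frac_missing[!low] - 0.07) <= 0.02))
  expect_true(all(abs(frac_missing[low] - 0.35) <= 0.02))
  # censoring is left-tail: observed values exceed the imputation floor
  m1 <- setdiff(names(co$concentrations), "sample_id")[1]
  x <- co$concentrations[[m1]]
  expect_true(min(x, na.rm = TRUE) > 0)
})

test_that("latent correlations of generated data converge to their targets", {
  spec <- synthetic_spec(
    seed = 9, n_subjects = 2000,
    panel = c(glycerophospholipid = 4L, `amino acid` = 2L),
    backbone_r = 0.5, n_differential = 2L,
    low_detection_metabolites = 0L, lod_missing_rate = 0
  )
  co <- generate_cohort(spec)
  # both strata share each compartment's latent correlation matrix, so they
  # pool into one 4000-sample estimate per compartment
  for (compartment in c("plasma", "JF")) {
    ids <- co$design$sample_id[co$design$compartment == compartment]
    x <- log(as.matrix(co$concentrations[
      match(ids, co$concentrations$sample_id), spec$metabolites]))
    emp <- cor(x)
    tgt <- dcmnet:::compartment_sigma(spec, compartment)
    expect_lt(max(abs(emp - tgt)), 0.05)
  }
  # the two compartment targets differ exactly at the planted pairs
  dp <- spec$differential_pairs
  dsig <- abs(dcmnet:::compartment_sigma(spec, "plasma") -
                dcmnet:::compartment_sigma(spec, "JF"))
  planted <- pair_key(dp$metabolite_i, dp$metabolite_j)
  for (i in seq_len(nrow(dsig))) {
    for (j in seq_len(ncol(dsig))) {
      if (i >= j) next
      key <- pair_key(rownames(dsig)[i], colnames(dsig)[j])
      if (key %in% planted) {
        expect_equal(dsig[i, j], 0.6, tolerance = 1e-8)
      } else {
        expect_lt(dsig[i, j], 1e-8)
      }
    }
  }
})

test_that("written cohorts feed the file readers unchanged", {
  co <- generate_cohort(synthetic_spec(seed = 10, n_subjects = 6,
                                       panel = c(`amino acid` = 4L, hexose = 1L),
                                       n_differential = 1L,
                                       low_detection_metabolites = 0L))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  conc <- read_concentration_table(file.path(d, "concentrations.csv"))
  expect_equal(as.data.frame(conc), as.data.frame(co$concentrations),
               tolerance = 1e-12)
  design <- read_cohort_design(file.path(d, "design.csv"))
  expect_equal(design$sample_id, co$design$sample_id)
  classes <- read_metabolite_classes(file.path(d, "classes.csv"))
  expect_equal(classes, co$classes)
})
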
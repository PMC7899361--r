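#' Specification for a synthetic paired two-compartment cohort
#'
#' Describes a study in which every subject contributes one plasma and one
#' joint-fluid (JF) sample measured on a targeted metabolomics panel. The
#' defaults emulate a 100-subject knee-osteoarthritis cohort profiled on a
#' 186-metabolite p180-style panel: 50 subjects per sex stratum, panel
#' composition 90 glycerophospholipids / 40 acylcarnitines / 21 amino acids /
#' 19 biogenic amines / 15 sphingolipids / 1 hexose, a shared positive
#' within-class correlation backbone, a small set of planted differentially
#' correlated pairs, mild below-LOD censoring, and 19 low-detection
#' metabolites that an 80% detection filter removes (leaving 167).
#'
#' Correlation targets are set on the latent Gaussian (log-concentration)
#' scale; concentrations are lognormal, so observed-scale Pearson
#' correlations are mildly attenuated.
#'
#' @param n_subjects Subjects per stratum (each gives one sample per
#'   compartment).
#' @param panel Named integer vector: panel class -> metabolite count.
#' @param backbone_r Baseline latent correlation between metabolites of the
#'   same panel class (between-class baseline is 0).
#' @param differential_pairs Either `NULL` (plant `n_differential` pairs
#'   automatically) or a tibble with columns `metabolite_i`, `metabolite_j`,
#'   `r_plasma`, `r_jf` of latent correlation targets.
#' @param n_differential Number of auto-planted differential pairs (between
#'   metabolites of different classes, avoiding low-detection metabolites).
#' @param r_plasma_target,r_jf_target Latent correlations of auto-planted
#'   pairs in each compartment (defaults 0.7 vs 0.1, a differential of 0.6).
#' @param lod_missing_rate Below-LOD censoring rate for ordinary metabolites.
#' @param low_detection_metabolites Number of metabolites planted with
#'   `low_detection_missing_rate` missingness so they fail the detection
#'   filter.
#' @param low_detection_missing_rate Missing fraction of those metabolites.
#' @param log_sigma Standard deviation of log-concentrations.
#' @param seed Integer seed; the generator never touches the global RNG.
#' @return A `synthetic_spec` list, with resolved `metabolites`, `classes`,
#'   `differential_pairs` and `low_detection_ids`.
#' @export
synthetic_spec <- function(n_subjects = 50L,
                           panel = c(glycerophospholipid = 90L,
                                     acylcarnitine = 40L,
                                     `amino acid` = 21L,
                                     `biogenic amine` = 19L,
                                     sphingolipid = 15L,
                                     hexose = 1L),
                           backbone_r = 0.5,
                           differential_pairs = NULL,
                           n_differential = 10L,
                           r_plasma_target = 0.7,
                           r_jf_target = 0.1,
                           lod_missing_rate = 0.05,
                           low_detection_metabolites = 19L,
                           low_detection_missing_rate = 0.4,
                           log_sigma = 0.5,
                           seed = 1L) {
  if (n_subjects < 4L) abort("Need at least 4 subjects per stratum (n - 3 > 0).")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    abort("`panel` must be a named class -> count vector.")
  }
  if (any(panel < 0) || sum(panel) < 2L) abort("`panel` must hold >= 2 metabolites.")
  if (abs(backbone_r) >= 1) abort("`backbone_r` must lie in (-1, 1).")
  if (low_detection_metabolites > sum(panel)) {
    abort("More low-detection metabolites than panel members.")
  }
  prefix <- c(glycerophospholipid = "PC", acylcarnitine = "AC",
              `amino acid` = "AA", `biogenic amine` = "BA",
              sphingolipid = "SM", hexose = "H")
  ids <- character(0)
  cls <- character(0)
  for (k in names(panel)) {
    pk <- if (k %in% names(prefix)) prefix[[k]] else toupper(substr(gsub("[^A-Za-z]", "", k), 1, 2))
    ids <- c(ids, sprintf("%s_%03d", pk, seq_len(panel[[k]])))
    cls <- c(cls, rep(k, panel[[k]]))
  }
  if (anyDuplicated(ids)) abort("Panel classes produce clashing metabolite id prefixes.")
  classes <- tibble::tibble(metabolite = ids, class = cls)

  low_ids <- withr::with_seed(seed, {
    if (low_detection_metabolites > 0L) {
      sort(sample(ids, low_detection_metabolites))
    } else character(0)
  })

  if (is.null(differential_pairs)) {
    differential_pairs <- withr::with_seed(seed + 1L, {
      auto_plant_pairs(classes, low_ids, n_differential,
                       r_plasma_target, r_jf_target)
    })
  } else {
    differential_pairs <- tibble::as_tibble(differential_pairs)
    need <- c("metabolite_i", "metabolite_j", "r_plasma", "r_jf")
    if (!all(need %in% names(differential_pairs))) {
      abort(paste0("`differential_pairs` needs columns: ", toString(need)))
    }
    unknown <- setdiff(c(differential_pairs$metabolite_i,
                         differential_pairs$metabolite_j), ids)
    if (length(unknown)) abort(paste0("Unknown metabolites in differential_pairs: ", toString(unknown)))
    if (any(abs(c(differential_pairs$r_plasma, differential_pairs$r_jf)) >= 1)) {
      abort("Target correlations must lie in (-1, 1).")
    }
  }

  structure(list(
    n_subjects = as.integer(n_subjects), panel = panel,
    metabolites = ids, classes = classes,
    backbone_r = backbone_r,
    differential_pairs = differential_pairs,
    lod_missing_rate = lod_missing_rate,
    low_detection_ids = low_ids,
    low_detection_missing_rate = low_detection_missing_rate,
    log_sigma = log_sigma,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

auto_plant_pairs <- function(classes, low_ids, n_pairs,
                             r_plasma_target, r_jf_target) {
  if (n_pairs == 0L) {
    return(tibble::tibble(metabolite_i = character(0), metabolite_j = character(0),
                          r_plasma = numeric(0), r_jf = numeric(0)))
  }
  eligible <- classes[!classes$metabolite %in% low_ids, ]
  if (length(unique(eligible$class)) < 2L) {
    abort("Auto-planting needs >= 2 panel classes with eligible metabolites.")
  }
  used <- character(0)
  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    pool <- eligible[!eligible$metabolite %in% used, ]
    a <- pool[sample.int(nrow(pool), 1L), ]
    pool_b <- pool[pool$class != a$class, ]
    if (nrow(pool_b) == 0L) abort("Ran out of cross-class metabolites to plant pairs.")
    b <- pool_b[sample.int(nrow(pool_b), 1L), ]
    ij <- sort(c(a$metabolite, b$metabolite))
    pairs[[p]] <- tibble::tibble(metabolite_i = ij[1], metabolite_j = ij[2],
                                 r_plasma = r_plasma_target, r_jf = r_jf_target)
    used <- c(used, ij)
  }
  dplyr::bind_rows(pairs)
}

#' Nearest positive semi-definite correlation matrix
#'
#' Projects a symmetric matrix onto the positive semi-definite cone by
#' clipping negative eigenvalues at zero, then rescales to unit diagonal;
#' the two steps are repeated until the smallest eigenvalue is
#' non-negative (up to numerical tolerance). A PSD correlation matrix passes
#' through unchanged.
#'
#' @param mat A symmetric matrix.
#' @return The projected correlation matrix, with attribute `"distance"`
#'   holding the largest absolute elementwise change.
#' @export
nearest_psd <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) ||
      max(abs(mat - t(mat))) > 1e-8) {
    abort("`mat` must be a symmetric square matrix.")
  }
  out <- (mat + t(mat)) / 2
  for (iter in 1:10) {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= -1e-10) break
    vals <- pmax(e$values, 0)
    out <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(pmax(diag(out), .Machine$double.eps))
    out <- out / tcrossprod(d)
    out <- (out + t(out)) / 2
    diag(out) <- 1
  }
  attr(out, "distance") <- max(abs(out - mat))
  out
}

# Latent correlation matrix for one compartment. Metabolites involved in a
# planted differential pair are decoupled from the class backbone (in both
# compartments alike) and form their own 2x2 block, so the pair targets are
# exactly realizable and the matrix stays PSD without distorting them; the
# two compartment matrices differ only at the planted entries.
compartment_sigma <- function(spec, compartment) {
  m <- length(spec$metabolites)
  sig <- matrix(0, m, m, dimnames = list(spec$metabolites, spec$metabolites))
  for (k in unique(spec$classes$class)) {
    members <- which(spec$classes$class == k)
    sig[members, members] <- spec$backbone_r
  }
  dp <- spec$differential_pairs
  if (nrow(dp)) {
    planted <- match(unique(c(dp$metabolite_i, dp$metabolite_j)), spec$metabolites)
    sig[planted, ] <- 0
    sig[, planted] <- 0
    tgt <- if (compartment == "plasma") dp$r_plasma else dp$r_jf
    i <- match(dp$metabolite_i, spec$metabolites)
    j <- match(dp$metabolite_j, spec$metabolites)
    sig[cbind(i, j)] <- tgt
    sig[cbind(j, i)] <- tgt
  }
  diag(sig) <- 1
  out <- nearest_psd(sig)
  if (attr(out, "distance") > 0.1) {
    abort("Target correlation structure is far from positive semi-definite; use milder targets.")
  }
  out
}

#' Generate a synthetic paired plasma/JF metabolomics cohort
#'
#' Draws, for each stratum (female and male) and compartment, latent
#' multivariate normal vectors whose correlation matrices share the
#' within-class backbone and differ exactly at the planted differential
#' pairs; exponentiates them to lognormal concentrations; and censors the
#' lowest values of each metabolite as below-LOD missing (ordinary
#' metabolites at `lod_missing_rate`, planted low-detection metabolites at
#' `low_detection_missing_rate`). Subject age and BMI are drawn to match a
#' typical advanced-osteoarthritis arthroplasty cohort (age about 65 +/- 8
#' years, BMI about 32 +/- 6 kg/m2, per-sex means differing slightly).
#'
#' The same seed always reproduces the same cohort bit-for-bit, and the
#' global RNG state is never read or modified.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `dcm_cohort`: `concentrations` (tibble,
#'   `sample_id` + one column per metabolite, `NA` = below LOD), `design`
#'   (cohort design tibble), `classes` (metabolite class map), and `truth`
#'   (list with the planted `differential_pairs` and `low_detection_ids`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must come from synthetic_spec().")
  m <- length(spec$metabolites)
  sigma <- list(plasma = compartment_sigma(spec, "plasma"),
                JF = compartment_sigma(spec, "JF"))
  chol_u <- lapply(sigma, chol)
  n <- spec$n_subjects
  demo <- list(
    female = list(prefix = "F", age = c(65.6, 7.1), bmi = c(33.4, 6.3)),
    male = list(prefix = "M", age = c(64.4, 8.1), bmi = c(31.7, 5.3))
  )
  rate <- ifelse(spec$metabolites %in% spec$low_detection_ids,
                 spec$low_detection_missing_rate, spec$lod_missing_rate)

  withr::with_seed(spec$seed + 2L, {
    mu <- runif(m, log(0.1), log(100))
    conc_blocks <- list()
    design_blocks <- list()
    for (stratum in names(demo)) {
      d <- demo[[stratum]]
      subjects <- sprintf("%s%02d", d$prefix, seq_len(n))
      age <- round(rnorm(n, d$age[1], d$age[2]), 1)
      bmi <- round(rnorm(n, d$bmi[1], d$bmi[2]), 1)
      for (compartment in c("plasma", "JF")) {
        z <- matrix(rnorm(n * m), n, m) %*% chol_u[[compartment]]
        conc <- exp(sweep(spec$log_sigma * z, 2L, mu, `+`))
        # empirical-rank censoring: the lowest round(n * rate) values of each
        # metabolite in this block fall below the LOD
        for (j in seq_len(m)) {
          k <- round(n * rate[j])
          if (k > 0L) conc[order(conc[, j])[seq_len(k)], j] <- NA_real_
        }
        sid <- paste0(subjects, "_", if (compartment == "plasma") "P" else "J")
        colnames(conc) <- spec$metabolites
        conc_blocks[[paste(stratum, compartment)]] <-
          tibble::tibble(sample_id = sid, !!!as.data.frame(conc))
        design_blocks[[paste(stratum, compartment)]] <- tibble::tibble(
          sample_id = sid, subject_id = subjects, compartment = compartment,
          stratum = stratum, age = age, bmi = bmi
        )
      }
    }
  })
  structure(list(
    concentrations = dplyr::bind_rows(conc_blocks),
    design = dplyr::bind_rows(design_blocks),
    classes = spec$classes,
    truth = list(differential_pairs = spec$differential_pairs,
                 low_detection_ids = spec$low_detection_ids),
    spec = spec
  ), class = "dcm_cohort")
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes `concentrations.csv`, `design.csv` and `classes.csv` under `dir`,
#' exactly the files [read_concentration_table()], [read_cohort_design()] and
#' [read_metabolite_classes()] read, so integration tests can exercise the
#' full file-based pipeline.
#'
#' @param cohort A `dcm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "dcm_cohort")) abort("`cohort` must come from generate_cohort().")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$concentrations, file.path(dir, "concentrations.csv"),
                   na = "NA", progress = FALSE)
  readr::write_csv(cohort$design, file.path(dir, "design.csv"), progress = FALSE)
  readr::write_csv(cohort$classes, file.path(dir, "classes.csv"), progress = FALSE)
  invisible(dir)
}
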
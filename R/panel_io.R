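#' Read a wide-format metabolite concentration table
#'
#' Reads a delimited text file (CSV or TSV, autodetected from the extension)
#' whose first column holds sample identifiers and whose remaining columns are
#' metabolite concentrations, as exported from targeted assays such as the
#' Biocrates AbsoluteIDQ p180 panel. Cells matching one of `missing_tokens`
#' become explicit `NA` (below-detection) values.
#'
#' @param path Path to the delimited file. Files ending in `.tsv` or `.txt`
#'   are read as tab-separated, anything else as comma-separated.
#' @param missing_tokens Character vector of cell values to treat as missing
#'   (below the limit of detection). The empty string and `"NA"` are the
#'   defaults; add `"<LOD"` or similar vendor markers as needed.
#' @param zero_as_missing If `TRUE`, exact zeros are mapped to missing, for
#'   assays that encode below-LOD measurements as 0. Default `FALSE`: zeros
#'   are valid measurements.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per metabolite; missing measurements are `NA`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,Ala,Gly", "s1,1.2,0.4", "s2,NA,0.5"), f)
#' read_concentration_table(f)
read_concentration_table <- function(path,
                                     missing_tokens = c("", "NA"),
                                     zero_as_missing = FALSE) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) {
    abort("Concentration file needs a sample id column plus >= 1 metabolite.")
  }
  names(raw)[1] <- "sample_id"
  mets <- names(raw)[-1]
  dup_m <- unique(mets[duplicated(mets)])
  if (length(dup_m)) {
    abort(paste0("Duplicate metabolite ids in header: ", toString(dup_m)))
  }
  parsed <- purrr::imap(raw[mets], function(col, name) {
    col <- as.character(col)
    col[col %in% missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric value '%s' at row %d, column '%s' (not in missing_tokens).",
        col[bad[1]], bad[1], name
      ))
    }
    if (zero_as_missing) num[!is.na(num) & num == 0] <- NA_real_
    num
  })
  out <- tibble::tibble(sample_id = as.character(raw$sample_id), !!!parsed)
  assert_conc_tbl(out)
  out
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE,
                    name_repair = "minimal")
}

#' Read a sample metadata (cohort design) table
#'
#' The design file binds each sample to its subject, compartment and stratum.
#' Required columns: `sample_id`, `subject_id`, `compartment` (values
#' `plasma` or `JF`, case-insensitive; `SF` is accepted as a synonym for
#' joint/synovial fluid), `stratum`. Optional: `age` (years), `bmi` (kg/m2).
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble, one row per sample, with `compartment` normalised to
#'   `"plasma"`/`"JF"`.
#' @export
read_cohort_design <- function(path) {
  raw <- read_delim_auto(path)
  validate_cohort_design(raw)
}

#' Validate a cohort design table
#'
#' Checks the invariants every downstream step relies on: one metadata row per
#' sample, recognised compartment labels, and at most one sample per subject
#' per compartment.
#'
#' @param design A data frame with at least `sample_id`, `subject_id`,
#'   `compartment`, `stratum`.
#' @return The validated design as a tibble (invisibly usable in pipes).
#' @export
validate_cohort_design <- function(design) {
  need <- c("sample_id", "subject_id", "compartment", "stratum")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    abort(paste0("Design is missing columns: ", toString(miss)))
  }
  design <- tibble::as_tibble(design)
  design$sample_id <- as.character(design$sample_id)
  design$subject_id <- as.character(design$subject_id)
  design$stratum <- as.character(design$stratum)
  dup <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup)) {
    abort(paste0("Duplicate sample ids in design: ", toString(dup)))
  }
  comp <- tolower(as.character(design$compartment))
  comp[comp %in% c("jf", "sf", "joint fluid", "synovial fluid")] <- "JF"
  comp[comp == "plasma"] <- "plasma"
  bad <- unique(design$compartment[!comp %in% c("plasma", "JF")])
  if (length(bad)) {
    abort(paste0("Unknown compartment labels: ", toString(bad),
                 " (expected plasma/JF)."))
  }
  design$compartment <- comp
  multi <- design |>
    dplyr::count(.data$subject_id, .data$compartment) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(paste0(
      "Subjects with more than one sample in a compartment: ",
      toString(paste0(multi$subject_id, "/", multi$compartment))
    ))
  }
  if ("age" %in% names(design)) design$age <- as.numeric(design$age)
  if ("bmi" %in% names(design)) design$bmi <- as.numeric(design$bmi)
  design
}

#' Read a metabolite class annotation file
#'
#' Two-column delimited file mapping each metabolite id to its panel class
#' (glycerophospholipid, acylcarnitine, amino acid, biogenic amine,
#' sphingolipid, hexose, or other).
#'
#' @param path Path to a CSV/TSV file with columns `metabolite`, `class`.
#' @return A tibble with columns `metabolite` and `class`.
#' @export
read_metabolite_classes <- function(path) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) abort("Class file needs columns metabolite, class.")
  names(raw)[1:2] <- c("metabolite", "class")
  tibble::tibble(metabolite = as.character(raw$metabolite),
                 class = as.character(raw$class))
}

#' Per-metabolite detection fraction
#'
#' Fraction of samples in which each metabolite was measured (non-missing),
#' across all rows of `data`.
#'
#' @param data A concentration tibble (`sample_id` plus metabolite columns).
#' @return A tibble with columns `metabolite` and `fraction_detected`.
#' @export
detection_fraction <- function(data) {
  assert_conc_tbl(data)
  mets <- metabolite_cols(data)
  tibble::tibble(
    metabolite = mets,
    fraction_detected = vapply(data[mets], function(x) mean(!is.na(x)),
                               numeric(1), USE.NAMES = FALSE)
  )
}

#' Filter metabolites by detection rate
#'
#' Retains the metabolites measured (non-missing) in strictly more than
#' `min_fraction` of the samples — the conventional "more than 80% of the
#' total samples" panel filter. The sample set and metabolite order are
#' unchanged.
#'
#' @param data A concentration tibble.
#' @param min_fraction Detection threshold in (0, 1]; a metabolite is kept iff
#'   its detected fraction is `> min_fraction` (strict). Default 0.8.
#' @return The filtered concentration tibble.
#' @export
filter_by_detection <- function(data, min_fraction = 0.8) {
  assert_conc_tbl(data)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be a single number in (0, 1].")
  }
  frac <- detection_fraction(data)
  keep <- frac$metabolite[frac$fraction_detected > min_fraction]
  if (length(keep) == 0L) {
    abort(sprintf(
      "No metabolite is detected in more than %.0f%% of samples; lower `min_fraction`.",
      100 * min_fraction
    ))
  }
  data[c("sample_id", keep)]
}

#' Half-minimum imputation of below-detection values
#'
#' Replaces each missing measurement of a metabolite with half the minimum
#' observed value of that metabolite — the standard surrogate for
#' below-limit-of-detection dropout in targeted metabolomics. Observed values
#' are never changed.
#'
#' @param data A concentration tibble; every metabolite must have at least one
#'   observed value (run [filter_by_detection()] first).
#' @return The completed concentration tibble, with no missing values.
#' @export
impute_half_min <- function(data) {
  assert_conc_tbl(data)
  mets <- metabolite_cols(data)
  all_na <- mets[vapply(data[mets], function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    abort(paste0(
      "Metabolites with no observed value (apply the detection filter first): ",
      toString(all_na)
    ))
  }
  data[mets] <- purrr::map(data[mets], function(x) {
    x[is.na(x)] <- min(x, na.rm = TRUE) / 2
    x
  })
  data
}

#' Assemble a paired plasma/joint-fluid dataset for one stratum
#'
#' Splits the samples of one stratum (e.g. one sex) by compartment and aligns
#' the two compartments on a common metabolite list, producing the unit of
#' analysis for differential correlation. Both compartments must have at
#' least 4 samples so the Fisher variance terms `n - 3` are positive.
#'
#' @param data A complete (filtered + imputed) concentration tibble covering
#'   the stratum's samples; rows not belonging to `stratum` are ignored.
#' @param design A cohort design table (see [read_cohort_design()]).
#' @param stratum The stratum label to extract, e.g. `"female"`.
#' @return A `paired_dataset`: a list with elements `stratum`, `plasma` and
#'   `jf` (concentration tibbles ordered by subject), `subjects_plasma`,
#'   `subjects_jf`, `n_plasma`, `n_jf` and `metabolites`.
#' @export
assemble_paired <- function(data, design, stratum) {
  assert_conc_tbl(data)
  design <- validate_cohort_design(design)
  if (!stratum %in% design$stratum) {
    abort(sprintf("Stratum '%s' not present in the design.", stratum))
  }
  orphan <- setdiff(data$sample_id, design$sample_id)
  if (length(orphan)) {
    abort(paste0("Samples without metadata: ", toString(orphan)))
  }
  sub <- design[design$stratum == stratum, ]
  sub <- sub[sub$sample_id %in% data$sample_id, ]
  mets <- metabolite_cols(data)
  if (anyNA(data[mets])) {
    abort("Concentrations still contain missing values; impute before pairing.")
  }
  take <- function(compartment) {
    s <- sub[sub$compartment == compartment, ]
    s <- s[order(s$subject_id), ]
    rows <- data[match(s$sample_id, data$sample_id), c("sample_id", mets)]
    list(tbl = rows, subjects = s$subject_id)
  }
  pl <- take("plasma")
  jf <- take("JF")
  for (side in list(c(nrow(pl$tbl), "plasma"), c(nrow(jf$tbl), "JF"))) {
    if (as.integer(side[1]) < 4L) {
      abort(sprintf(
        "Compartment %s of stratum '%s' has %s samples; >= 4 are required so the Fisher variance term n - 3 is positive.",
        side[2], stratum, side[1]
      ))
    }
  }
  structure(
    list(
      stratum = stratum,
      plasma = pl$tbl, jf = jf$tbl,
      subjects_plasma = pl$subjects, subjects_jf = jf$subjects,
      n_plasma = nrow(pl$tbl), n_jf = nrow(jf$tbl),
      metabolites = mets
    ),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "<paired_dataset> stratum '%s': %d plasma + %d JF samples, %d metabolites\n",
    x$stratum, x$n_plasma, x$n_jf, length(x$metabolites)
  ))
  invisible(x)
}
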
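# Fixture builders used across the suite. Everything is generated in code;
# no data files ship with the package.

# Paired dataset straight from two samples-by-metabolites matrices.
make_paired <- function(xp, xj, stratum = "female") {
  stopifnot(ncol(xp) == ncol(xj))
  mets <- colnames(xp) %||% paste0("M", seq_len(ncol(xp)))
  colnames(xp) <- colnames(xj) <- mets
  tbl <- function(x, prefix) {
    tibble::tibble(sample_id = sprintf("%s%03d", prefix, seq_len(nrow(x))),
                   as.data.frame(x))
  }
  structure(
    list(
      stratum = stratum,
      plasma = tbl(xp, "p"), jf = tbl(xj, "j"),
      subjects_plasma = sprintf("u%03d", seq_len(nrow(xp))),
      subjects_jf = sprintf("u%03d", seq_len(nrow(xj))),
      n_plasma = nrow(xp), n_jf = nrow(xj),
      metabolites = mets
    ),
    class = "paired_dataset"
  )
}

# Positive-valued paired data with no differential structure.
null_paired <- function(n = 20, m = 5, seed = 1) {
  withr::with_seed(seed, {
    make_paired(exp(matrix(rnorm(n * m), n, m)),
                exp(matrix(rnorm(n * m), n, m)))
  })
}

# A diffcorr_tbl with a prescribed significant edge set (for network tests).
fake_diffcorr <- function(edges, r_diff = NULL, p_perm = NULL, meta = list()) {
  df <- tibble::tibble(
    metabolite_i = edges[[1]],
    metabolite_j = edges[[2]],
    r_plasma = NA_real_, r_jf = NA_real_,
    z_plasma = NA_real_, z_jf = NA_real_,
    r_diff = r_diff %||% rep(1, nrow(edges)),
    p_perm = p_perm %||% rep(0.01, nrow(edges)),
    sig_nominal = TRUE,
    sig_adjusted = FALSE
  )
  attr(df, "diffcorr_meta") <- meta
  class(df) <- c("diffcorr_tbl", class(tibble::tibble()))
  df
}

# Canonical unordered-pair key for joining results against ground truth.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# Write a small concentration CSV and return its path.
write_conc_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

`%||%` <- rlang::`%||%`
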
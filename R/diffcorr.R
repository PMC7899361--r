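#' Pearson correlation matrix of a complete concentration table
#'
#' @param data A complete concentration tibble (no missing values, >= 4
#'   samples) or a numeric samples-by-metabolites matrix.
#' @return A symmetric correlation matrix with unit diagonal and a `"n"`
#'   attribute holding the sample count.
#' @export
pearson_matrix <- function(data) {
  m <- if (is.matrix(data)) data else {
    assert_conc_tbl(data)
    as_conc_matrix(data)
  }
  if (anyNA(m)) abort("Missing values present; impute before correlating.")
  if (nrow(m) < 4L) abort("At least 4 samples are required (n - 3 > 0).")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance metabolites: ",
                 toString(colnames(m)[sds == 0]),
                 ". Drop constant columns before correlating."))
  }
  r <- cor(m, method = "pearson")
  diag(r) <- 1
  attr(r, "n") <- nrow(m)
  r
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform under which a sample correlation is approximately normal with
#' variance `1/(n - 3)`. Coefficients at exactly +/-1 (degenerate fixtures)
#' are clamped to `+/-(1 - 1e-7)` so the transform stays finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return The z-transformed values.
#' @export
#' @examples
#' fisher_z(0.5) # log(3) / 2
fisher_z <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    abort("`r` must be finite numeric correlation(s).")
  }
  if (any(abs(r) > 1)) abort("Correlations must lie in [-1, 1].")
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

#' Differential correlation statistic between two compartments
#'
#' The weighted difference of Fisher z-transformed correlations,
#' `r_diff = sqrt((n_plasma - 3)/2) * z_plasma - sqrt((n_jf - 3)/2) * z_jf`,
#' i.e. the JF correlation is subtracted from the plasma one. With equal group
#' sizes this is exactly the textbook normal-deviate statistic
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` for the equality of two
#' independent correlations, so under no differential correlation it is
#' approximately standard normal.
#'
#' @param r_plasma,r_jf Pearson correlations of the pair in each compartment.
#' @param n_plasma,n_jf Sample counts per compartment; both must exceed 3.
#' @param weighted If `FALSE`, returns the raw z-difference `z_plasma - z_jf`
#'   without the sample-size weights (sensitivity analysis only).
#' @return The differential correlation statistic (vectorised over `r`).
#' @export
#' @examples
#' r_diff(0.5, 0, 50, 50) # sqrt(23.5) * atanh(0.5)
r_diff <- function(r_plasma, r_jf, n_plasma, n_jf, weighted = TRUE) {
  if (any(n_plasma <= 3) || any(n_jf <= 3)) {
    abort("Both sample counts must exceed 3: the variance term n - 3 must be positive.")
  }
  z1 <- fisher_z(r_plasma)
  z2 <- fisher_z(r_jf)
  if (!weighted) return(z1 - z2)
  sqrt((n_plasma - 3) / 2) * z1 - sqrt((n_jf - 3) / 2) * z2
}

# Unordered-pair index (i < j, row-ordered) for an m x m symmetric matrix.
pair_index <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

drop_zero_variance <- function(paired) {
  sds_p <- apply(as_conc_matrix(paired$plasma), 2L, stats::sd)
  sds_j <- apply(as_conc_matrix(paired$jf), 2L, stats::sd)
  dead <- paired$metabolites[sds_p == 0 | sds_j == 0]
  if (length(dead)) {
    warn(paste0("Dropping zero-variance metabolites: ", toString(dead)))
    keep <- c("sample_id", setdiff(paired$metabolites, dead))
    paired$plasma <- paired$plasma[keep]
    paired$jf <- paired$jf[keep]
    paired$metabolites <- setdiff(paired$metabolites, dead)
  }
  paired
}

new_diffcorr_tbl <- function(df, meta) {
  attr(df, "diffcorr_meta") <- meta
  class(df) <- c("diffcorr_tbl", class(tibble::tibble()))
  df
}

#' Differential correlation statistics for every metabolite pair
#'
#' Computes per-compartment Pearson correlations and the differential
#' correlation statistic [r_diff()] for all `m * (m - 1) / 2` unordered
#' metabolite pairs of a paired dataset. Metabolites with zero variance in
#' either compartment are dropped with a warning.
#'
#' @param paired A `paired_dataset` from [assemble_paired()] (complete data).
#' @param weighted Passed to [r_diff()].
#' @return A `diffcorr_tbl`: a tibble with one row per unordered pair and
#'   columns `metabolite_i`, `metabolite_j`, `r_plasma`, `r_jf`, `z_plasma`,
#'   `z_jf`, `r_diff`; run metadata (sample sizes) is stored as an attribute
#'   and surfaced by [glance()].
#' @export
diffcorr_pairs <- function(paired, weighted = TRUE) {
  if (!inherits(paired, "paired_dataset")) {
    abort("`paired` must be a paired_dataset (see assemble_paired()).")
  }
  paired <- drop_zero_variance(paired)
  if (length(paired$metabolites) < 2L) {
    abort("Need at least two metabolites with nonzero variance.")
  }
  rp <- pearson_matrix(paired$plasma)
  rj <- pearson_matrix(paired$jf)
  idx <- pair_index(length(paired$metabolites))
  r_p <- rp[idx]
  r_j <- rj[idx]
  df <- tibble::tibble(
    metabolite_i = paired$metabolites[idx[, 1L]],
    metabolite_j = paired$metabolites[idx[, 2L]],
    r_plasma = r_p,
    r_jf = r_j,
    z_plasma = fisher_z(r_p),
    z_jf = fisher_z(r_j),
    r_diff = r_diff(r_p, r_j, paired$n_plasma, paired$n_jf, weighted = weighted)
  )
  new_diffcorr_tbl(df, list(
    stratum = paired$stratum,
    n_plasma = paired$n_plasma, n_jf = paired$n_jf,
    weighted = weighted
  ))
}

#' Permutation p-values for differential correlations
#'
#' Tests every pair's differential correlation against a permutation null in
#' which the compartment labels carry no information. One shared set of `B`
#' label shufflings is used for all pairs; for each shuffling the full
#' `r_diff` vector is recomputed and compared in absolute value with the
#' observed statistics. Two-sided p-values use the add-one estimator
#' `p = (1 + #permutations with |r_diff*| >= |r_diff|) / (B + 1)`, so
#' `p` is always in `[1/(B+1), 1]` and ties count against significance.
#'
#' @param paired A complete `paired_dataset`.
#' @param B Number of permutations (default 1000).
#' @param scheme `"pooled"` (default): all samples are re-assigned at random
#'   to two groups of the original sizes. `"paired"`: the plasma/JF labels
#'   are swapped independently within each subject; requires every subject to
#'   have both compartments.
#' @param seed Integer seed governing the shufflings; the global RNG state is
#'   left untouched.
#' @param weighted Passed to [r_diff()].
#' @return A `diffcorr_tbl` as from [diffcorr_pairs()] with an added
#'   `p_perm` column; the permutation settings join the metadata attribute.
#' @export
permute_diffcorr <- function(paired, B = 1000L,
                             scheme = c("pooled", "paired"),
                             seed = 1L, weighted = TRUE) {
  scheme <- match.arg(scheme)
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B)) {
    abort("`B` must be a positive integer number of permutations.")
  }
  B <- as.integer(B)
  paired <- drop_zero_variance(paired)
  obs <- diffcorr_pairs(paired, weighted = weighted)
  m <- length(paired$metabolites)
  idx <- pair_index(m)
  xp <- as_conc_matrix(paired$plasma)
  xj <- as_conc_matrix(paired$jf)
  n_p <- nrow(xp)
  n_j <- nrow(xj)
  w1 <- sqrt((n_p - 3) / 2)
  w2 <- sqrt((n_j - 3) / 2)
  lim <- 1 - 1e-7
  if (scheme == "paired") {
    if (n_p != n_j || !identical(paired$subjects_plasma, paired$subjects_jf)) {
      lonely <- union(
        setdiff(paired$subjects_plasma, paired$subjects_jf),
        setdiff(paired$subjects_jf, paired$subjects_plasma)
      )
      abort(paste0(
        "Paired permutation needs both compartments for every subject; offending subjects: ",
        toString(lonely)
      ))
    }
  }
  pooled <- rbind(xp, xj)
  n_tot <- n_p + n_j
  abs_obs <- abs(obs$r_diff)
  exceed <- integer(nrow(obs))
  rd_perm <- function(g1, g2) {
    c1 <- cor(pooled[g1, , drop = FALSE])[idx]
    c2 <- cor(pooled[g2, , drop = FALSE])[idx]
    if (!weighted) {
      atanh(pmin(pmax(c1, -lim), lim)) - atanh(pmin(pmax(c2, -lim), lim))
    } else {
      w1 * atanh(pmin(pmax(c1, -lim), lim)) - w2 * atanh(pmin(pmax(c2, -lim), lim))
    }
  }
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      if (scheme == "pooled") {
        ord <- sample.int(n_tot)
        g1 <- ord[seq_len(n_p)]
        g2 <- ord[(n_p + 1L):n_tot]
      } else {
        swap <- runif(n_p) < 0.5
        g1 <- ifelse(swap, n_p + seq_len(n_p), seq_len(n_p))
        g2 <- ifelse(swap, seq_len(n_p), n_p + seq_len(n_p))
      }
      exceed <- exceed + (abs(rd_perm(g1, g2)) >= abs_obs)
    }
  })
  obs$p_perm <- (1 + exceed) / (B + 1)
  meta <- attr(obs, "diffcorr_meta")
  meta$B <- B
  meta$scheme <- scheme
  meta$seed <- seed
  new_diffcorr_tbl(obs, meta)
}

#' Flag significant differential correlations with multiplicity control
#'
#' Adds `sig_nominal` (raw `p_perm < alpha`) and `sig_adjusted` flags. The
#' Bonferroni tier declares a pair significant when
#' `p_perm < alpha / n_pairs`; with 13,861 pairs and `alpha = 0.05` this is
#' the familiar `3.6e-6` threshold. Because a `B`-fold permutation p-value
#' cannot go below `1/(B + 1)`, the function warns when that floor exceeds
#' the Bonferroni threshold: no pair could then pass the adjusted tier and
#' more permutations are needed.
#'
#' @param table A `diffcorr_tbl` with `p_perm` filled.
#' @param alpha Nominal significance level (default 0.05).
#' @param method `"bonferroni"` (default), `"bh"` (Benjamini-Hochberg
#'   step-up FDR), or `"none"` (adjusted tier equals the nominal one).
#' @return The table with `sig_nominal` and `sig_adjusted` columns; the level,
#'   method and adjusted threshold join the metadata attribute.
#' @export
adjust_significance <- function(table, alpha = 0.05,
                                method = c("bonferroni", "bh", "none")) {
  method <- match.arg(method)
  if (!inherits(table, "diffcorr_tbl") || !"p_perm" %in% names(table)) {
    abort("`table` must be a diffcorr_tbl with permutation p-values.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single level in (0, 1).")
  }
  m_pairs <- nrow(table)
  table$sig_nominal <- table$p_perm < alpha
  threshold <- switch(method,
    bonferroni = alpha / m_pairs,
    bh = NA_real_,
    none = alpha
  )
  meta <- attr(table, "diffcorr_meta")
  if (method == "bonferroni") {
    if (!is.null(meta$B) && 1 / (meta$B + 1) > threshold) {
      warn(sprintf(
        paste0("Permutation floor 1/(B+1) = %.3g exceeds the Bonferroni ",
               "threshold %.3g; no pair can reach adjusted significance at ",
               "B = %d. Increase B."),
        1 / (meta$B + 1), threshold, meta$B
      ))
    }
    table$sig_adjusted <- table$p_perm < threshold
  } else if (method == "bh") {
    table$sig_adjusted <- p.adjust(table$p_perm, method = "BH") <= alpha
  } else {
    table$sig_adjusted <- table$sig_nominal
  }
  meta$alpha <- alpha
  meta$correction <- method
  meta$adjusted_threshold <- threshold
  new_diffcorr_tbl(table, meta)
}

#' Write / read a differential correlation table with its run metadata
#'
#' The on-disk format is a tab-separated table preceded by `#`-prefixed
#' `key: value` header lines carrying the run metadata (sample sizes,
#' permutation count and scheme, seed, level, correction method), so a saved
#' analysis can be reloaded and re-thresholded without recomputation.
#'
#' @param table A `diffcorr_tbl`.
#' @param path Output file path.
#' @return `write_diffcorr()` returns `path` invisibly; `read_diffcorr()`
#'   returns the restored `diffcorr_tbl`.
#' @export
write_diffcorr <- function(table, path) {
  meta <- attr(table, "diffcorr_meta") %||% list()
  hdr <- purrr::imap_chr(meta, function(v, k) {
    sprintf("# %s: %s", k, format(v, digits = 15))
  })
  readr::write_lines(hdr, path)
  readr::write_tsv(tibble::as_tibble(as.data.frame(table)), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_diffcorr
#' @export
read_diffcorr <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(kv) == 3L) {
      val <- kv[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[kv[2]]] <- if (!is.na(num)) num else val
    }
  }
  df <- readr::read_tsv(I(lines[setdiff(seq_along(lines), hdr)]),
                        show_col_types = FALSE, progress = FALSE)
  new_diffcorr_tbl(tibble::as_tibble(df), meta)
}
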
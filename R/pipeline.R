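#' Run the full differential correlation network pipeline
#'
#' For every stratum of the design (each analysed independently), the
#' pipeline: (1) applies the detection filter across the stratum's pooled
#' plasma + JF samples and half-minimum imputation; (2) assembles the paired
#' dataset; (3) computes all-pairs differential correlations and permutation
#' p-values; (4) flags significance at the nominal level and after
#' multiplicity correction; (5) builds the signed differential correlation
#' networks at both tiers, computes centralities and hubs on the nominal
#' network; and (6) writes per-stratum outputs plus a machine-readable
#' summary under `out_dir`.
#'
#' Outputs per stratum `<s>`: `<s>_diffcorr.tsv` (pair table with metadata
#' header), `<s>_network_nominal.<ext>` and `<s>_network_adjusted.<ext>` for
#' each requested format, `<s>_nodes.tsv` (centralities + hub flags),
#' `<s>_hubs.tsv`, and a shared `manifest.json` + `summary.json`. Re-running
#' with the same inputs and seed reproduces every file byte-for-byte.
#'
#' @param concentrations Concentration tibble (`sample_id` + metabolites).
#' @param design Cohort design tibble (see [read_cohort_design()]).
#' @param out_dir Output directory, created if needed.
#' @param classes Optional metabolite class tibble.
#' @param min_detection Detection filter threshold (strict `>`), default 0.8.
#' @param alpha Significance level, default 0.05.
#' @param B Permutations, default 1000.
#' @param correction `"bonferroni"`, `"bh"` or `"none"`.
#' @param scheme Permutation scheme, `"pooled"` or `"paired"`.
#' @param degree_quantile,centrality_quantile,hub_combine,hub_ties Hub rule,
#'   see [identify_hubs()].
#' @param export_formats Network export formats, see [export_network()].
#' @param seed Base seed; stratum `k` (alphabetical) uses `seed + k - 1`.
#' @param strata Optional subset of strata to analyse (default: all).
#' @return A tibble with one summary row per stratum (sample sizes, pair and
#'   significance counts by sign, node/edge counts, mean degree, hub count);
#'   the full per-stratum result bundles (paired data, diffcorr table,
#'   networks) are attached as the `"results"` attribute.
#' @export
run_dcm_pipeline <- function(concentrations, design, out_dir,
                             classes = NULL,
                             min_detection = 0.8,
                             alpha = 0.05,
                             B = 1000L,
                             correction = c("bonferroni", "bh", "none"),
                             scheme = c("pooled", "paired"),
                             degree_quantile = 0.9,
                             centrality_quantile = 0.9,
                             hub_combine = "or",
                             hub_ties = "include",
                             export_formats = c("graphml", "sif", "edge-table"),
                             seed = 1L,
                             strata = NULL) {
  correction <- match.arg(correction)
  scheme <- match.arg(scheme)
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B)) {
    abort("`B` must be a positive integer (>= 1) before any computation starts.")
  }
  assert_conc_tbl(concentrations, "concentrations")
  design <- validate_cohort_design(design)
  export_formats <- match.arg(export_formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_strata <- sort(unique(design$stratum))
  strata <- strata %||% all_strata
  bad <- setdiff(strata, all_strata)
  if (length(bad)) abort(paste0("Unknown strata requested: ", toString(bad)))

  config <- list(
    min_detection = min_detection, alpha = alpha, B = as.integer(B),
    correction = correction, scheme = scheme,
    degree_quantile = degree_quantile, centrality_quantile = centrality_quantile,
    hub_combine = hub_combine, hub_ties = hub_ties,
    export_formats = export_formats, seed = as.integer(seed), strata = strata
  )
  results <- list()
  summaries <- list()
  errors <- list()
  ext <- c(graphml = "graphml", sif = "sif", `edge-table` = "tsv")

  for (k in seq_along(strata)) {
    s <- strata[k]
    res <- tryCatch(
      run_stratum(concentrations, design, s, classes, config,
                  seed = as.integer(seed) + k - 1L, out_dir = out_dir, ext = ext),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[s]] <- conditionMessage(res)
      inform(sprintf("[dcmnet] stratum '%s' FAILED: %s", s, conditionMessage(res)))
      next
    }
    results[[s]] <- res
    summaries[[s]] <- res$summary
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  jsonlite::write_json(
    list(config = config, package_version = as.character(utils::packageVersion("dcmnet"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(strata = summaries, errors = errors),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  attr(summary_tbl, "results") <- results
  attr(summary_tbl, "errors") <- errors
  summary_tbl
}

run_stratum <- function(concentrations, design, s, classes, config, seed,
                        out_dir, ext) {
  ids <- design$sample_id[design$stratum == s]
  sub <- concentrations[concentrations$sample_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("No concentration rows for stratum '%s'.", s))
  filtered <- filter_by_detection(sub, config$min_detection)
  complete <- impute_half_min(filtered)
  paired <- assemble_paired(complete, design, s)
  inform(sprintf(
    "[dcmnet] stratum '%s': %d plasma + %d JF samples, %d/%d metabolites retained",
    s, paired$n_plasma, paired$n_jf,
    length(paired$metabolites), length(metabolite_cols(sub))
  ))
  dc <- permute_diffcorr(paired, B = config$B, scheme = config$scheme, seed = seed)
  dc <- adjust_significance(dc, alpha = config$alpha, method = config$correction)
  write_diffcorr(dc, file.path(out_dir, paste0(s, "_diffcorr.tsv")))

  nets <- list()
  for (tier in c("nominal", "adjusted")) {
    net <- suppressWarnings(build_network(dc, tier = tier, classes = classes))
    if (nrow(net$nodes) > 0L) {
      net <- centralities(net)
      net <- identify_hubs(net, config$degree_quantile, config$centrality_quantile,
                           combine = config$hub_combine, ties = config$hub_ties)
    }
    for (fmt in config$export_formats) {
      export_network(net, file.path(out_dir, sprintf("%s_network_%s.%s", s, tier, ext[[fmt]])),
                     format = fmt)
    }
    nets[[tier]] <- net
  }
  nominal <- nets$nominal
  readr::write_tsv(nominal$nodes, file.path(out_dir, paste0(s, "_nodes.tsv")),
                   progress = FALSE)
  hubs <- nominal$nodes[!is.na(nominal$nodes$is_hub) & nominal$nodes$is_hub, , drop = FALSE]
  readr::write_tsv(hubs, file.path(out_dir, paste0(s, "_hubs.tsv")), progress = FALSE)

  n_nodes <- nrow(nominal$nodes)
  n_edges <- nrow(nominal$edges)
  summary <- tibble::tibble(
    stratum = s,
    n_plasma = paired$n_plasma, n_jf = paired$n_jf,
    n_metabolites = length(paired$metabolites),
    n_pairs = nrow(dc),
    n_sig_nominal = sum(dc$sig_nominal),
    n_sig_positive = sum(dc$sig_nominal & dc$r_diff >= 0),
    n_sig_negative = sum(dc$sig_nominal & dc$r_diff < 0),
    n_sig_adjusted = sum(dc$sig_adjusted),
    n_nodes = n_nodes, n_edges = n_edges,
    mean_degree = if (n_nodes > 0) 2 * n_edges / n_nodes else 0,
    n_hubs = nrow(hubs)
  )
  inform(sprintf(
    "[dcmnet] stratum '%s': %d/%d pairs significant (%d positive, %d negative); network %d nodes / %d edges, mean degree %.2f, %d hubs",
    s, summary$n_sig_nominal, summary$n_pairs, summary$n_sig_positive,
    summary$n_sig_negative, n_nodes, n_edges, summary$mean_degree, summary$n_hubs
  ))
  list(stratum = s, paired = paired, diffcorr = dc, networks = nets,
       summary = summary)
}

#' Rebuild networks from a saved differential correlation table
#'
#' Re-thresholds a saved pair table at a new level and/or correction method
#' without recomputing correlations or permutations, then rebuilds the
#' signed network with centralities and hubs.
#'
#' @param path Path to a file written by [write_diffcorr()].
#' @param alpha,correction New significance settings.
#' @param tier Which tier's network to return.
#' @param classes Optional class annotations.
#' @param ... Passed to [identify_hubs()].
#' @return A `dc_network`.
#' @export
rebuild_network <- function(path, alpha = 0.05, correction = "bonferroni",
                            tier = "nominal", classes = NULL, ...) {
  dc <- read_diffcorr(path)
  dc <- adjust_significance(dc, alpha = alpha, method = correction)
  net <- build_network(dc, tier = tier, classes = classes)
  if (nrow(net$nodes) > 0L) {
    net <- centralities(net)
    net <- identify_hubs(net, ...)
  }
  net
}
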
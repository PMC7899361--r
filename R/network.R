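#' Build the signed differential correlation network
#'
#' Edges are exactly the metabolite pairs flagged significant at the chosen
#' tier; nodes are the metabolites incident to at least one such edge
#' (metabolites with no significant differential correlation do not appear).
#' Edge sign is the sign of the differential correlation statistic: a
#' positive sign means the pair is more strongly correlated in plasma than in
#' joint fluid (conventionally drawn red), a negative sign the reverse
#' (blue). Nodes and edges are ordered lexicographically so all exports are
#' byte-stable.
#'
#' @param table A `diffcorr_tbl` with significance flags (see
#'   [adjust_significance()]).
#' @param tier `"nominal"` (raw permutation p below the level) or
#'   `"adjusted"` (after multiplicity correction).
#' @param classes Optional tibble `metabolite`, `class` with panel class
#'   annotations carried onto the nodes.
#' @return A `dc_network`: a list with tibbles `nodes` (metabolite, class,
#'   centrality slots) and `edges` (metabolite_i, metabolite_j, r_diff, sign,
#'   p_perm), the underlying [igraph][igraph::graph_from_data_frame] graph,
#'   and the build metadata. An empty tier yields an empty network with a
#'   warning, not an error.
#' @export
build_network <- function(table, tier = c("nominal", "adjusted"),
                          classes = NULL) {
  tier <- match.arg(tier)
  flag <- paste0("sig_", tier)
  if (!inherits(table, "diffcorr_tbl") || !flag %in% names(table)) {
    abort("`table` must be a diffcorr_tbl with significance flags (run adjust_significance()).")
  }
  sig <- table[table[[flag]], , drop = FALSE]
  edges <- tibble::tibble(
    metabolite_i = pmin(sig$metabolite_i, sig$metabolite_j),
    metabolite_j = pmax(sig$metabolite_i, sig$metabolite_j),
    r_diff = sig$r_diff,
    sign = ifelse(sig$r_diff >= 0, "positive", "negative"),
    p_perm = if ("p_perm" %in% names(sig)) sig$p_perm else NA_real_
  )
  edges <- edges[order(edges$metabolite_i, edges$metabolite_j), , drop = FALSE]
  node_ids <- sort(unique(c(edges$metabolite_i, edges$metabolite_j)))
  if (length(node_ids) == 0L) {
    warn(sprintf("No pair is significant at the %s tier; returning an empty network.", tier))
  }
  nodes <- tibble::tibble(
    metabolite = node_ids,
    class = if (is.null(classes)) NA_character_ else {
      classes$class[match(node_ids, classes$metabolite)]
    },
    degree = NA_real_, betweenness = NA_real_, closeness = NA_real_,
    is_hub = NA
  )
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
  meta <- attr(table, "diffcorr_meta") %||% list()
  meta$tier <- tier
  structure(list(nodes = nodes, edges = edges, graph = g, meta = meta),
            class = "dc_network")
}

#' @export
print.dc_network <- function(x, ...) {
  nn <- nrow(x$nodes)
  ne <- nrow(x$edges)
  cat(sprintf("<dc_network> %d nodes, %d edges (mean degree %.2f); %d positive / %d negative\n",
              nn, ne, if (nn > 0) 2 * ne / nn else 0,
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  if (!all(is.na(x$nodes$is_hub))) {
    cat(sprintf("  hubs: %s\n", toString(x$nodes$metabolite[x$nodes$is_hub])))
  }
  invisible(x)
}

#' Node centralities of a differential correlation network
#'
#' Fills the `degree`, `betweenness` and `closeness` node attributes.
#' Degree is the incident edge count. Betweenness is shortest-path
#' betweenness over unit-length edges (edge sign and weight ignored),
#' normalised by `(n-1)(n-2)/2`. Closeness uses the within-component
#' definition scaled by `(component size - 1) / (n - 1)` (the
#' Wasserman-Faust correction), so values remain comparable across the
#' components of a disconnected network and lie in `[0, 1]`.
#'
#' @param net A nonempty `dc_network`.
#' @return The network with centrality columns filled.
#' @export
centralities <- function(net) {
  if (!inherits(net, "dc_network")) abort("`net` must be a dc_network.")
  n <- nrow(net$nodes)
  if (n == 0L) abort("Cannot compute centralities of an empty network.")
  g <- net$graph
  deg <- igraph::degree(g)
  btw <- if (n > 2L) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    rep(0, n)
  }
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  comp_size <- comp$csize[comp$membership]
  clo <- vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ]) & seq_len(n) != i
    if (!any(reach) || n == 1L) return(0)
    ((comp_size[i] - 1) / sum(d[i, reach])) * ((comp_size[i] - 1) / (n - 1))
  }, numeric(1))
  ord <- match(net$nodes$metabolite, igraph::V(g)$name)
  net$nodes$degree <- as.numeric(deg[ord])
  net$nodes$betweenness <- as.numeric(btw[ord])
  net$nodes$closeness <- as.numeric(clo[ord])
  net
}

#' Identify core metabolites (network hubs)
#'
#' A node is a hub when its degree reaches the `degree_quantile` of all node
#' degrees AND its betweenness or closeness (or both, with
#' `combine = "and"`) reaches the `centrality_quantile` of the respective
#' distribution. Thresholds use the median-unbiased sample quantile
#' (`stats::quantile(type = 8)`); with the default `ties = "include"` a node
#' exactly at the threshold qualifies, while `ties = "strict"` requires
#' strictly exceeding it (under which a perfectly regular graph has no hubs).
#'
#' @param net A `dc_network` with centralities computed.
#' @param degree_quantile,centrality_quantile Quantile levels in `[0, 1]`
#'   (defaults 0.9).
#' @param combine How the two centrality criteria combine: `"or"` (default,
#'   high in at least one) or `"and"` (high in both).
#' @param ties `"include"` (default) or `"strict"` threshold comparison.
#' @return The network with the logical `is_hub` node column filled.
#' @export
identify_hubs <- function(net, degree_quantile = 0.9,
                          centrality_quantile = 0.9,
                          combine = c("or", "and"),
                          ties = c("include", "strict")) {
  combine <- match.arg(combine)
  ties <- match.arg(ties)
  if (!inherits(net, "dc_network")) abort("`net` must be a dc_network.")
  if (nrow(net$nodes) == 0L) abort("Cannot identify hubs in an empty network.")
  if (anyNA(net$nodes$degree)) net <- centralities(net)
  cmp <- if (ties == "include") `>=` else `>`
  thr <- function(x, q) quantile(x, q, type = 8, names = FALSE)
  deg_ok <- cmp(net$nodes$degree, thr(net$nodes$degree, degree_quantile))
  btw_ok <- cmp(net$nodes$betweenness, thr(net$nodes$betweenness, centrality_quantile))
  clo_ok <- cmp(net$nodes$closeness, thr(net$nodes$closeness, centrality_quantile))
  cent_ok <- if (combine == "or") btw_ok | clo_ok else btw_ok & clo_ok
  net$nodes$is_hub <- deg_ok & cent_ok
  net
}

#' Export a differential correlation network
#'
#' Writes the network for downstream tools such as Cytoscape. `"graphml"`
#' carries all node and edge attributes in one file and round-trips exactly
#' through [read_network_graphml()]. `"sif"` writes the simple interaction
#' format with interaction types `pos_dc`/`neg_dc` plus a companion
#' `<path>_nodes.tsv` attribute table. `"edge-table"` writes a plain TSV of
#' the edges. Node ordering is lexicographic, so repeated exports of the
#' same network are byte-identical.
#'
#' @param net A `dc_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"edge-table"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "edge-table")) {
  format <- match.arg(format)
  if (!inherits(net, "dc_network")) abort("`net` must be a dc_network.")
  if (format == "graphml") {
    g <- net$graph
    for (col in c("class", "degree", "betweenness", "closeness")) {
      g <- igraph::set_vertex_attr(g, col, value = net$nodes[[col]])
    }
    g <- igraph::set_vertex_attr(
      g, "is_hub",
      value = ifelse(is.na(net$nodes$is_hub), FALSE, net$nodes$is_hub)
    )
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s",
                     net$edges$metabolite_i,
                     ifelse(net$edges$sign == "positive", "pos_dc", "neg_dc"),
                     net$edges$metabolite_j)
    readr::write_lines(lines, path)
    readr::write_tsv(net$nodes, paste0(path, "_nodes.tsv"), progress = FALSE)
  } else {
    readr::write_tsv(net$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @param classes Optional class annotation tibble to re-attach on read.
#' @export
read_network_graphml <- function(path, classes = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  name <- igraph::V(g)$name %||% character(0)
  vattr <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(
    metabolite = name,
    class = vattr$class %||% NA_character_,
    degree = as.numeric(vattr$degree %||% NA_real_),
    betweenness = as.numeric(vattr$betweenness %||% NA_real_),
    closeness = as.numeric(vattr$closeness %||% NA_real_),
    is_hub = as.logical(vattr$is_hub %||% NA)
  )
  el <- igraph::as_edgelist(g)
  eattr <- igraph::edge_attr(g)
  edges <- tibble::tibble(
    metabolite_i = pmin(el[, 1L], el[, 2L]),
    metabolite_j = pmax(el[, 1L], el[, 2L]),
    r_diff = as.numeric(eattr$r_diff %||% NA_real_),
    sign = as.character(eattr$sign %||% NA_character_),
    p_perm = as.numeric(eattr$p_perm %||% NA_real_)
  )
  ord <- order(edges$metabolite_i, edges$metabolite_j)
  edges <- edges[ord, , drop = FALSE]
  nodes <- nodes[order(nodes$metabolite), , drop = FALSE]
  if (!is.null(classes)) {
    nodes$class <- classes$class[match(nodes$metabolite, classes$metabolite)]
  }
  g2 <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                      vertices = data.frame(name = nodes$metabolite))
  structure(list(nodes = nodes, edges = edges, graph = g2, meta = list()),
            class = "dc_network")
}
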
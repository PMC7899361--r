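#' Tidy and glance methods for differential correlation results
#'
#' `tidy()` on a `diffcorr_tbl` returns the per-pair records as a plain
#' tibble; on a `dc_network` it returns the node table (one row per
#' metabolite with class, centralities and hub flag). `glance()` returns a
#' one-row summary: for a pair table the sample sizes, permutation settings
#' and significance counts by sign; for a network the node/edge counts, mean
#' degree, signed edge counts and hub count.
#'
#' @param x A `diffcorr_tbl` or `dc_network`.
#' @param ... Unused.
#' @return A tibble.
#' @name dcmnet-tidiers
NULL

#' @rdname dcmnet-tidiers
#' @method tidy diffcorr_tbl
#' @export
tidy.diffcorr_tbl <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  attr(out, "diffcorr_meta") <- NULL
  out
}

#' @rdname dcmnet-tidiers
#' @method glance diffcorr_tbl
#' @export
glance.diffcorr_tbl <- function(x, ...) {
  meta <- attr(x, "diffcorr_meta") %||% list()
  has_sig <- "sig_nominal" %in% names(x)
  tibble::tibble(
    n_pairs = nrow(x),
    n_plasma = meta$n_plasma %||% NA_integer_,
    n_jf = meta$n_jf %||% NA_integer_,
    B = meta$B %||% NA_integer_,
    scheme = meta$scheme %||% NA_character_,
    alpha = meta$alpha %||% NA_real_,
    correction = meta$correction %||% NA_character_,
    n_sig_nominal = if (has_sig) sum(x$sig_nominal) else NA_integer_,
    n_sig_positive = if (has_sig) sum(x$sig_nominal & x$r_diff >= 0) else NA_integer_,
    n_sig_negative = if (has_sig) sum(x$sig_nominal & x$r_diff < 0) else NA_integer_,
    n_sig_adjusted = if ("sig_adjusted" %in% names(x)) sum(x$sig_adjusted) else NA_integer_
  )
}

#' @rdname dcmnet-tidiers
#' @method tidy dc_network
#' @export
tidy.dc_network <- function(x, ...) {
  x$nodes
}

#' @rdname dcmnet-tidiers
#' @method glance dc_network
#' @export
glance.dc_network <- function(x, ...) {
  nn <- nrow(x$nodes)
  ne <- nrow(x$edges)
  tibble::tibble(
    n_nodes = nn,
    n_edges = ne,
    mean_degree = if (nn > 0) 2 * ne / nn else 0,
    n_positive_edges = sum(x$edges$sign == "positive"),
    n_negative_edges = sum(x$edges$sign == "negative"),
    n_hubs = sum(x$nodes$is_hub, na.rm = TRUE)
  )
}

#' Plot differential correlations of all metabolite pairs
#'
#' Scatter of each pair's plasma correlation against its joint-fluid
#' correlation. Pairs on the diagonal correlate identically in both
#' compartments; significant pairs (when flags are present) are coloured by
#' the sign of the differential correlation — red for plasma-dominant,
#' blue for JF-dominant.
#'
#' @param object A `diffcorr_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffcorr_tbl
#' @export
autoplot.diffcorr_tbl <- function(object, ...) {
  df <- tidy(object)
  df$status <- if ("sig_nominal" %in% names(df)) {
    dplyr::case_when(
      df$sig_nominal & df$r_diff >= 0 ~ "positive differential",
      df$sig_nominal ~ "negative differential",
      .default = "not significant"
    )
  } else "not significant"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_plasma, y = .data$r_jf,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "positive differential" = "#c0392b",
      "negative differential" = "#2980b9",
      "not significant" = "grey70"
    )) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "Pearson r (plasma)", y = "Pearson r (joint fluid)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a differential correlation network
#'
#' Force-directed layout (deterministic for a given network) with red edges
#' for positive differential correlations, blue for negative; node size
#' scales with degree and hubs are labelled.
#'
#' @param object A `dc_network` with centralities computed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dc_network
#' @export
autoplot.dc_network <- function(object, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::annotate("text", 0, 0, label = "empty network"))
  }
  xy <- withr::with_seed(1L, igraph::layout_with_fr(object$graph))
  pos <- tibble::tibble(metabolite = igraph::V(object$graph)$name,
                        x = xy[, 1L], y = xy[, 2L])
  nodes <- dplyr::left_join(object$nodes, pos, by = "metabolite")
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(metabolite_i = "metabolite")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(metabolite_j = "metabolite"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   colour = .data$sign),
      alpha = 0.45, linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "grey25"
    ) +
    ggplot2::geom_text(
      data = nodes[!is.na(nodes$is_hub) & nodes$is_hub, , drop = FALSE],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$metabolite),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "#c0392b", negative = "#2980b9")) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::labs(colour = "differential sign", size = "degree") +
    ggplot2::theme_void()
}

#' Plot node centralities against degree
#'
#' Mirrors the standard hub-identification view: closeness and betweenness
#' centrality each plotted against node degree, hubs highlighted.
#'
#' @param net A `dc_network` with centralities (and optionally hubs) filled.
#' @return A ggplot object, faceted by centrality measure.
#' @export
plot_centralities <- function(net) {
  if (!inherits(net, "dc_network")) abort("`net` must be a dc_network.")
  df <- net$nodes |>
    tidyr::pivot_longer(c("closeness", "betweenness"),
                        names_to = "measure", values_to = "centrality")
  df$hub <- !is.na(df$is_hub) & df$is_hub
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$centrality,
                                   colour = .data$hub)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(
      data = df[df$hub, , drop = FALSE],
      ggplot2::aes(label = .data$metabolite), vjust = -0.8, size = 3,
      show.legend = FALSE
    ) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey50")) +
    ggplot2::labs(x = "node degree", y = "centrality", colour = "core metabolite") +
    ggplot2::theme_bw()
}
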
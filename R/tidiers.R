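#' @rdname compset-tidiers
#' @param x A result object.
#' @param ... Unused.
#' @method tidy compset_hea
#' @export
tidy.compset_hea <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Tidy and summarize compset results
#'
#' `tidy()` returns the per-unit result rows as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @name compset-tidiers
#' @param x A result object.
#' @param ... Unused.
#' @method glance compset_hea
#' @export
glance.compset_hea <- function(x, ...) {
  tibble(n_assays = nrow(x),
         n_flagged = sum(x$flagged),
         n_significant = sum(x$q <= 0.05),
         n_skipped = attr(x, "n_skipped") %||% 0L,
         top_assay = if (nrow(x)) x$assay_id[1] else NA_character_,
         top_es = if (nrow(x)) x$es[1] else NA_real_)
}

#' @rdname compset-tidiers
#' @method tidy compset_tree_enrichment
#' @export
tidy.compset_tree_enrichment <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname compset-tidiers
#' @method glance compset_tree_enrichment
#' @export
glance.compset_tree_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_flagged = sum(x$flagged),
         n_significant = sum(x$q <= 0.05),
         top_term = if (nrow(x)) x$term[1] else NA_character_,
         top_es = if (nrow(x)) x$es[1] else NA_real_)
}

#' @rdname compset-tidiers
#' @method tidy compset_clusters
#' @export
tidy.compset_clusters <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname compset-tidiers
#' @method glance compset_clusters
#' @export
glance.compset_clusters <- function(x, ...) {
  tibble(k = attr(x, "k"),
         n_compounds = nrow(x),
         inertia = attr(x, "inertia"),
         mean_silhouette = attr(x, "silhouette"))
}

#' @rdname compset-tidiers
#' @method tidy cc_network
#' @export
tidy.cc_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' @rdname compset-tidiers
#' @method glance cc_network
#' @export
glance.cc_network <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_edges = nrow(x$edges),
         n_terms = length(unique(x$edges$class_term)),
         class_kind = x$class_kind)
}

unclass_result <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "compset_")]
  for (a in c("n_skipped", "universe", "query_name", "kind", "centroids",
              "inertia", "k", "silhouette")) {
    attr(x, a) <- NULL
  }
  x
}

#' Plot hit-enriched-assay results
#'
#' Lollipop chart of enrichment scores for the top assays, colored by FDR
#' significance.
#'
#' @param object A `compset_hea` result.
#' @param top_n Number of top-ranked assays to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compset_hea
#' @export
autoplot.compset_hea <- function(object, top_n = 20, ...) {
  d <- head(tidy(object), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$es,
    y = stats::reorder(.data$assay_id, .data$es),
    colour = .data$q <= 0.05)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$assay_id, .data$es))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "enrichment score (bits)", y = NULL,
                  colour = "q ≤ 0.05",
                  title = "Hit-enriched assays") +
    ggplot2::theme_minimal()
}

#' Plot tree-enrichment results
#'
#' @param object A `compset_tree_enrichment` result.
#' @param top_n Number of top-ranked terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compset_tree_enrichment
#' @export
autoplot.compset_tree_enrichment <- function(object, top_n = 20, ...) {
  d <- head(tidy(object), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$es, y = stats::reorder(.data$term, .data$es),
    size = .data$n_query_compounds, colour = -log10(.data$q))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enrichment score (bits)", y = NULL,
                  size = "query compounds", colour = "-log10 q",
                  title = "Enrichment tree") +
    ggplot2::theme_minimal()
}

#' Plot a compound-cluster network
#'
#' Cluster-by-term matrix of enrichment edges.
#'
#' @param object A `cc_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_network
#' @export
autoplot.cc_network <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$cluster), y = .data$class_term, fill = .data$es)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "compound cluster", y = NULL, fill = "ES (bits)",
                  title = sprintf("CC-network (%s)", object$class_kind)) +
    ggplot2::theme_minimal()
}
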
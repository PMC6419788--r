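#' Cluster query compounds in fingerprint space
#'
#' k-means on 0/1 fingerprint vectors treated as reals with Euclidean
#' distance (squared Euclidean on bit vectors is a linear transform of
#' Hamming distance, so the structural-similarity intent is preserved).
#' Initialization is k-means++ seeded deterministically from `seed`;
#' `restarts` independent runs are performed and the partition with the
#' lowest within-cluster sum of squares wins, ties broken by restart index.
#' Identical inputs, `k`, and `seed` give identical assignments.
#'
#' @param fps Fingerprint matrix (rows = compounds, rownames = merge keys).
#' @param k Number of clusters, `1 <= k <= nrow(fps)`. No automatic
#'   selection is attempted; see the mean silhouette width in [glance()]
#'   to guide the choice.
#' @param seed Master seed for initialization.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A tibble of class `compset_clusters`: `merge_key`, `cluster`
#'   (integer), with attributes `centroids` (k x bits matrix), `inertia`,
#'   and `silhouette` (mean silhouette width, `NA` for k = 1).
#' @export
cluster_compounds <- function(fps, k, seed = 1L, restarts = 10L) {
  if (!is.matrix(fps)) fps <- as.matrix(fps)
  n <- nrow(fps)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    abort("`k` must be a positive integer", class = "compset_parameter_error")
  }
  if (k > n) {
    abort(sprintf("`k` (%d) exceeds the number of compounds (%d)", k, n),
          class = "compset_parameter_error")
  }
  x <- fps
  storage.mode(x) <- "double"

  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- with_seed(derive_seed(seed, paste0("kmeans++", r)),
                         kmeanspp_init(x, k))
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-9) best <- fit
  }
  # canonical cluster ids: by order of first appearance
  ids <- match(best$cluster, unique(best$cluster))
  out <- tibble(merge_key = rownames(fps), cluster = as.integer(ids))
  cent <- best$centers[unique(best$cluster), , drop = FALSE]
  rownames(cent) <- seq_len(nrow(cent))
  attr(out, "centroids") <- cent
  attr(out, "inertia") <- best$tot.withinss
  attr(out, "k") <- as.integer(k)
  attr(out, "silhouette") <- mean_silhouette(x, ids)
  class(out) <- c("compset_clusters", class(out))
  out
}

# k-means++ seeding (Arthur & Vassilvitskii 2007): first center uniform,
# subsequent centers sampled proportional to squared distance to the
# nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- colSums((t(x) - centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

mean_silhouette <- function(x, cluster) {
  if (length(unique(cluster)) < 2L ||
      !requireNamespace("cluster", quietly = TRUE)) {
    return(NA_real_)
  }
  sil <- cluster::silhouette(cluster, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Enrichment of one compound cluster against annotation classes
#'
#' The cluster `R` plays the role of the query and `R^C` (the background
#' minus the cluster) the complement; interaction-pair 2x2 counts per class
#' term are scored exactly as in [run_tree_enrichment()].
#'
#' @param members Character vector of the cluster's merge keys.
#' @param index A `term_index` over the class tree.
#' @param background Analysis universe of merge keys (contains `members`).
#' @return The `compset_tree_enrichment` tibble for this cluster.
#' @export
cc_enrichment <- function(members, index, background) {
  run_tree_enrichment(compound_set(members, name = "cluster"),
                      index, background, report_threshold = Inf)
}

#' Build the compound-cluster network (CC-Network)
#'
#' Links each compound cluster to the annotation classes (target families
#' or disease terms) in which its members' interactions are enriched. Edges
#' keep (cluster, term) pairs with `es >= edge_threshold` and
#' `q <= q_threshold`, where q is BH-adjusted jointly over all (cluster,
#' term) pairs.
#'
#' @param clusters A `compset_clusters` tibble from [cluster_compounds()].
#' @param index A `term_index` over the class tree.
#' @param background Analysis universe of merge keys.
#' @param edge_threshold Minimum enrichment score (bits) for an edge.
#' @param q_threshold Maximum FDR q for an edge.
#' @return An object of class `cc_network`: list with `clusters` (tibble
#'   `cluster`, `n_members`, `members`), `edges` (tibble `cluster`,
#'   `class_term`, `a`, `b`, `c`, `d`, `es`, `p`, `q`), `class_kind`.
#' @export
build_cc_network <- function(clusters, index, background,
                             edge_threshold = 1.0, q_threshold = 0.05) {
  stopifnot(inherits(index, "term_index"))
  memb <- split(clusters$merge_key, clusters$cluster)
  if (length(memb) == 0L) {
    return(structure(list(clusters = tibble(cluster = integer(),
                                            n_members = integer(),
                                            members = list()),
                          edges = empty_cc_edges(), class_kind = index$kind),
                     class = "cc_network"))
  }
  per <- purrr::imap(memb, function(m, cl) {
    e <- cc_enrichment(m, index, background)
    mutate(e, cluster = as.integer(cl))
  })
  all_edges <- bind_rows(per)
  if (nrow(all_edges)) {
    all_edges <- all_edges |>
      mutate(q = bh_fdr(.data$p)) |>
      filter(.data$es >= edge_threshold, .data$q <= q_threshold) |>
      arrange(.data$cluster, desc(.data$es), .data$term) |>
      select("cluster", class_term = "term", "a", "b", "c", "d",
             "es", "p", "q")
  } else {
    all_edges <- empty_cc_edges()
  }
  structure(
    list(
      clusters = tibble(cluster = as.integer(names(memb)),
                        n_members = lengths(memb),
                        members = purrr::map(memb, sort)),
      edges = all_edges,
      class_kind = index$kind
    ),
    class = "cc_network")
}

empty_cc_edges <- function() {
  tibble(cluster = integer(), class_term = character(),
         a = integer(), b = integer(), c = integer(), d = integer(),
         es = numeric(), p = numeric(), q = numeric())
}

#' @export
print.cc_network <- function(x, ...) {
  cat(sprintf("<cc_network (%s): %d clusters, %d edges>\n",
              x$class_kind, nrow(x$clusters), nrow(x$edges)))
  print(x$edges, ...)
  invisible(x)
}

#' Export a CC-Network
#'
#' Writes three files under `dir`: `ccnetwork.graphml` (typed nodes:
#' clusters and class terms; edges weighted by enrichment score),
#' `cc_edges.tsv`, and `cc_members.tsv`. Output is byte-stable for
#' identical networks.
#'
#' @param network A `cc_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cc_network <- function(network, dir) {
  stopifnot(inherits(network, "cc_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- network$edges
  cl_nodes <- tibble(name = paste0("CC", network$clusters$cluster),
                     type = "cluster")
  term_nodes <- tibble(name = unique(edges$class_term), type = "class_term")
  g <- igraph::graph_from_data_frame(
    d = tibble(from = paste0("CC", edges$cluster), to = edges$class_term,
               weight = edges$es, q = edges$q),
    directed = FALSE,
    vertices = bind_rows(cl_nodes, term_nodes))
  igraph::write_graph(g, file.path(dir, "ccnetwork.graphml"),
                      format = "graphml")
  readr::write_tsv(edges, file.path(dir, "cc_edges.tsv"))
  readr::write_tsv(
    tibble(cluster = rep(network$clusters$cluster,
                         network$clusters$n_members),
           merge_key = unlist(network$clusters$members, use.names = FALSE)),
    file.path(dir, "cc_members.tsv"))
  invisible(dir)
}
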
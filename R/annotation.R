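#' Load a compound-entity interaction table
#'
#' Tab-separated columns `compound_id`, `entity_id`, `entity_kind`
#' (`target` or `disease`), `source`. Edges duplicated across sources are
#' collapsed; the raw and deduplicated row counts are reported.
#'
#' @param path Path to the TSV.
#' @param registry Optional registry for compound id resolution.
#' @return A tibble of unique edges `merge_key`, `entity_id`, `entity_kind`,
#'   with attribute `n_raw` (rows before deduplication).
#' @export
load_interactions <- function(path, registry = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("compound_id", "entity_id", "entity_kind")
  if (!all(need %in% names(tab))) {
    abort("interaction table needs columns compound_id, entity_id, entity_kind",
          class = "compset_format_error")
  }
  bad <- !tab$entity_kind %in% c("target", "disease")
  if (any(bad)) {
    abort(sprintf("unknown entity_kind '%s' on line %d",
                  tab$entity_kind[which(bad)[1]], which(bad)[1] + 1L),
          class = "compset_format_error")
  }
  n_raw <- nrow(tab)
  tab$merge_key <- if (is.null(registry)) tab$compound_id else {
    resolve_ids(tab$compound_id, registry)
  }
  out <- tab |>
    filter(!is.na(.data$merge_key)) |>
    distinct(.data$merge_key, .data$entity_id, .data$entity_kind)
  inform(sprintf("interactions: %d raw rows, %d unique edges", n_raw, nrow(out)))
  attr(out, "n_raw") <- n_raw
  out
}

#' Load an ontology/classification tree with its annotations
#'
#' The tree is a parent-child edge list TSV with columns `child_term`,
#' `parent_term` (a DAG: multiple parents allowed for GO / Disease Ontology
#' / MeSH; protein-family trees must be single-parent). Annotations map
#' terms to entity ids (TSV columns `term`, `entity_id`).
#'
#' @param tree_path,annot_path Paths to the two TSVs.
#' @param kind One of `"protein_family"`, `"go_bp"`, `"disease_ontology"`,
#'   `"mesh"`.
#' @return An object of class `ontology_tree`: list with `kind`, `nodes`,
#'   `parents` (tibble `child`, `parent`), `term_entities` (tibble `term`,
#'   `entity_id`).
#' @export
load_ontology <- function(tree_path, annot_path,
                          kind = c("disease_ontology", "protein_family",
                                   "go_bp", "mesh")) {
  kind <- match.arg(kind)
  edges <- readr::read_tsv(tree_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!all(c("child_term", "parent_term") %in% names(edges))) {
    abort("tree file needs columns child_term and parent_term",
          class = "compset_format_error")
  }
  annot <- readr::read_tsv(annot_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!all(c("term", "entity_id") %in% names(annot))) {
    abort("annotation file needs columns term and entity_id",
          class = "compset_format_error")
  }
  ontology_tree(edges$child_term, edges$parent_term,
                annot$term, annot$entity_id, kind = kind)
}

#' Construct an ontology tree in memory
#'
#' @param child,parent Parallel character vectors of tree edges.
#' @param term,entity_id Parallel character vectors of direct annotations.
#' @param kind Tree kind; protein-family trees are validated as
#'   single-parent.
#' @return An `ontology_tree` object.
#' @export
ontology_tree <- function(child, parent, term, entity_id,
                          kind = "disease_ontology") {
  parents <- distinct(tibble(child = child, parent = parent))
  nodes <- union(parents$child, parents$parent)
  g <- igraph::graph_from_data_frame(parents, directed = TRUE)
  if (!igraph::is_dag(g)) {
    abort(sprintf("classification graph contains a cycle (involving term '%s')",
                  find_cycle_member(parents)),
          class = "compset_graph_error")
  }
  if (kind == "protein_family") {
    multi <- names(which(table(parents$child) > 1))
    if (length(multi)) {
      abort(sprintf("protein-family tree must be single-parent; term '%s' has multiple parents",
                    multi[1]),
            class = "compset_graph_error")
    }
  }
  te <- distinct(tibble(term = term, entity_id = entity_id))
  nodes <- union(nodes, te$term)
  structure(list(kind = kind, nodes = nodes, parents = parents,
                 term_entities = te),
            class = "ontology_tree")
}

# One member of some cycle in a child->parent edge list (for error messages).
find_cycle_member <- function(parents) {
  g <- igraph::graph_from_data_frame(parents, directed = TRUE)
  for (v in igraph::V(g)$name) {
    nbr <- parents$parent[parents$child == v]
    on_cycle <- any(purrr::map_lgl(nbr, function(p) {
      v %in% igraph::subcomponent(g, p, mode = "out")$name
    }))
    if (on_cycle) return(v)
  }
  "unknown"
}

#' Build a term-to-compound index with descendant aggregation
#'
#' For every term, collects the entities annotated to the term or any of its
#' descendants, the compounds interacting with any of those entities, and
#' the number of distinct compound-entity interaction pairs. A pair
#' reachable through two paths of the DAG is counted once. Levels are
#' distances from the root(s), for tree-style rendering.
#'
#' @param tree An `ontology_tree`.
#' @param interactions An edge tibble from [load_interactions()] (or with
#'   columns `merge_key`, `entity_id`).
#' @return An object of class `term_index`: list with `terms` (tibble
#'   `term`, `level`, `n_entities`, `n_compounds`, `interaction_count`, and
#'   list-columns `entities`, `compounds`), `interactions`, `kind`.
#' @export
build_term_index <- function(tree, interactions) {
  stopifnot(inherits(tree, "ontology_tree"))
  stopifnot(all(c("merge_key", "entity_id") %in% names(interactions)))
  g <- igraph::graph_from_data_frame(tree$parents, directed = TRUE,
                                     vertices = tibble(name = tree$nodes))
  te <- split(tree$term_entities$entity_id, tree$term_entities$term)
  # descendants of t = vertices that reach t along child->parent edges
  ints <- distinct(as_tibble(interactions[, c("merge_key", "entity_id")]))
  by_entity <- split(ints$merge_key, ints$entity_id)

  roots <- setdiff(tree$parents$parent, tree$parents$child)
  lev <- rep(NA_real_, length(tree$nodes))
  names(lev) <- tree$nodes
  if (length(roots)) {
    d <- igraph::distances(g, v = tree$nodes, to = roots, mode = "out")
    lev <- apply(d, 1, function(r) suppressWarnings(min(r)))
  }
  lev[!is.finite(lev)] <- 0

  rows <- purrr::map(tree$nodes, function(t) {
    below <- igraph::subcomponent(g, t, mode = "in")$name
    ents <- sort(unique(unlist(te[below], use.names = FALSE)))
    sub <- ints[ints$entity_id %in% ents, , drop = FALSE]
    tibble(
      term = t,
      level = unname(lev[t]),
      n_entities = length(ents),
      n_compounds = length(unique(sub$merge_key)),
      interaction_count = nrow(sub),
      entities = list(ents),
      compounds = list(sort(unique(sub$merge_key)))
    )
  })
  structure(list(terms = bind_rows(rows) |> arrange(.data$level, .data$term),
                 interactions = ints, kind = tree$kind),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat(sprintf("<term_index: %s; %d terms, %d interaction edges>\n",
              x$kind, nrow(x$terms), nrow(x$interactions)))
  print(select(x$terms, -"entities", -"compounds"), ...)
  invisible(x)
}
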
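# Shared fixture builders (constructed in code; no stored data).

# A flagged screening assay: n_tested compounds, the first n_active flagged.
make_flag_assay <- function(n_tested, n_active, assay_id = "SCREEN1") {
  ids <- sprintf("CPD%04d", seq_len(n_tested))
  tibble::tibble(
    assay_id = assay_id,
    merge_key = ids,
    flag = c(rep("active", n_active), rep("inactive", n_tested - n_active)),
    direction = "higher_is_active",
    title = "phenotypic screen",
    target_gene = NA_character_
  )
}

# An activity-only assay from a named numeric vector.
make_activity_assay <- function(activities, assay_id = "A1",
                                direction = "higher_is_active") {
  tibble::tibble(assay_id = assay_id, merge_key = names(activities),
                 activity = unname(activities), direction = direction)
}

# Random small DAG over n nodes (node i links to 1-2 earlier nodes), with
# random term annotations and compound-entity edges.
random_annotation_case <- function(n_terms = 8, n_entities = 10,
                                   n_compounds = 15, seed = 1) {
  withr::with_seed(seed, {
    terms <- paste0("T", seq_len(n_terms))
    child <- character(); parent <- character()
    for (i in 2:n_terms) {
      np <- sample(1:2, 1)
      ps <- sample(seq_len(i - 1), min(np, i - 1))
      child <- c(child, rep(terms[i], length(ps)))
      parent <- c(parent, terms[ps])
    }
    ann_term <- sample(terms, n_entities, replace = TRUE)
    ents <- paste0("E", seq_len(n_entities))
    cps <- paste0("C", seq_len(n_compounds))
    n_edges <- n_compounds * 2
    ints <- tibble::tibble(
      merge_key = sample(cps, n_edges, replace = TRUE),
      entity_id = sample(ents, n_edges, replace = TRUE),
      entity_kind = "disease"
    ) |> dplyr::distinct()
    list(
      tree = compset::ontology_tree(child, parent, ann_term, ents,
                                    kind = "disease_ontology"),
      interactions = ints,
      child = child, parent = parent,
      ann = tibble::tibble(term = ann_term, entity_id = ents)
    )
  })
}

# Transitive descendants of `term` (inclusive) from raw edge vectors —
# reachability oracle independent of build_term_index.
descendants_of <- function(term, child, parent) {
  res <- term
  repeat {
    more <- child[parent %in% res & !child %in% res]
    if (length(more) == 0L) return(res)
    res <- c(res, more)
  }
}
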
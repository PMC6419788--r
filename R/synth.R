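#' Configuration for a synthetic compound universe
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: a 10,000-compound universe, a 40-compound query (the size of
#' a typical deduplicated screening-hit set), 50 flag-based assays of 2,000
#' tested compounds each with one assay whose hit probability is planted at
#' 0.3 inside the query versus a 0.001 background, three planted
#' fingerprint blocks (within-block bit probability 0.9, between 0.1), and
#' a disease/target annotation planted on one block's query compounds.
#'
#' @param n_compounds,q_size,n_assays,assay_size Universe dimensions.
#' @param planted_assay_hit_prob_in_q,background_hit_prob Hit probabilities
#'   for the planted assay inside the query and everywhere else.
#' @param n_clusters_planted Number of planted fingerprint blocks.
#' @param within_block_bit_prob,between_block_bit_prob Probability that a
#'   block-characteristic (resp. foreign) fingerprint bit is set.
#' @param fp_bits Fingerprint width.
#' @param planted_term Ontology term enriched in one planted block.
#' @param planted_term_annotation_prob_in_cluster Probability that a
#'   planted-block query compound carries an interaction under
#'   `planted_term`.
#' @param background_annotation_prob Probability that any compound carries
#'   a random background interaction.
#' @param seed Master seed; named sub-streams (fingerprints, assays,
#'   annotations) derive their own seeds from it so adding a stream never
#'   perturbs the others.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_compounds = 10000L, q_size = 40L, n_assays = 50L,
                         assay_size = 2000L,
                         planted_assay_hit_prob_in_q = 0.3,
                         background_hit_prob = 0.001,
                         n_clusters_planted = 3L,
                         within_block_bit_prob = 0.9,
                         between_block_bit_prob = 0.1,
                         fp_bits = 256L,
                         planted_term = "viral infectious disease",
                         planted_term_annotation_prob_in_cluster = 0.8,
                         background_annotation_prob = 0.02,
                         seed = 7L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              q_size = as.integer(q_size),
              n_assays = as.integer(n_assays),
              assay_size = as.integer(assay_size),
              planted_assay_hit_prob_in_q = planted_assay_hit_prob_in_q,
              background_hit_prob = background_hit_prob,
              n_clusters_planted = as.integer(n_clusters_planted),
              within_block_bit_prob = within_block_bit_prob,
              between_block_bit_prob = between_block_bit_prob,
              fp_bits = as.integer(fp_bits),
              planted_term = planted_term,
              planted_term_annotation_prob_in_cluster =
                planted_term_annotation_prob_in_cluster,
              background_annotation_prob = background_annotation_prob,
              seed = as.integer(seed))
  for (p in c("planted_assay_hit_prob_in_q", "background_hit_prob",
              "within_block_bit_prob", "between_block_bit_prob",
              "planted_term_annotation_prob_in_cluster",
              "background_annotation_prob")) {
    assert_scalar_number(cfg[[p]], p, 0, 1)
  }
  if (cfg$q_size > cfg$n_compounds || cfg$assay_size > cfg$n_compounds) {
    abort("q_size and assay_size cannot exceed n_compounds",
          class = "compset_config_error")
  }
  if (cfg$q_size < cfg$n_clusters_planted) {
    abort("q_size must be at least n_clusters_planted",
          class = "compset_config_error")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic compound universe with planted enrichments
#'
#' Produces, deterministically for a given config, all inputs the analytic
#' modules consume: block-structured fingerprints; flag-based assays with
#' one planted hit-enriched assay; disease and target interaction tables
#' with a term planted on one fingerprint block's query compounds; the
#' query set; and a truth record carrying the planted assay id, planted
#' block labels, and the analytic expected enrichment score
#' `log2(p_planted / p_background)` (the expectation of
#' `log2((E[a]/E[c]) / (q_n/qc_n))` under the design).
#'
#' @param config A [synth_config()].
#' @return A `synth_universe` list: `config`, `registry`, `query`,
#'   `fingerprints` (matrix), `assays` (measurement tibble), `hitsets`
#'   (via [assign_hits()] semantics: flags), `disease_tree`, `target_tree`
#'   (`ontology_tree`s), `disease_interactions`, `target_interactions`,
#'   `truth` (list: `planted_assay`, `expected_es`, `labels` tibble,
#'   `planted_term`, `planted_block`).
#' @export
generate_universe <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  ids <- sprintf("SYN%05d", seq_len(cfg$n_compounds))
  query_ids <- ids[seq_len(cfg$q_size)]
  blocks <- rep(seq_len(cfg$n_clusters_planted),
                length.out = cfg$n_compounds)

  # fingerprints: block-characteristic bit segments
  fp <- with_seed(derive_seed(cfg$seed, "fingerprints"), {
    seg <- split(seq_len(cfg$fp_bits),
                 rep(seq_len(cfg$n_clusters_planted),
                     length.out = cfg$fp_bits))
    m <- matrix(0L, cfg$n_compounds, cfg$fp_bits)
    for (b in seq_len(cfg$n_clusters_planted)) {
      rows <- which(blocks == b)
      own <- seg[[b]]
      m[rows, own] <- rbinom(length(rows) * length(own), 1L,
                             cfg$within_block_bit_prob)
      other <- setdiff(seq_len(cfg$fp_bits), own)
      m[rows, other] <- rbinom(length(rows) * length(other), 1L,
                               cfg$between_block_bit_prob)
    }
    rownames(m) <- ids
    m
  })

  # assays: flag-based; assay 1 is the planted hit-enriched assay
  assays <- with_seed(derive_seed(cfg$seed, "assays"), {
    purrr::map(seq_len(cfg$n_assays), function(i) {
      aid <- sprintf("ASSAY%02d", i)
      # every assay screens a library containing the query compounds (the
      # screening-hit setting); only the planted assay enriches hits in Q
      tested <- c(query_ids,
                  sample(setdiff(ids, query_ids),
                         cfg$assay_size - cfg$q_size))
      p <- if (i == 1L) {
        ifelse(tested %in% query_ids,
               cfg$planted_assay_hit_prob_in_q, cfg$background_hit_prob)
      } else {
        rep(cfg$background_hit_prob, cfg$assay_size)
      }
      active <- rbinom(length(tested), 1L, p) == 1L
      tibble(assay_id = aid, merge_key = tested,
             flag = ifelse(active, "active", "inactive"),
             direction = "higher_is_active",
             title = if (i == 1L) "planted phenotypic screen" else
               sprintf("background assay %02d", i),
             target_gene = if (i == 1L) "PLANTED1" else NA_character_)
    }) |> bind_rows()
  })

  # annotations: disease + target trees, planted on block 2's query members
  planted_block <- min(2L, cfg$n_clusters_planted)
  ann <- with_seed(derive_seed(cfg$seed, "annotations"), {
    make_annotations(cfg, ids, query_ids, blocks, planted_block)
  })

  registry <- tibble(merge_key = ids, smiles = NA_character_,
                     n_members = 1L,
                     members = purrr::map(ids, identity))
  truth <- list(
    planted_assay = "ASSAY01",
    expected_es = if (cfg$background_hit_prob > 0) {
      log2(cfg$planted_assay_hit_prob_in_q / cfg$background_hit_prob)
    } else Inf,
    labels = tibble(merge_key = query_ids,
                    block = blocks[seq_len(cfg$q_size)]),
    planted_term = cfg$planted_term,
    planted_block = planted_block
  )
  structure(list(config = cfg, registry = registry,
                 query = compound_set(query_ids, name = "synthetic-query"),
                 fingerprints = fp, assays = assays,
                 disease_tree = ann$disease_tree,
                 target_tree = ann$target_tree,
                 disease_interactions = ann$disease_interactions,
                 target_interactions = ann$target_interactions,
                 truth = truth),
            class = "synth_universe")
}

# Disease and target trees with one planted term; interactions drawn for
# planted-block query compounds at the planted rate and for everyone at the
# background rate.
make_annotations <- function(cfg, ids, query_ids, blocks, planted_block) {
  dis_terms <- unique(c(cfg$planted_term, "cancer", "metabolic disease",
                        "cardiovascular disease", "nervous system disease"))
  dis_tree <- ontology_tree(
    child = dis_terms, parent = rep("disease", length(dis_terms)),
    term = rep(dis_terms, each = 3L),
    entity_id = paste0("D_", rep(seq_along(dis_terms), each = 3L), "_",
                       rep(1:3, length(dis_terms))),
    kind = "disease_ontology")
  tgt_fams <- c("ion channel", "kinase", "gpcr", "protease")
  tgt_tree <- ontology_tree(
    child = tgt_fams, parent = rep("protein", length(tgt_fams)),
    term = rep(tgt_fams, each = 3L),
    entity_id = paste0("T_", rep(seq_along(tgt_fams), each = 3L), "_",
                       rep(1:3, length(tgt_fams))),
    kind = "protein_family")

  draw_edges <- function(tree, planted_term_name) {
    te <- tree$term_entities
    planted_entities <- te$entity_id[te$term == planted_term_name]
    in_cluster <- query_ids[blocks[seq_along(query_ids)] == planted_block]
    planted_on <- in_cluster[
      rbinom(length(in_cluster), 1L,
             cfg$planted_term_annotation_prob_in_cluster) == 1L]
    planted <- tibble(
      merge_key = planted_on,
      entity_id = if (length(planted_on)) {
        sample(planted_entities, length(planted_on), replace = TRUE)
      } else character())
    bg_on <- ids[rbinom(length(ids), 1L, cfg$background_annotation_prob) == 1L]
    bg <- tibble(
      merge_key = bg_on,
      entity_id = if (length(bg_on)) {
        sample(te$entity_id, length(bg_on), replace = TRUE)
      } else character())
    bind_rows(planted, bg) |>
      distinct() |>
      mutate(entity_kind = if (tree$kind == "protein_family") "target"
             else "disease")
  }
  list(disease_tree = dis_tree, target_tree = tgt_tree,
       disease_interactions = draw_edges(dis_tree, cfg$planted_term),
       target_interactions = draw_edges(tgt_tree, "ion channel"))
}

#' Write a synthetic universe to plain-text files
#'
#' Writes `registry.tsv`, `assays.tsv`, `query.txt`,
#' `interactions_disease.tsv`, `interactions_target.tsv`,
#' `disease_tree.tsv`, `disease_annot.tsv`, `target_tree.tsv`,
#' `target_annot.tsv`, `labels.tsv`, and `truth.tsv` (columns
#' `planted_assay`, `expected_es`, `planted_term`, `planted_block`).
#' Regeneration from an identical config is byte-identical.
#'
#' @param universe A `synth_universe`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synth_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  w(select(universe$registry, "merge_key", canonical_smiles = "smiles",
           "n_members"), "registry.tsv")
  w(mutate(universe$assays, compound_id = .data$merge_key,
           .keep = "unused", .before = 1) |>
      select("assay_id", "compound_id", "flag", "direction", "title",
             "target_gene"),
    "assays.tsv")
  writeLines(as.character(universe$query), file.path(dir, "query.txt"))
  for (kind in c("disease", "target")) {
    ints <- universe[[paste0(kind, "_interactions")]]
    w(select(ints, compound_id = "merge_key", "entity_id", "entity_kind"),
      sprintf("interactions_%s.tsv", kind))
    tree <- universe[[paste0(kind, "_tree")]]
    w(select(tree$parents, child_term = "child", parent_term = "parent"),
      sprintf("%s_tree.tsv", kind))
    w(tree$term_entities, sprintf("%s_annot.tsv", kind))
  }
  w(universe$truth$labels, "labels.tsv")
  w(tibble(planted_assay = universe$truth$planted_assay,
           expected_es = universe$truth$expected_es,
           planted_term = universe$truth$planted_term,
           planted_block = universe$truth$planted_block),
    "truth.tsv")
  invisible(dir)
}

#' Generate isotope / protonation variants of a structure
#'
#' Produces up to `n` syntactically distinct SMILES that all normalize to
#' the base structure's merge key: the base itself, a carboxylate
#' deprotonation where present, protonated-amine forms, a leading
#' deuterium label, and isotope-labelled bracket forms (single atoms, then
#' pairs, then triples). Every candidate is validated by re-standardizing
#' and comparing merge keys, so chemically illegal edits are dropped. If
#' the structure admits fewer than `n` legal variants, the maximum is
#' returned with a warning.
#'
#' @param base_smiles A parseable SMILES.
#' @param n Number of variants requested.
#' @return Character vector of SMILES (first element is the normalized
#'   base), with attribute `merge_key`.
#' @export
make_variants <- function(base_smiles, n) {
  base <- normalize_structure(base_smiles)
  can <- base$smiles
  key <- base$merge_key

  # Candidates are validated in batches: normalize in memory, then compute
  # all InChIKeys in a single Open Babel run and keep those matching the
  # base key (chemically illegal hydrogen counts change the formula and
  # self-reject).
  validate <- function(cands) {
    if (length(cands) == 0L) return(character())
    norm <- purrr::map_chr(cands, function(s) {
      tryCatch(normalize_smiles(s), error = function(e) NA_character_)
    })
    okn <- which(!is.na(norm))
    keys <- rep(NA_character_, length(cands))
    if (length(okn)) {
      keys[okn] <- tryCatch(inchikey_batch(norm[okn]), error = function(e) {
        purrr::map_chr(norm[okn], function(s) {
          tryCatch(inchikey_batch(s), error = function(e2) NA_character_)
        })
      })
    }
    cands[!is.na(keys) & keys == key]
  }
  out <- can
  add <- function(vals) {
    for (v in vals) {
      if (length(out) >= n) break
      if (!v %in% out) out <<- c(out, v)
    }
  }

  # deprotonated carboxylate first, so acids yield [neutral, anion, ...]
  acids <- unique(c(sub("C(=O)O", "C(=O)[O-]", can, fixed = TRUE),
                    sub("OC(=O)", "[O-]C(=O)", can, fixed = TRUE)))
  add(validate(setdiff(acids, can)))

  atoms <- locate_atoms(can)
  masses <- list(C = c(13L, 14L), c = c(13L, 14L), N = 15L, n = 15L,
                 O = c(17L, 18L), S = c(33L, 34L))
  # enumerate single isotope labels with hydrogen-count guesses
  meta <- list()
  for (i in seq_len(nrow(atoms))) {
    sym <- atoms$sym[i]
    for (m in masses[[sym]] %||% integer()) {
      for (h in 0:4) {
        lab <- sub("H0", "", sprintf("[%d%sH%d]", m, sym, h), fixed = TRUE)
        meta <- c(meta, list(list(pos = atoms$pos[i], len = atoms$len[i],
                                  text = lab, tag = paste(i, m))))
      }
    }
  }
  cands <- purrr::map_chr(meta, function(e) apply_edit_list(can, list(e)))
  valid <- validate(cands)
  # keep the first valid hydrogen guess per (atom, mass)
  singles <- list(); seen <- character(); single_smiles <- character()
  for (j in seq_along(cands)) {
    if (cands[j] %in% valid && !meta[[j]]$tag %in% seen) {
      seen <- c(seen, meta[[j]]$tag)
      singles <- c(singles, list(meta[[j]]))
      single_smiles <- c(single_smiles, cands[j])
    }
  }
  add(single_smiles)

  if (length(out) < n) add(validate(paste0("[2H]", can)))
  if (length(out) < n) {
    nrows <- atoms[atoms$sym == "N", , drop = FALSE]
    am <- purrr::map(seq_len(nrow(nrows)), function(i) {
      purrr::map_chr(1:3, function(h) {
        apply_edits(can, nrows[i, , drop = FALSE], sprintf("[NH%d+]", h))
      })
    })
    add(validate(unlist(am)))
  }

  # pairs and triples of validated single labels at distinct positions
  for (size in 2:3) {
    if (length(out) >= n || length(singles) < size) break
    combos <- utils::combn(seq_along(singles), size, simplify = FALSE)
    combo_smiles <- purrr::map_chr(combos, function(cb) {
      ed <- singles[cb]
      if (anyDuplicated(purrr::map_dbl(ed, "pos"))) return(NA_character_)
      apply_edit_list(can, ed)
    })
    combo_smiles <- combo_smiles[!is.na(combo_smiles)]
    # multi-edits of individually validated labels; cap the batch at what
    # is still needed (with headroom for the odd rejection)
    need <- (n - length(out)) * 2L + 10L
    add(validate(head(combo_smiles, need)))
  }
  if (length(out) < n) {
    warn(sprintf("structure admits only %d legal variants (requested %d)",
                 length(out), n))
  }
  structure(out, merge_key = key)
}

# Atom token positions outside brackets in a SMILES string.
locate_atoms <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  res <- list()
  depth <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (depth == 0L && ch %in% c("C", "N", "O", "S", "P", "F", "B", "I",
                                 "c", "n", "o", "s", "p")) {
      len <- 1L
      if (ch %in% c("C", "B") && i < length(chars) &&
          chars[i + 1L] %in% c("l", "r")) {
        len <- 2L  # Cl / Br, not labelable here
        i <- i + len
        next
      }
      res <- c(res, list(tibble(pos = i, len = len, sym = ch)))
    }
    i <- i + 1L
  }
  if (length(res) == 0L) {
    return(tibble(pos = integer(), len = integer(), sym = character()))
  }
  bind_rows(res)
}

apply_edits <- function(smiles, atom_row, replacement) {
  paste0(substr(smiles, 1L, atom_row$pos - 1L), replacement,
         substr(smiles, atom_row$pos + atom_row$len, nchar(smiles)))
}

# Apply several single-token edits right-to-left so positions stay valid.
apply_edit_list <- function(smiles, edits) {
  ord <- order(purrr::map_dbl(edits, "pos"), decreasing = TRUE)
  for (e in edits[ord]) {
    smiles <- paste0(substr(smiles, 1L, e$pos - 1L), e$text,
                     substr(smiles, e$pos + e$len, nchar(smiles)))
  }
  smiles
}
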
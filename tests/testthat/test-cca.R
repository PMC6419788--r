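block_fps <- function(n_per_block, blocks = 3, bits = 120, within = 1,
                      between = 0, seed = NULL) {
  make <- function() {
    seg <- split(seq_len(bits), rep(seq_len(blocks), length.out = bits))
    m <- matrix(0L, n_per_block * blocks, bits)
    lab <- rep(seq_len(blocks), each = n_per_block)
    for (b in seq_len(blocks)) {
      rows <- which(lab == b)
      m[rows, seg[[b]]] <- rbinom(length(rows) * length(seg[[b]]), 1, within)
      m[rows, -seg[[b]]] <- rbinom(length(rows) * (bits - length(seg[[b]])),
                                   1, between)
    }
    rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
    list(fps = m, labels = lab)
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

test_that("k-means recovers well-separated groups exactly", {
  sep <- block_fps(10, blocks = 2, within = 1, between = 0, seed = 1)
  cl <- cluster_compounds(sep$fps, k = 2, seed = 5)
  expect_equal(adjusted_rand_index(cl$cluster, sep$labels), 1.0)
  # k = 1 puts everything together
  one <- cluster_compounds(sep$fps, k = 1, seed = 5)
  expect_equal(unique(one$cluster), 1L)
  expect_error(cluster_compounds(sep$fps, k = 25, seed = 1),
               class = "compset_parameter_error")
  expect_error(cluster_compounds(sep$fps, k = 0, seed = 1),
               class = "compset_parameter_error")
})

test_that("noisy planted blocks are recovered and partitions are valid", {
  noisy <- block_fps(20, blocks = 3, bits = 256, within = 0.9,
                     between = 0.1, seed = 42)
  cl <- cluster_compounds(noisy$fps, k = 3, seed = 7)
  expect_equal(adjusted_rand_index(cl$cluster, noisy$labels), 1.0)
  g <- glance(cl)
  expect_equal(g$k, 3L)
  expect_gt(g$mean_silhouette, 0)
  # partition property on random inputs
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(6:20, 1); k <- sample(1:4, 1)
      fps <- matrix(rbinom(n * 32, 1, 0.4), n, 32,
                    dimnames = list(paste0("x", 1:n), NULL))
      cc <- cluster_compounds(fps, k = min(k, n), seed = i)
      expect_setequal(cc$merge_key, rownames(fps))
      expect_equal(anyDuplicated(cc$merge_key), 0L)
      expect_lte(length(unique(cc$cluster)), min(k, n))
    }
  })
})

test_that("clustering is deterministic in the seed and equivariant to bit permutation", {
  noisy <- block_fps(15, blocks = 3, bits = 128, within = 0.85,
                     between = 0.15, seed = 3)
  c1 <- cluster_compounds(noisy$fps, k = 3, seed = 11)
  c2 <- cluster_compounds(noisy$fps, k = 3, seed = 11)
  expect_identical(c1$cluster, c2$cluster)
  perm <- withr::with_seed(4, sample(ncol(noisy$fps)))
  c3 <- cluster_compounds(noisy$fps[, perm], k = 3, seed = 11)
  expect_identical(c1$cluster, c3$cluster)
})

test_that("cluster enrichment agrees with direct 2x2 arithmetic", {
  # constructed case: 10-compound cluster, each with one annotation under T
  tree <- ontology_tree(child = c("T", "U"), parent = c("root", "root"),
                        term = c("T", "U"), entity_id = c("tT", "tU"))
  cl_ids <- sprintf("q%02d", 1:10)
  bg_ids <- sprintf("b%03d", 1:990)
  ints <- dplyr::bind_rows(
    tibble::tibble(merge_key = cl_ids, entity_id = "tT", entity_kind = "disease"),
    tibble::tibble(merge_key = bg_ids[1:40], entity_id = "tT",
                   entity_kind = "disease"),
    tibble::tibble(merge_key = bg_ids[41:990], entity_id = "tU",
                   entity_kind = "disease"))
  idx <- build_term_index(tree, ints)
  res <- cc_enrichment(cl_ids, idx, c(cl_ids, bg_ids))
  row <- res[res$term == "T", ]
  expect_equal(row$a, 10L); expect_equal(row$b, 0L)
  expect_equal(row$c, 40L); expect_equal(row$d, 950L)
  expect_equal(row$es, log2((10.5 / 40.5) / (0.5 / 950.5)))
  expect_equal(row$es, 8.95, tolerance = 1e-3)
  expect_equal(row$p, fisher_p(10, 0, 40, 950))
  # randomized oracle equivalence
  withr::with_seed(31, {
    for (i in 1:50) {
      nq <- sample(3:12, 1); nb <- sample(50:200, 1)
      q_ids <- paste0("q", 1:nq); b_ids <- paste0("b", 1:nb)
      ints_r <- tibble::tibble(
        merge_key = sample(c(q_ids, b_ids), 4 * nq, replace = TRUE),
        entity_id = sample(c("tT", "tU"), 4 * nq, replace = TRUE),
        entity_kind = "disease") |> dplyr::distinct()
      idx_r <- build_term_index(tree, ints_r)
      got <- cc_enrichment(q_ids, idx_r, c(q_ids, b_ids))
      rT <- got[got$term == "T", ]
      a <- sum(ints_r$merge_key %in% q_ids & ints_r$entity_id == "tT")
      b <- sum(ints_r$merge_key %in% q_ids) - a
      cc <- sum(!ints_r$merge_key %in% q_ids & ints_r$entity_id == "tT")
      d <- sum(!ints_r$merge_key %in% q_ids) - cc
      expect_equal(rT$es, oracle_es_odds(a, b, cc, d), tolerance = 1e-12)
      expect_equal(rT$p, oracle_fisher_enum(a, b, cc, d), tolerance = 1e-9)
    }
  })
})

test_that("the CC-network links planted clusters to their class terms", {
  u <- generate_universe(synth_config())
  idx <- build_term_index(u$disease_tree, u$disease_interactions)
  fps <- u$fingerprints[as.character(u$query), ]
  cl <- cluster_compounds(fps, k = 3, seed = 13)
  net <- build_cc_network(cl, idx, u$registry$merge_key)
  expect_s3_class(net, "cc_network")
  # the planted block's cluster carries an edge to the planted term
  planted_members <- u$truth$labels$merge_key[
    u$truth$labels$block == u$truth$planted_block]
  planted_cluster <- unique(cl$cluster[cl$merge_key %in% planted_members])
  expect_length(planted_cluster, 1L)
  hit <- net$edges[net$edges$class_term == u$truth$planted_term, ]
  expect_true(planted_cluster %in% hit$cluster)
  # impossible thresholds remove all edges
  none <- build_cc_network(cl, idx, u$registry$merge_key,
                           edge_threshold = Inf, q_threshold = 0)
  expect_equal(nrow(none$edges), 0L)
  expect_s3_class(autoplot(net), "ggplot")
})

test_that("clusters with identical annotation profiles get identical edge sets", {
  tree <- ontology_tree(child = "T", parent = "root",
                        term = "T", entity_id = "tT")
  ids <- sprintf("c%02d", 1:20)
  # two 10-compound clusters, same annotation pattern (first 5 of each)
  ints <- tibble::tibble(merge_key = c(ids[1:5], ids[11:15]),
                         entity_id = "tT", entity_kind = "disease")
  idx <- build_term_index(tree, ints)
  cl <- structure(tibble::tibble(merge_key = ids,
                                 cluster = rep(1:2, each = 10)),
                  class = c("compset_clusters", class(tibble::tibble())))
  net <- build_cc_network(cl, idx, c(ids, sprintf("b%02d", 1:30)),
                          edge_threshold = -Inf, q_threshold = 1)
  e1 <- sort(net$edges$class_term[net$edges$cluster == 1])
  e2 <- sort(net$edges$class_term[net$edges$cluster == 2])
  expect_equal(e1, e2)
})

test_that("identical seeds give byte-identical network exports", {
  u <- generate_universe(synth_config())
  idx <- build_term_index(u$disease_tree, u$disease_interactions)
  fps <- u$fingerprints[as.character(u$query), ]
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cl <- cluster_compounds(fps, k = 3, seed = 13)
    export_cc_network(build_cc_network(cl, idx, u$registry$merge_key), d)
  }
  for (f in c("ccnetwork.graphml", "cc_edges.tsv", "cc_members.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e6),
                     readBin(file.path(d2, f), "raw", n = 1e6),
                     label = f)
  }
})
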
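test_that("hit-enrichment LLR reproduces worked values", {
  expect_equal(es_hea(5, 45, 100, 900), 0.0)
  expect_equal(es_hea(4, 9, 10, 90), 2.0)
  # large sparse assay: log2((12/140) / (40/390180))
  expect_equal(es_hea(12, 140, 40, 390180), log2((12 / 140) / (40 / 390180)))
  expect_equal(es_hea(12, 140, 40, 390180), 9.71, tolerance = 5e-4)
  expect_error(es_hea(1, 1, 0, 10),
               class = "compset_undefined_background_error")
})

test_that("odds-ratio ES reproduces worked values including the zero-cell rule", {
  expect_equal(es_odds(10, 10, 10, 10), 0.0)
  expect_equal(es_odds(8, 2, 2, 8), 4.0)
  expect_equal(es_odds(2, 38, 0, 100000),
               log2((2.5 / 0.5) / (38.5 / 100000.5)))
  expect_equal(es_odds(2, 38, 0, 100000), 13.66, tolerance = 5e-4)
})

test_that("enrichment scores match brute-force arithmetic on random tables", {
  tabs <- random_tables(1000)
  got_odds <- es_odds(tabs$a, tabs$b, tabs$c, tabs$d)
  got_hea <- es_hea(tabs$a, tabs$c, tabs$a + tabs$b + 1, tabs$c + tabs$d + 1)
  expect_equal(got_odds,
               mapply(oracle_es_odds, tabs$a, tabs$b, tabs$c, tabs$d),
               tolerance = 1e-12)
  expect_equal(got_hea,
               mapply(oracle_es_hea, tabs$a, tabs$c,
                      tabs$a + tabs$b + 1, tabs$c + tabs$d + 1),
               tolerance = 1e-12)
})

test_that("fisher p-values are exact hypergeometric tails", {
  expect_equal(fisher_p(5, 0, 0, 15), 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(fisher_p(3, 2, 2, 13), 1126 / 15504, tolerance = 1e-12)
  expect_equal(fisher_p(0, 5, 5, 10), 1.0)
  # exhaustive check against explicit enumeration for small universes
  for (N in c(5, 12, 20)) {
    g <- expand.grid(m = 0:N, k = 0:N)
    tab <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      a <- max(0, g$k[i] + g$m[i] - N):min(g$k[i], g$m[i])
      data.frame(a = a, b = g$k[i] - a, c = g$m[i] - a,
                 d = N - g$m[i] - g$k[i] + a)
    }))
    expect_equal(fisher_p(tab$a, tab$b, tab$c, tab$d),
                 mapply(oracle_fisher_enum, tab$a, tab$b, tab$c, tab$d),
                 tolerance = 1e-12, label = sprintf("N=%d", N))
  }
})

test_that("BH adjustment matches step-up arithmetic and is well-behaved", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.05, 0.9)),
               c(0.02, 0.2 / 3, 0.2 / 3, 0.9), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 0)), class = "compset_value_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "compset_value_error")
  withr::with_seed(21, {
    for (i in 1:25) {
      p <- runif(sample(3:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15) && all(q <= 1))
      # step-up monotonicity: adjusted values are non-decreasing in p-rank
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("hit-enriched-assay analysis ranks a planted assay first", {
  u <- generate_universe(synth_config())
  hs <- assign_hits(u$assays)
  hea <- run_hea(u$query, hs)
  expect_s3_class(hea, "compset_hea")
  expect_equal(hea$assay_id[1], u$truth$planted_assay)
  expect_true(hea$flagged[1])
  expect_lt(hea$q[1], 0.001)
  expect_equal(hea$rank, seq_len(nrow(hea)))
  # glance/tidy/autoplot interface
  g <- glance(hea)
  expect_equal(g$top_assay, u$truth$planted_assay)
  expect_s3_class(autoplot(hea), "ggplot")
})

test_that("queries disjoint from all assays yield an empty skipped report", {
  hs <- assign_hits(make_flag_assay(100, 5))
  out <- run_hea(compound_set("ZZZ999"), hs)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_error(run_hea(character(), hs), class = "compset_empty_set_error")
})

test_that("an assay with background-rate hits in the query scores near zero", {
  # Q = 10 of 100 tested; hits split proportionally (2 in Q, 18 outside)
  a <- tibble::tibble(
    assay_id = "NULL1",
    merge_key = sprintf("c%03d", 1:100),
    flag = c(rep("active", 2), rep("inactive", 8),
             rep("active", 18), rep("inactive", 72)),
    direction = "higher_is_active")
  hea <- run_hea(compound_set(sprintf("c%03d", 1:10)), assign_hits(a))
  expect_equal(hea$es, 0.0)
  expect_gt(hea$q, 0.5)  # a proportional split carries no evidence
})

test_that("tree enrichment scores planted terms and respects aggregation", {
  u <- generate_universe(synth_config())
  idx <- build_term_index(u$disease_tree, u$disease_interactions)
  tet <- run_tree_enrichment(u$query, idx, u$registry$merge_key)
  expect_s3_class(tet, "compset_tree_enrichment")
  expect_equal(tet$term[1], u$truth$planted_term)
  expect_lt(tet$q[1], 0.01)
  # child counts never exceed the parent's (root aggregates everything)
  root <- tet[tet$term == "disease", ]
  for (t in setdiff(tet$term, "disease")) {
    expect_lte(tet$a[tet$term == t], root$a)
    expect_lte(tet$a[tet$term == t] + tet$c[tet$term == t], root$a + root$c)
  }
  expect_error(run_tree_enrichment(u$query, idx, character()),
               class = "compset_value_error")
})

test_that("tree enrichment matches hand arithmetic on a tiny planted case", {
  # one term annotated to an entity hit by 2 query compounds and nobody else
  tree <- ontology_tree(child = "ANO-like", parent = "root",
                        term = "ANO-like", entity_id = "t1")
  ints <- tibble::tibble(
    merge_key = c("q1", "q2", sprintf("b%02d", 1:20)),
    entity_id = c("t1", "t1", rep("other", 20)),
    entity_kind = "target")
  # "other" is outside the tree: only t1 pairs are under ANO-like
  idx <- build_term_index(tree, ints)
  res <- run_tree_enrichment(compound_set(c("q1", "q2", "q3")), idx,
                             c("q1", "q2", "q3", sprintf("b%02d", 1:20)))
  row <- res[res$term == "ANO-like", ]
  expect_equal(row$a, 2L); expect_equal(row$c, 0L)
  expect_equal(row$es, es_odds(2, 0, 0, 20))
  expect_equal(row$p, fisher_p(2, 0, 0, 20))
  # proportional annotation scores zero
  ints2 <- tibble::tibble(merge_key = c("q1", "b01", "q2", "b02"),
                          entity_id = c("t1", "t1", "o", "o"),
                          entity_kind = "target")
  tree2 <- ontology_tree(child = c("X", "Y"), parent = c("root", "root"),
                         term = c("X", "Y"), entity_id = c("t1", "o"))
  res2 <- run_tree_enrichment(compound_set(c("q1", "q2")),
                              build_term_index(tree2, ints2),
                              c("q1", "q2", "b01", "b02"))
  expect_equal(res2$es[res2$term == "X"], 0.0)
})
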
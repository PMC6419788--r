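test_that("ethanol descriptors match reference values", {
  reg <- merge_registry(standardize(c(eth = "CCO")))
  p <- compute_properties(reg)
  expect_equal(p$mw, 46.07, tolerance = 0.01 / 46.07)
  expect_equal(p$tpsa, 20.23)
  expect_equal(p$hbd, 1L)
  expect_equal(p$hba, 1L)
  expect_equal(p$lipinski_violations, 0L)
  expect_gte(p$qed, 0); expect_lte(p$qed, 1)
})

test_that("lipinski counting matches the four-predicate definition", {
  cases <- tibble::tribble(
    ~mw, ~logp, ~hbd, ~hba, ~violations, ~pass,
    180.2, 1.2, 1, 4, 0L, TRUE,
    600, 6, 6, 11, 4L, FALSE,
    500, 5, 5, 10, 0L, TRUE,   # boundary values are compliant
    501, 1, 1, 1, 1L, TRUE     # one violation still passes
  )
  out <- lipinski(cases)
  expect_equal(out$lipinski_violations, cases$violations)
  expect_equal(out$pass_lipinski, cases$pass)
})

test_that("lipinski agrees with brute-force predicates on random vectors", {
  props <- withr::with_seed(99, tibble::tibble(
    mw = runif(1000, 50, 900), logp = runif(1000, -3, 9),
    hbd = sample(0:9, 1000, replace = TRUE),
    hba = sample(0:14, 1000, replace = TRUE)))
  got <- lipinski(props)$lipinski_violations
  want <- vapply(seq_len(1000), function(i) {
    sum(c(props$mw[i] > 500, props$logp[i] > 5,
          props$hbd[i] > 5, props$hba[i] > 10))
  }, integer(1))
  expect_equal(got, want)
})

test_that("qed desirability machinery reproduces the reference toolkit", {
  # descriptor vectors and expected scores computed with RDKit 2024.09.2
  # (QED.properties / QED.qed / QED.weights_none)
  cases <- list(
    list(d = data.frame(MW = 46.069, ALOGP = -0.0014000000000000123,
                        HBA = 1, HBD = 1, PSA = 20.23, ROTB = 0, AROM = 0,
                        ALERTS = 0),
         mean = 0.40680796565539457, unit = 0.391801981537285),
    list(d = data.frame(MW = 180.15899999999996, ALOGP = 1.3101, HBA = 4,
                        HBD = 1, PSA = 63.60000000000001, ROTB = 2,
                        AROM = 1, ALERTS = 2),
         mean = 0.5501217966938848, unit = 0.6734029196324833),
    list(d = data.frame(MW = 493.6150000000002, ALOGP = 4.590320000000004,
                        HBA = 7, HBD = 2, PSA = 86.28000000000002, ROTB = 7,
                        AROM = 4, ALERTS = 0),
         mean = 0.38941616262964607, unit = 0.3772245986773283)
  )
  for (cs in cases) {
    expect_equal(qed_from_descriptors(cs$d, weights = "mean"), cs$mean,
                 tolerance = 1e-6)
    expect_equal(qed_from_descriptors(cs$d, weights = "unit"), cs$unit,
                 tolerance = 1e-6)
  }
})

test_that("qed stays in [0,1] over a descriptor grid and rejects bad weights", {
  grid <- withr::with_seed(3, tibble::tibble(
    MW = runif(200, 20, 1200), ALOGP = runif(200, -5, 10),
    HBA = sample(0:15, 200, TRUE), HBD = sample(0:8, 200, TRUE),
    PSA = runif(200, 0, 300), ROTB = sample(0:20, 200, TRUE),
    AROM = sample(0:6, 200, TRUE), ALERTS = sample(0:5, 200, TRUE)))
  q <- qed_from_descriptors(grid)
  expect_true(all(q >= 0 & q <= 1))
  expect_error(qed_from_descriptors(grid[1, -1]), class = "compset_value_error")
  expect_error(qed_from_descriptors(grid[1, ], weights = setNames(rep(0, 8),
               names(grid))), class = "compset_value_error")
})

test_that("qed_score computes scores from structures", {
  q <- qed_score(c(eth = "CCO", asp = "CC(=O)Oc1ccccc1C(=O)O"))
  expect_length(q, 2L)
  expect_true(all(q > 0 & q < 1))
  # aspirin is more drug-like than ethanol under unit weights
  expect_gt(q[2], q[1])
})

test_that("fingerprints are deterministic, foldable, and discriminating", {
  reg <- merge_registry(standardize(c(
    eth = "CCO", asp = "CC(=O)Oc1ccccc1C(=O)O", caf = "Cn1cnc2c1c(=O)n(C)c(=O)n2C")))
  f1 <- fingerprint_compounds(reg)
  f2 <- fingerprint_compounds(reg)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 1024L)
  expect_true(all(f1 %in% c(0L, 1L)))
  eth <- f1[reg$merge_key[reg$smiles == "CCO"], ]
  asp <- f1[reg$merge_key[reg$smiles != "CCO"][1], ]
  expect_equal(tanimoto(eth, eth), 1.0)
  expect_lt(tanimoto(eth, asp), 1.0)
  f256 <- fingerprint_compounds(reg, n_bits = 256)
  expect_equal(ncol(f256), 256L)
  # folding preserves every set bit (OR semantics)
  expect_true(all(rowSums(f256) <= rowSums(f1)))
  expect_true(all(rowSums(f256) > 0))
  expect_error(fingerprint_compounds(reg, n_bits = 100),
               class = "compset_value_error")
  expect_error(fingerprint_compounds(reg, n_bits = 2048),
               class = "compset_value_error")
})

test_that("tanimoto follows its definition and is a bounded symmetric measure", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1.0)  # all-zero convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), class = "compset_dimension_error")
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
      t1 <- tanimoto(a, b)
      expect_equal(t1, tanimoto(b, a))
      expect_gte(t1, 0); expect_lte(t1, 1)
    }
  })
})

test_that("similarity search ranks, thresholds, and breaks ties deterministically", {
  # constructed fingerprints with known similarities to the query
  q <- c(rep(1, 4), rep(0, 6))
  fps <- rbind(
    A = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),   # 4/5  = 0.8
    B = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),   # 2/4  = 0.5
    C = c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0))   # 1/5  = 0.2
  res <- similarity_search(fps, q, threshold = 0.5)
  expect_equal(res$merge_key, c("A", "B"))
  expect_equal(res$similarity, c(0.8, 0.5))
  expect_equal(nrow(similarity_search(fps, q, threshold = 0)), 3L)
  # exact duplicate ranks first at threshold 1
  fps2 <- rbind(fps, D = q)
  res2 <- similarity_search(fps2, q, threshold = 1)
  expect_equal(res2$merge_key, "D")
  expect_equal(res2$similarity, 1.0)
  # empty registry
  expect_equal(nrow(similarity_search(fps[0, , drop = FALSE], q)), 0L)
  # ties broken lexicographically
  fps3 <- rbind(Z = q, A = q)
  expect_equal(similarity_search(fps3, q, 0)$merge_key, c("A", "Z"))
})
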
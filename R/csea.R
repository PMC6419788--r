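#' Enrichment score for hit-enriched assays (log-likelihood ratio)
#'
#' `ES = log2( (q_hits / qc_hits) / (q_n / qc_n) )`: the hit odds of the
#' query set against the hit odds implied by its share of the tested
#' universe, in bits. When either hit count is zero, 0.5 is added to both
#' hit counts first (Haldane-Anscombe continuity) so the score stays
#' finite.
#'
#' @param q_hits,qc_hits Hit counts inside and outside the query set.
#' @param q_n,qc_n Tested-compound counts inside and outside the query set
#'   (both must be positive).
#' @param pseudocount Continuity correction applied to both hit counts when
#'   a zero is present.
#' @return Numeric vector of enrichment scores in bits.
#' @export
es_hea <- function(q_hits, qc_hits, q_n, qc_n, pseudocount = 0.5) {
  if (any(q_n <= 0) || any(qc_n <= 0)) {
    abort("q_n and qc_n must be positive (undefined background)",
          class = "compset_undefined_background_error")
  }
  zero <- q_hits == 0 | qc_hits == 0
  a <- q_hits + pseudocount * zero
  c_ <- qc_hits + pseudocount * zero
  log2((a / c_) / (q_n / qc_n))
}

#' Enrichment score from a 2x2 table (log2 odds ratio)
#'
#' `ES = log2( (a/c) / (b/d) )` on a contingency table; used for target /
#' disease enrichment (interaction-pair counts) and compound-cluster
#' enrichment. When any cell is zero, `pseudocount` is added to all four
#' cells first.
#'
#' @param a,b,c,d Cell counts: query-and-annotated, query-not-annotated,
#'   background-and-annotated, background-not-annotated.
#' @param pseudocount Haldane-Anscombe correction for zero cells.
#' @return Numeric vector of log2 odds ratios.
#' @export
es_odds <- function(a, b, c, d, pseudocount = 0.5) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  pc <- pseudocount * zero
  log2(((a + pc) / (c + pc)) / ((b + pc) / (d + pc)))
}

#' One-sided Fisher (hypergeometric) enrichment p-value
#'
#' Upper-tail probability `P(X >= a)` of the hypergeometric distribution
#' with the table's margins: the exact one-sided Fisher test in the
#' enrichment direction.
#'
#' @inheritParams es_odds
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
fisher_p <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values (q-values), same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]", class = "compset_value_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Create a query compound set
#'
#' @param members Character vector of merge keys.
#' @param name Set name.
#' @return A `compound_set`: character vector of unique members with a
#'   `name` attribute.
#' @export
compound_set <- function(members, name = "query") {
  members <- unique(as.character(members))
  if (length(members) == 0L) {
    abort("compound set is empty", class = "compset_empty_set_error")
  }
  structure(members, name = name, class = c("compound_set", "character"))
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set '%s': %d compounds>\n",
              attr(x, "name"), length(x)))
  invisible(x)
}

#' Hit-enriched-assay analysis (HEA)
#'
#' Scores every assay for over-representation of the query compounds among
#' its hits. By default the universe is per assay: only query compounds
#' tested in that assay count towards `Q`, and `Q^C` is the remaining
#' tested compounds — untested compounds carry no evidence. The enrichment
#' score is the log2 likelihood ratio ([es_hea()]); significance is the
#' one-sided Fisher test with BH FDR across all analyzed assays. Assays
#' sharing no tested compound with the query are skipped (counted in the
#' `n_skipped` attribute).
#'
#' @param query A `compound_set` (or character vector of merge keys).
#' @param hitsets Hit-set tibble from [assign_hits()].
#' @param report_threshold Assays with `es >= report_threshold` are flagged
#'   (the conventional reporting cut is 5 bits).
#' @param universe `"per_assay"` (default) or `"global"` (Q is the full
#'   query regardless of testing status; the global tested universe is the
#'   union of all tested compounds).
#' @return A tibble of class `compset_hea`: `rank`, `assay_id`, `title`,
#'   `target_gene`, `a`, `b`, `c`, `d` (contingency counts on compounds),
#'   `es`, `p`, `q`, `flagged`; ordered by `es` descending (ties by `p`,
#'   then assay id).
#' @export
run_hea <- function(query, hitsets, report_threshold = 5,
                    universe = c("per_assay", "global")) {
  universe <- match.arg(universe)
  if (length(query) == 0L) {
    abort("empty query set", class = "compset_empty_set_error")
  }
  q <- unique(as.character(query))
  glob <- unique(unlist(hitsets$tested, use.names = FALSE))

  rows <- purrr::pmap(
    list(hitsets$assay_id, hitsets$hits, hitsets$tested,
         hitsets$title %||% rep(NA_character_, nrow(hitsets)),
         hitsets$target_gene %||% rep(NA_character_, nrow(hitsets))),
    function(assay_id, hits, tested, title, target_gene) {
      if (universe == "per_assay") {
        q_t <- intersect(q, tested)
        if (length(q_t) == 0L) return(NULL)
        qc_t <- setdiff(tested, q_t)
        a <- length(intersect(q_t, hits))
        b <- length(q_t) - a
        c_ <- length(intersect(qc_t, hits))
        d <- length(qc_t) - c_
      } else {
        if (length(intersect(q, tested)) == 0L) return(NULL)
        a <- length(intersect(q, hits))
        b <- length(q) - a
        c_ <- length(setdiff(hits, q))
        d <- length(setdiff(glob, union(q, hits)))
      }
      if ((a + b) == 0L || (c_ + d) == 0L) return(NULL)
      tibble(assay_id = assay_id, title = title, target_gene = target_gene,
             a = a, b = b, c = c_, d = d,
             es = es_hea(a, c_, a + b, c_ + d),
             p = fisher_p(a, b, c_, d))
    })
  kept <- bind_rows(rows)
  n_skipped <- nrow(hitsets) - nrow(kept)
  if (nrow(kept) == 0L) {
    out <- tibble(rank = integer(), assay_id = character(),
                  title = character(), target_gene = character(),
                  a = integer(), b = integer(), c = integer(), d = integer(),
                  es = numeric(), p = numeric(), q = numeric(),
                  flagged = logical())
  } else {
    out <- kept |>
      mutate(q = bh_fdr(.data$p)) |>
      arrange(desc(.data$es), .data$p, .data$assay_id) |>
      mutate(rank = row_number(),
             flagged = .data$es >= report_threshold) |>
      select("rank", "assay_id", "title", "target_gene",
             "a", "b", "c", "d", "es", "p", "q", "flagged")
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "universe") <- universe
  attr(out, "query_name") <- attr(query, "name") %||% "query"
  class(out) <- c("compset_hea", class(out))
  out
}

#' Target / disease enrichment over a classification tree (TET / DET)
#'
#' For every term of the index, counts compound-entity interaction pairs in
#' a 2x2 layout — pairs involving query compounds under the term (`a`),
#' query pairs elsewhere (`b`), and the same split for the background
#' complement (`c`, `d`) — and scores the log2 odds ratio ([es_odds()]) with
#' a one-sided Fisher p-value and BH FDR across terms. Compounds outside
#' the query are assumed not to interact beyond their recorded edges, so
#' sparsely annotated backgrounds inflate scores and results warrant
#' cautious reading; pairs sharing a compound are also not independent, so
#' pair-level p-values understate that dependence.
#'
#' @param query A `compound_set` or character vector of merge keys.
#' @param index A `term_index` from [build_term_index()].
#' @param background Character vector of merge keys forming the analysis
#'   universe (must contain the query).
#' @param report_threshold Terms with `es >= report_threshold` are flagged.
#' @return A tibble of class `compset_tree_enrichment`: `rank`, `term`,
#'   `level`, `a`, `b`, `c`, `d` (pair counts), `n_query_compounds`, `es`,
#'   `p`, `q`, `flagged`.
#' @export
run_tree_enrichment <- function(query, index, background,
                                report_threshold = 5) {
  stopifnot(inherits(index, "term_index"))
  q <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!all(q %in% background)) {
    abort("background must contain every query compound",
          class = "compset_value_error")
  }
  terms <- index$terms
  if (nrow(terms) == 0L) {
    return(structure(tibble(rank = integer(), term = character(),
                            level = numeric(), a = integer(), b = integer(),
                            c = integer(), d = integer(),
                            n_query_compounds = integer(), es = numeric(),
                            p = numeric(), q = numeric(), flagged = logical()),
                     class = c("compset_tree_enrichment",
                               class(tibble()))))
  }
  ints <- index$interactions |> filter(.data$merge_key %in% background)
  in_q <- ints$merge_key %in% q
  total_q <- sum(in_q)
  total_qc <- sum(!in_q)

  counts <- purrr::map(terms$entities, function(ents) {
    under <- ints$entity_id %in% ents
    a <- sum(under & in_q)
    c_ <- sum(under & !in_q)
    nq <- length(unique(ints$merge_key[under & in_q]))
    c(a = a, b = total_q - a, c = c_, d = total_qc - c_, nq = nq)
  })
  cm <- do.call(rbind, counts)
  out <- terms |>
    select("term", "level") |>
    mutate(a = as.integer(cm[, "a"]), b = as.integer(cm[, "b"]),
           c = as.integer(cm[, "c"]), d = as.integer(cm[, "d"]),
           n_query_compounds = as.integer(cm[, "nq"]),
           es = es_odds(.data$a, .data$b, .data$c, .data$d),
           p = fisher_p(.data$a, .data$b, .data$c, .data$d),
           q = bh_fdr(.data$p)) |>
    arrange(desc(.data$es), .data$p, .data$term) |>
    mutate(rank = row_number(), flagged = .data$es >= report_threshold) |>
    select("rank", "term", "level", "a", "b", "c", "d",
           "n_query_compounds", "es", "p", "q", "flagged")
  attr(out, "kind") <- index$kind
  class(out) <- c("compset_tree_enrichment", class(out))
  out
}
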
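#' Compute physicochemical properties for a registry
#'
#' Adds Open Babel descriptors to a registry table: molecular weight (g/mol),
#' atom-contribution logP, topological polar surface area (TPSA, in square
#' Angstroms), hydrogen-bond donor and acceptor counts, Lipinski violation
#' count, and the QED drug-likeness score. logP is model-dependent: values
#' from other toolkits (e.g. Crippen logP) will differ.
#'
#' @param registry A registry tibble (needs `merge_key` and `smiles`).
#' @param qed_weights Weight preset for [qed_score()]; default `"unit"`.
#' @return The input tibble with columns `mw`, `logp`, `tpsa`, `hbd`, `hba`,
#'   `lipinski_violations`, `pass_lipinski`, `qed` added.
#' @export
compute_properties <- function(registry, qed_weights = "unit") {
  stopifnot(all(c("merge_key", "smiles") %in% names(registry)))
  if (nrow(registry) == 0L) {
    return(mutate(registry, mw = numeric(), logp = numeric(), tpsa = numeric(),
                  hbd = integer(), hba = integer(),
                  lipinski_violations = integer(), pass_lipinski = logical(),
                  qed = numeric()))
  }
  sdf <- smiles_to_sdfset(registry$smiles, registry$merge_key)
  p <- ChemmineR::propOB(sdf)
  out <- registry |>
    mutate(
      mw   = p$MW,
      logp = p$logP,
      tpsa = p$TPSA,
      hbd  = as.integer(p$HBD),
      hba  = as.integer(p$HBA1)
    )
  out <- lipinski(out)
  out$qed <- qed_score(out, weights = qed_weights)
  out
}

# SMILES vector -> SDFset with given ids; descriptor failures raise a
# property error naming the offending structure.
smiles_to_sdfset <- function(smiles, ids) {
  sdf <- tryCatch(
    ChemmineR::smiles2sdf(setNames(smiles, ids)),
    error = function(e) {
      abort(sprintf("descriptor generation failed: %s", conditionMessage(e)),
            class = "compset_property_error")
    }
  )
  sdf
}

#' Lipinski rule-of-five violation count
#'
#' Counts violations of the four rules (MW > 500, logP > 5, H-bond donors
#' > 5, H-bond acceptors > 10). Boundary values are compliant. A compound
#' passes with at most one violation, the rule's customary reading.
#'
#' @param props A data frame with columns `mw`, `logp`, `hbd`, `hba`.
#' @return The input with integer `lipinski_violations` and logical
#'   `pass_lipinski` columns added (replaced if already present).
#' @export
lipinski <- function(props) {
  stopifnot(all(c("mw", "logp", "hbd", "hba") %in% names(props)))
  v <- (props$mw > 500) + (props$logp > 5) + (props$hbd > 5) + (props$hba > 10)
  props$lipinski_violations <- as.integer(v)
  props$pass_lipinski <- v <= 1L
  as_tibble(props)
}

#' Path-based (FP2-like) binary fingerprints
#'
#' Computes Open Babel FP2 fingerprints — linear substructure paths up to
#' length 7 hashed into a fixed-width bit vector — for every registry entry.
#' Widths below 1024 are obtained by OR-folding the 1024-bit FP2 vector in
#' halves; widths above 1024 are not supported by the FP2 hash.
#'
#' @param registry A registry tibble, or a named character vector of SMILES.
#' @param n_bits Fingerprint width: a power of two, 64 to 1024.
#' @return An integer 0/1 matrix with one row per compound (rownames are
#'   merge keys) and `n_bits` columns.
#' @export
fingerprint_compounds <- function(registry, n_bits = 1024L) {
  if (!is.numeric(n_bits) || n_bits < 64 || n_bits > 1024 ||
      bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0L) {
    abort("`n_bits` must be a power of two between 64 and 1024",
          class = "compset_value_error")
  }
  if (is.data.frame(registry)) {
    smiles <- registry$smiles
    ids <- registry$merge_key
  } else {
    smiles <- as.character(registry)
    ids <- names(registry) %||% paste0("cpd", seq_along(smiles))
  }
  sdf <- smiles_to_sdfset(smiles, ids)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  m <- fp@fpma
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  while (ncol(m) > n_bits) {
    h <- ncol(m) / 2L
    m <- (m[, seq_len(h), drop = FALSE] | m[, h + seq_len(h), drop = FALSE]) * 1L
  }
  m
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are all-zero.
#'
#' @param a,b Equal-length 0/1 (or logical) vectors.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("fingerprints have different lengths",
          class = "compset_dimension_error")
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(1.0)
  sum(a & b) / un
}

#' Rank registry compounds by fingerprint similarity to a query
#'
#' @param fps Fingerprint matrix from [fingerprint_compounds()].
#' @param query A single fingerprint vector of matching width.
#' @param threshold Minimum Tanimoto similarity to report, in `[0, 1]`.
#' @return A tibble `merge_key`, `similarity`, sorted by similarity
#'   descending with ties broken by key.
#' @export
similarity_search <- function(fps, query, threshold = 0.7) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (NROW(fps) == 0L) {
    return(tibble(merge_key = character(), similarity = numeric()))
  }
  if (ncol(fps) != length(query)) {
    abort("query fingerprint width does not match registry fingerprints",
          class = "compset_dimension_error")
  }
  q <- as.logical(query)
  inter <- as.vector(fps %*% q)
  un <- rowSums(fps > 0) + sum(q) - inter
  sim <- unname(ifelse(un == 0, 1.0, inter / un))
  tibble(merge_key = rownames(fps), similarity = sim) |>
    filter(.data$similarity >= threshold) |>
    arrange(desc(.data$similarity), .data$merge_key)
}
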
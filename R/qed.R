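# QED (quantitative estimate of drug-likeness), Bickerton et al. (2012,
# Nature Chemistry 4:90-98): each of eight descriptors is mapped through an
# asymmetric double-sigmoid desirability function (ADS) fitted to the
# descriptor's distribution over approved drugs, and the score is the
# (weighted) geometric mean of the eight desirabilities.

# Published ADS parameters (a, b, c, d, e, f, dmax) per descriptor.
.qed_ads <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
             49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
             0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
             0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000000001,
             0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
             12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684,
             1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000000001,
             1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000000001,
             0.185904477, 0.875193782, 417.7253140)
)

# Published weight presets; "unit" is the unweighted geometric mean.
.qed_weights <- list(
  unit = c(MW = 1, ALOGP = 1, HBA = 1, HBD = 1,
           PSA = 1, ROTB = 1, AROM = 1, ALERTS = 1),
  mean = c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
           PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95),
  max  = c(MW = 0.50, ALOGP = 0.25, HBA = 0.00, HBD = 0.50,
           PSA = 0.00, ROTB = 0.50, AROM = 0.25, ALERTS = 1.00)
)

qed_ads_value <- function(x, p) {
  (p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
     (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))) / p[7]
}

#' QED desirability weight presets
#'
#' @param preset `"unit"` (unweighted), `"mean"`, or `"max"` — the latter two
#'   are the published weight sets optimizing mean and maximum information
#'   content.
#' @return A named numeric vector of eight weights.
#' @export
qed_weights <- function(preset = c("unit", "mean", "max")) {
  .qed_weights[[match.arg(preset)]]
}

#' QED from a descriptor table
#'
#' Maps the eight QED descriptors through the published desirability
#' functions and returns their weighted geometric mean. This is the exact
#' QED arithmetic; supply descriptor values from any toolkit.
#'
#' @param descriptors A data frame (or named list) with columns `MW`,
#'   `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`, `AROM`, `ALERTS`.
#' @param weights A weight preset name for [qed_weights()], or a named
#'   numeric vector of eight non-negative weights (not all zero).
#' @return A numeric vector in `[0, 1]`, one value per row.
#' @export
qed_from_descriptors <- function(descriptors, weights = "unit") {
  dl <- as.list(descriptors)
  if (!all(names(.qed_ads) %in% names(dl))) {
    abort("descriptors must provide MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS",
          class = "compset_value_error")
  }
  d <- as_tibble(dl[names(.qed_ads)])
  w <- if (is.character(weights)) qed_weights(weights) else weights[names(.qed_ads)]
  if (any(is.na(w)) || any(w < 0) || sum(w) == 0) {
    abort("weights must be eight non-negative values (not all zero) named after the descriptors",
          class = "compset_value_error")
  }
  logd <- purrr::map2(d, .qed_ads, function(x, p) log(qed_ads_value(x, p)))
  exp(Reduce(`+`, purrr::map2(logd, w, `*`)) / sum(w))
}

#' QED drug-likeness score from structures
#'
#' Computes the eight QED descriptors with Open Babel (molecular weight,
#' atom-contribution logP, H-bond acceptors and donors, TPSA, rotatable
#' bonds, aromatic rings, structural-alert matches) and applies
#' [qed_from_descriptors()]. The bundled structural-alert catalogue is a
#' reduced curated set (see `system.file("extdata/structural_alerts.tsv",
#' package = "compset")`); supply `alerts_file` to use a different one.
#' Because logP (and the alert catalogue) are toolkit-dependent, absolute
#' values differ slightly across toolkits.
#'
#' @param registry A registry tibble (`merge_key`, `smiles`) or a character
#'   vector of SMILES.
#' @param weights Passed to [qed_from_descriptors()].
#' @param alerts_file Tab-separated `name<TAB>smarts` file of structural
#'   alerts.
#' @return A numeric vector in `[0, 1]`.
#' @export
qed_score <- function(registry, weights = "unit", alerts_file = NULL) {
  if (is.data.frame(registry)) {
    smiles <- registry$smiles
    ids <- registry$merge_key
  } else {
    smiles <- as.character(registry)
    ids <- names(registry) %||% paste0("cpd", seq_along(smiles))
  }
  if (length(smiles) == 0L) return(numeric())
  sdf <- smiles_to_sdfset(smiles, ids)
  p <- ChemmineR::propOB(sdf)
  rotb <- ChemmineR::smartsSearchOB(
    sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
  arom <- aromatic_ring_counts(sdf)
  alerts_file <- alerts_file %||%
    system.file("extdata", "structural_alerts.tsv", package = "compset")
  alerts <- count_alerts(sdf, alerts_file)
  qed_from_descriptors(
    tibble(MW = p$MW, ALOGP = p$logP, HBA = p$HBA1, HBD = p$HBD,
           PSA = p$TPSA, ROTB = as.numeric(rotb),
           AROM = arom, ALERTS = alerts),
    weights = weights
  )
}

# Aromatic SSSR ring count per molecule; rings() collapses to a vector when
# no molecule has a ring.
aromatic_ring_counts <- function(sdf) {
  r <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)
  if (is.data.frame(r) || is.matrix(r)) as.numeric(r[, "AROMATIC"])
  else rep(0, length(sdf))
}

# Number of distinct structural-alert patterns matched per molecule.
count_alerts <- function(sdf, alerts_file) {
  lines <- readr::read_lines(alerts_file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  smarts <- purrr::map_chr(strsplit(lines, "\t"), 2)
  hits <- rep(0, length(sdf))
  for (s in smarts) {
    m <- tryCatch(ChemmineR::smartsSearchOB(sdf, s, uniqueMatches = TRUE),
                  error = function(e) rep(0, length(sdf)))
    hits <- hits + as.numeric(m > 0)
  }
  hits
}
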
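#' Standardize compound structures to unified records
#'
#' Normalizes each input structure (strip isotope labels, neutralize charges
#' where a proton can be added or removed without violating valence, drop
#' explicit hydrogens) and derives a merge key: the 27-character standard
#' InChIKey of the normalized structure. Different isotopic, charged, and
#' (de)protonated forms of the same molecule therefore receive the same key
#' and can be collapsed with [merge_registry()].
#'
#' @param x A character vector of SMILES (names, if present, become
#'   `source_id`), or a data frame with columns `source_id` and `smiles`.
#' @param on_error `"stop"` to abort on the first unparseable structure,
#'   `"drop"` to drop offenders with a warning.
#'
#' @return A tibble with one row per input: `source_id`, `input` (the raw
#'   text), `smiles` (canonical normalized SMILES), `merge_key`.
#' @examples
#' \dontrun{
#' standardize(c(ethanol = "CCO", acetate = "CC(=O)[O-]"))
#' }
#' @export
standardize <- function(x, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  if (is.data.frame(x)) {
    if (!all(c("source_id", "smiles") %in% names(x))) {
      abort("data-frame input needs columns `source_id` and `smiles`",
            class = "compset_value_error")
    }
    ids <- as.character(x$source_id)
    smi <- as.character(x$smiles)
  } else {
    smi <- as.character(x)
    ids <- names(x) %||% paste0("cpd", seq_along(smi))
    if (is.null(names(x)) && length(smi)) ids <- paste0("cpd", seq_along(smi))
  }
  if (length(smi) == 0L || all(!nzchar(trimws(smi)))) {
    abort("no structures supplied", class = "compset_empty_input_error")
  }

  norm <- purrr::map_chr(smi, function(s) {
    tryCatch(normalize_smiles(s), compset_parse_error = function(e) NA_character_)
  })
  bad <- is.na(norm)
  if (any(bad)) {
    offenders <- smi[bad]
    if (on_error == "stop") {
      abort(sprintf("unparseable structure input: %s", offenders[1]),
            class = "compset_parse_error", input = offenders[1])
    }
    warn(sprintf("dropped %d unparseable structure(s)", sum(bad)))
  }
  keep <- !bad
  tibble(
    source_id = ids[keep],
    input     = smi[keep],
    smiles    = norm[keep],
    merge_key = inchikey_batch(norm[keep])
  )
}

# Normalize one SMILES: parse check, isotope-label strip, Open Babel charge
# neutralization, canonical SMILES (implicit hydrogens). Stereo is kept.
normalize_smiles <- function(smiles) {
  s <- trimws(smiles)
  if (!nzchar(s)) {
    abort("empty structure input", class = c("compset_empty_input_error",
                                             "compset_parse_error"))
  }
  can <- ob_convert(s, "CAN")
  if (is.na(can)) {
    abort(sprintf("cannot parse structure: %s", s),
          class = "compset_parse_error", input = s)
  }
  # Drop isotope mass labels inside bracket atoms: [13CH3] -> [CH3], [2H] -> [H].
  stripped <- gsub("\\[([0-9]+)([A-Za-z@])", "[\\2", can)
  neutral <- ob_convert(stripped, "CAN", neutralize = TRUE)
  if (is.na(neutral)) neutral <- stripped
  neutral
}

# Standard InChIKeys for a vector of (already canonical) SMILES in one
# Open Babel process. The in-memory ChemmineOB route drops tetrahedral
# stereo when writing InChI, so keys go through the obabel executable.
inchikey_batch <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  tmp_in <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(smiles, tmp_in)
  keys <- suppressWarnings(
    system2("obabel", c(tmp_in, "-oinchikey"), stdout = TRUE, stderr = FALSE))
  keys <- keys[grepl(inchikey_pattern(), keys)]
  if (length(keys) != length(smiles)) {
    # rare fallback: convert one at a time so failures stay aligned
    keys <- purrr::map_chr(smiles, function(s) {
      k <- suppressWarnings(system2("obabel", c(shQuote(paste0("-:", s)),
                                                "-oinchikey"),
                                    stdout = TRUE, stderr = FALSE))
      k <- k[grepl(inchikey_pattern(), k)]
      if (length(k)) k[1] else NA_character_
    })
  }
  bad <- is.na(keys) | !grepl(inchikey_pattern(), keys)
  if (any(bad)) {
    abort(sprintf("InChIKey generation failed for: %s", smiles[which(bad)[1]]),
          class = "compset_parse_error", input = smiles[which(bad)[1]])
  }
  keys
}

# Normalize one structure and compute its merge key.
normalize_structure <- function(smiles) {
  neutral <- normalize_smiles(smiles)
  list(smiles = neutral, merge_key = inchikey_batch(neutral))
}

inchikey_pattern <- function() "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

# Thin wrapper over ChemmineOB::convertFormat; returns NA_character_ on
# failure instead of raising from inside Open Babel.
ob_convert <- function(smiles, to, neutralize = FALSE) {
  out <- tryCatch(
    if (neutralize) {
      ChemmineOB::convertFormat(
        "SMI", to, paste0(smiles, "\n"),
        options = data.frame(names = "neutralize", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n"))
    },
    error = function(e) ""
  )
  out <- trimws(sub("\t.*", "", out[1]))
  out <- sub("^InChIKey=", "", out)
  if (!nzchar(out)) NA_character_ else out
}

#' Merge standardized records into a deduplicated registry
#'
#' Collapses records sharing a merge key into one registry entry, emulating
#' the consolidation of salt, isotope, and protonation variants under a
#' single compound identifier (lovastatin, for instance, spans dozens of
#' database entries that all normalize to one key).
#'
#' @param records A tibble from [standardize()] (columns `source_id`,
#'   `smiles`, `merge_key`).
#' @param skeleton If `TRUE`, merge on the 14-character connectivity block of
#'   the InChIKey only (stereo-insensitive).
#'
#' @return A registry tibble with one row per distinct key: `merge_key`,
#'   `smiles` (representative canonical SMILES), `n_members`, `members`
#'   (list-column of unique source ids).
#' @export
merge_registry <- function(records, skeleton = FALSE) {
  if (is.null(records) || nrow(records) == 0L) {
    return(tibble(merge_key = character(), smiles = character(),
                  n_members = integer(), members = list()))
  }
  stopifnot(all(c("source_id", "smiles", "merge_key") %in% names(records)))
  key <- if (skeleton) substr(records$merge_key, 1L, 14L) else records$merge_key
  records |>
    mutate(.key = key) |>
    group_by(.key) |>
    summarise(
      smiles    = .data$smiles[1],
      members   = list(unique(.data$source_id)),
      .groups = "drop"
    ) |>
    mutate(n_members = lengths(.data$members)) |>
    select(merge_key = ".key", "smiles", "n_members", "members") |>
    arrange(.data$merge_key)
}

#' Read a SMILES file into a source table
#'
#' One molecule per line; an optional second tab-separated field is the
#' source id. Lines starting with `#` are skipped.
#'
#' @param path Path to the file.
#' @return A tibble with columns `source_id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t")
  tibble(
    source_id = purrr::map_chr(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][2] else paste0("cpd", i)
    }),
    smiles = purrr::map_chr(parts, 1)
  )
}

#' Read an SDF (V2000) file into a source table
#'
#' @param path Path to the SDF file.
#' @return A tibble with columns `source_id` (molecule titles, made unique)
#'   and `smiles`.
#' @export
read_sdf_file <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- ChemmineR::sdf2smiles(sdf)
  ids <- make.unique(ChemmineR::sdfid(sdf))
  tibble(source_id = ids, smiles = unname(as.character(smi)))
}

#' Write a registry (with properties, if present) to TSV
#'
#' Columns: `merge_key`, `canonical_smiles`, `n_members`, then any property
#' columns present (`mw`, `logp`, `tpsa`, `hbd`, `hba`,
#' `lipinski_violations`, `qed`).
#'
#' @param registry A registry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  props <- intersect(c("mw", "logp", "tpsa", "hbd", "hba",
                       "lipinski_violations", "qed"), names(registry))
  out <- registry |>
    select("merge_key", canonical_smiles = "smiles", "n_members",
           all_of(props))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a registry TSV written by [write_registry()]
#'
#' @param path Path to the TSV.
#' @return A registry tibble (without the in-memory `members` list-column;
#'   each entry resolves to itself).
#' @export
read_registry <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab |>
    dplyr::rename(smiles = "canonical_smiles") |>
    mutate(members = purrr::map(.data$merge_key, identity))
}
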
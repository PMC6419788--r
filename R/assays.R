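#' Read a bioassay activity table
#'
#' Expected tab-separated columns: `assay_id`, `compound_id`, `activity`,
#' `flag` (`active`, `inactive`, or `NA`), `direction` (`higher_is_active`
#' or `lower_is_active`; required — potency readouts are not auto-detected
#' from titles), and optional `title`, `target_gene`. If `registry` is
#' given, `compound_id` is resolved to merge keys through its `members`
#' list-column.
#'
#' @param path Path to the TSV.
#' @param registry Optional registry tibble for id resolution.
#' @return A tibble with one row per (assay, compound) measurement and a
#'   `merge_key` column.
#' @export
read_assays <- function(path, registry = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           assay_id = "c", compound_id = "c",
                           .default = readr::col_guess()))
  need <- c("assay_id", "compound_id")
  if (!all(need %in% names(tab))) {
    abort("assay table needs columns assay_id and compound_id",
          class = "compset_format_error")
  }
  if (!"direction" %in% names(tab)) {
    abort("assay table needs a direction column (higher_is_active / lower_is_active)",
          class = "compset_format_error")
  }
  bad <- !tab$direction %in% c("higher_is_active", "lower_is_active")
  if (any(bad)) {
    abort(sprintf("unknown direction on line %d: %s",
                  which(bad)[1] + 1L, tab$direction[which(bad)[1]]),
          class = "compset_format_error")
  }
  tab$merge_key <- if (is.null(registry)) {
    tab$compound_id
  } else {
    resolve_ids(tab$compound_id, registry)
  }
  tab
}

# Map source ids (or merge keys) to merge keys via the registry's members
# list-column; unresolved ids become NA.
resolve_ids <- function(ids, registry) {
  lut <- tibble(
    source_id = unlist(registry$members),
    merge_key = rep(registry$merge_key, lengths(registry$members))
  )
  lut <- bind_rows(lut, tibble(source_id = registry$merge_key,
                               merge_key = registry$merge_key))
  lut <- distinct(lut, .data$source_id, .keep_all = TRUE)
  lut$merge_key[match(ids, lut$source_id)]
}

#' Z-score hit selection for one assay
#'
#' Values are oriented so that larger means more active (negated when
#' `direction = "lower_is_active"`), standardized with the sample standard
#' deviation (denominator n - 1), and compounds at `z >= z_cut` are
#' returned. When the standard deviation is zero the Z-score is undefined
#' and the selection is empty.
#'
#' @param activities Named numeric vector (names are merge keys).
#' @param direction `"higher_is_active"` or `"lower_is_active"`.
#' @param z_cut Z-score cutoff (default 2).
#' @return Character vector of selected merge keys.
#' @export
zscore_hits <- function(activities, direction = "higher_is_active",
                        z_cut = 2) {
  x <- orient(activities, direction)
  if (length(x) < 2L) return(character())
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(character())
  names(x)[(x - mean(x)) / s >= z_cut]
}

#' Top-percentile hit selection for one assay
#'
#' Selects the `k = max(1, floor(top_frac * n))` best-oriented compounds,
#' plus every compound tied with the k-th ranked value.
#'
#' @inheritParams zscore_hits
#' @param top_frac Fraction of tested compounds to take (default 0.01).
#' @return Character vector of selected merge keys.
#' @export
top_percent_hits <- function(activities, direction = "higher_is_active",
                             top_frac = 0.01) {
  if (length(activities) == 0L) return(character())
  assert_scalar_number(top_frac, "top_frac", 0, 1)
  x <- orient(activities, direction)
  k <- max(1L, floor(top_frac * length(x)))
  cut <- sort(x, decreasing = TRUE)[k]
  names(x)[x >= cut]
}

orient <- function(activities, direction) {
  direction <- match.arg(direction, c("higher_is_active", "lower_is_active"))
  x <- activities
  if (direction == "lower_is_active") x <- -x
  x
}

#' Assign hit sets for bioassays
#'
#' Applies the three-criterion hit policy per assay: if active/inactive
#' flags are available they define the hits; otherwise, for assays with at
#' least `min_n` tested compounds, the hit set is the union of the Z-score
#' selection (`z >= z_cut`) and the top-percentile selection. Smaller
#' unflagged assays yield an empty hit set with a warning. Z-scores are
#' computed per assay over its tested compounds.
#'
#' @param assays A measurement tibble from [read_assays()] (columns
#'   `assay_id`, `merge_key`, and `activity` and/or `flag`, plus
#'   `direction`), or a list of such tibbles.
#' @param z_cut,top_frac Cutoffs for the statistical criteria.
#' @param min_n Minimum tested compounds for the statistical criteria.
#' @return A tibble with one row per assay: `assay_id`, `title`,
#'   `target_gene` (when present), `n_tested`, `n_hits`, `criteria`
#'   (`"flags"` or `"zscore+top_percent"`), and list-columns `hits` and
#'   `tested`.
#' @export
assign_hits <- function(assays, z_cut = 2, top_frac = 0.01, min_n = 20L) {
  if (is.list(assays) && !is.data.frame(assays)) assays <- bind_rows(assays)
  if (!all(c("assay_id", "merge_key") %in% names(assays))) {
    abort("need columns assay_id and merge_key", class = "compset_format_error")
  }
  has_flag <- "flag" %in% names(assays)
  has_act  <- "activity" %in% names(assays)
  if (!has_flag && !has_act) {
    abort("assay table carries neither flags nor activities",
          class = "compset_unusable_assay_error")
  }
  assert_scalar_number(top_frac, "top_frac", 0, 1)

  per_assay <- split(assays, assays$assay_id)
  rows <- purrr::map(per_assay, function(a) {
    tested <- unique(a$merge_key)
    dirn <- if ("direction" %in% names(a)) a$direction[1] else "higher_is_active"
    flags <- if (has_flag) a$flag else rep(NA_character_, nrow(a))
    if (has_flag && any(!is.na(flags))) {
      hits <- unique(a$merge_key[!is.na(flags) & flags == "active"])
      crit <- "flags"
    } else if (!has_act || all(is.na(a$activity))) {
      abort(sprintf("assay %s has neither flags nor activities", a$assay_id[1]),
            class = "compset_unusable_assay_error")
    } else if (length(tested) < min_n) {
      warn(sprintf("assay %s: only %d tested compounds (< min_n = %d); no hits assigned",
                   a$assay_id[1], length(tested), min_n))
      hits <- character()
      crit <- "none"
    } else {
      act <- setNames(a$activity, a$merge_key)
      act <- act[!duplicated(names(act))]
      hits <- union(zscore_hits(act, dirn, z_cut),
                    top_percent_hits(act, dirn, top_frac))
      crit <- "zscore+top_percent"
    }
    tibble(
      assay_id = a$assay_id[1],
      title = if ("title" %in% names(a)) a$title[1] else NA_character_,
      target_gene = if ("target_gene" %in% names(a)) a$target_gene[1] else NA_character_,
      n_tested = length(tested),
      n_hits = length(hits),
      hit_rate = if (length(tested)) length(hits) / length(tested) else NA_real_,
      criteria = crit,
      hits = list(sort(hits)),
      tested = list(sort(tested))
    )
  })
  bind_rows(rows) |> arrange(.data$assay_id)
}
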
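#' Build a query compound set from identifiers
#'
#' Resolves source ids (or merge keys) against a registry; duplicates
#' collapse and unresolved ids are reported. A screen's hit list can map to
#' more merge keys than input ids when an id matches a multi-variant
#' registry entry, or fewer when variants collapse.
#'
#' @param ids Character vector of ids, or a path to a file with one id per
#'   line (`#` comments allowed).
#' @param registry Registry tibble.
#' @param name Set name.
#' @return A `compound_set` with attribute `resolution` (tibble
#'   `n_input`, `n_resolved`, `n_unresolved`).
#' @export
load_set <- function(ids, registry, name = "query") {
  if (length(ids) == 1L && file.exists(ids)) {
    lines <- readr::read_lines(ids)
    ids <- trimws(lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)])
  }
  ids <- unique(as.character(ids))
  lut <- tibble(
    source_id = unlist(registry$members),
    merge_key = rep(registry$merge_key, lengths(registry$members))
  ) |>
    bind_rows(tibble(source_id = registry$merge_key,
                     merge_key = registry$merge_key)) |>
    distinct()
  hitsp <- lut[lut$source_id %in% ids, , drop = FALSE]
  resolved_ids <- unique(hitsp$source_id)
  keys <- unique(hitsp$merge_key)
  n_un <- length(ids) - length(resolved_ids)
  if (length(keys) == 0L) {
    abort(sprintf("no resolvable ids (0/%d resolved)", length(ids)),
          class = "compset_empty_set_error")
  }
  if (n_un > 0) {
    inform(sprintf("%d/%d ids resolved (%d unresolved)",
                   length(resolved_ids), length(ids), n_un))
  }
  out <- compound_set(sort(keys), name = name)
  attr(out, "resolution") <- tibble(n_input = length(ids),
                                    n_resolved = length(resolved_ids),
                                    n_unresolved = n_un)
  out
}

#' Combine two compound sets with set algebra
#'
#' @param a,b `compound_set` objects (or character vectors) built over the
#'   same registry.
#' @param op `"union"`, `"intersect"`, or `"difference"` (a minus b).
#' @return A `compound_set` with a derived name.
#' @export
set_op <- function(a, b, op = c("union", "intersect", "difference")) {
  op <- match.arg(op)
  an <- attr(a, "name") %||% "a"
  bn <- attr(b, "name") %||% "b"
  members <- switch(op,
    union = union(a, b),
    intersect = intersect(a, b),
    difference = setdiff(a, b))
  sym <- c(union = "∪", intersect = "∩", difference = "∖")[op]
  if (length(members) == 0L) {
    # empty results are representable downstream as plain character()
    return(structure(character(), name = paste0(an, sym, bn),
                     class = c("compound_set", "character")))
  }
  compound_set(sort(members), name = paste0(an, sym, bn))
}

#' Parse a property-filter expression
#'
#' Accepts strings like `"mw<=500"`, `"qed>=0.5"`, `"lipinski_violations==1"`
#' over the property fields `mw`, `logp`, `tpsa`, `hbd`, `hba`, `qed`,
#' `lipinski_violations`.
#'
#' @param expr Filter string.
#' @return A list with `field`, `op` (`le`, `ge`, `eq`), `value`.
#' @export
parse_filter <- function(expr) {
  m <- regmatches(expr, regexec("^\\s*([a-z_]+)\\s*(<=|>=|==)\\s*(-?[0-9.]+)\\s*$",
                                expr))[[1]]
  fields <- c("mw", "logp", "tpsa", "hbd", "hba", "qed", "lipinski_violations")
  if (length(m) != 4L || !m[2] %in% fields) {
    abort(sprintf("cannot parse filter '%s' (fields: %s; ops: <=, >=, ==)",
                  expr, paste(fields, collapse = ", ")),
          class = "compset_config_error")
  }
  list(field = m[2], op = c("<=" = "le", ">=" = "ge", "==" = "eq")[[m[3]]],
       value = as.numeric(m[4]))
}

#' Filter a compound set by physicochemical properties
#'
#' Keeps members satisfying every filter (conjunction; for disjunction,
#' union filtered sets with [set_op()]). Members whose properties are
#' missing in the registry fail the filters and are dropped with a message.
#'
#' @param s A `compound_set`.
#' @param filters A list of filters from [parse_filter()] (or filter
#'   strings).
#' @param registry Registry tibble with property columns (see
#'   [compute_properties()]).
#' @return The filtered `compound_set`.
#' @export
filter_set <- function(s, filters, registry) {
  if (length(filters) == 0L) return(s)
  filters <- purrr::map(filters, function(f) {
    if (is.character(f)) parse_filter(f) else f
  })
  props <- registry[match(as.character(s), registry$merge_key), , drop = FALSE]
  keep <- rep(TRUE, length(s))
  for (f in filters) {
    if (!f$field %in% names(props)) {
      abort(sprintf("unknown or uncomputed property field '%s'", f$field),
            class = "compset_config_error")
    }
    v <- props[[f$field]]
    ok <- switch(f$op, le = v <= f$value, ge = v >= f$value,
                 eq = v == f$value)
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  dropped <- sum(is.na(props$merge_key))
  if (dropped > 0) {
    inform(sprintf("%d member(s) without registry properties were excluded",
                   dropped))
  }
  out <- as.character(s)[keep]
  structure(sort(out), name = attr(s, "name"),
            class = c("compound_set", "character"))
}
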
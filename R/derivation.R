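# Per-person derivation of a single ethnic category from episodic records.
#
# Two methods are applied to the episodic sources: most recent (recency) and
# most frequent (modal), each with source-specific tie-breaking. Whenever a
# tie-breaking chain cannot select a unique category the person is marked
# UNRESOLVED. Missing-data codes (Not Stated, Not Known) are ordinary
# candidate values at this stage — they can win a derivation — and are only
# handled specially by the reallocation cascade and by the metrics.

.GDPPR_PRIORITY <- c("GP_JOURNAL", "GP_PATIENT")
.HES_PRIORITY <- c("HES_APC", "HES_AE_ECDS", "HES_OP")

# rows at the per-person extreme of `col`; vectorised (join, no per-group R)
.keep_extreme <- function(dt, col, which = c("max", "min")) {
  which <- match.arg(which)
  if (nrow(dt) == 0L) return(dt)
  ext <- dt[, .(.ext = F(V)), by = person_id,
            env = list(F = which, V = col)]
  dt <- ext[dt, on = "person_id"]
  dt <- dt[V == .ext, env = list(V = col)]
  dt[, .ext := NULL]
  dt[]
}

# unique category per person, UNRESOLVED on conflict
.unique_or_unresolved <- function(dt) {
  u <- unique(dt[, .(person_id, category)])
  k <- u[, .(.k = .N), by = person_id]
  u <- k[u, on = "person_id"]
  unique(rbind(
    u[.k == 1L, .(person_id, category)],
    u[.k > 1L, .(person_id, category = "UNRESOLVED")]
  ))
}

# modal category per person, UNRESOLVED on a tie for the maximum frequency
.modal_or_unresolved <- function(dt) {
  cnt <- dt[, .(.n = .N), by = .(person_id, category)]
  cnt <- .keep_extreme(cnt, ".n", "max")
  .unique_or_unresolved(cnt)
}

# recency with sub-source priority applied only among records sharing the
# single latest date: an older high-priority record never outranks a newer
# low-priority one
.recency_priority <- function(dt, priority) {
  dt <- .keep_extreme(dt, "record_date", "max")
  dt[, .pr := match(sub_source, priority)]
  dt <- .keep_extreme(dt, ".pr", "min")
  .unique_or_unresolved(dt)
}

.derive_core <- function(dt, source, method) {
  if (source == "GDPPR" && method == "recency") {
    .recency_priority(dt, .GDPPR_PRIORITY)
  } else if (source == "GDPPR" && method == "modal") {
    jp <- unique(dt[sub_source == "GP_JOURNAL", person_id])
    rbind(
      .modal_or_unresolved(dt[sub_source == "GP_JOURNAL"]),
      .modal_or_unresolved(dt[!(person_id %in% jp)])
    )
  } else if (source == "HES" && method == "recency") {
    .recency_priority(dt, .HES_PRIORITY)
  } else if (source == "HES" && method == "modal") {
    .modal_or_unresolved(dt)
  } else if (source == "TT" && method == "recency") {
    dt <- copy(dt)
    dt[category %in% c("DATA_NOT_RECORDED", "VALUE_OUTSIDE_NATIONAL_CODE"),
       category := "NOT_KNOWN"]
    dt <- .keep_extreme(dt, "year", "max")
    dt <- .keep_extreme(dt, "record_date", "max")
    .unique_or_unresolved(dt)
  } else if (source == "ECIA") {
    k <- dt[, .N, by = person_id]
    if (any(k$N > 1L)) {
      stop("ECIA must contain a single record per person; violated for: ",
           paste(head(k$person_id[k$N > 1L], 5L), collapse = ", "),
           call. = FALSE)
    }
    dt[, .(person_id, category)]
  } else {
    stop("no '", method, "' derivation is defined for source ", source,
         call. = FALSE)
  }
}

#' Derive one ethnic category per person from episodic records
#'
#' Reduces each person's records within one source to a single category:
#'
#' * **GDPPR recency** — latest date across the GP-Journal and GP-Patient
#'   tables; on same-date conflict the GP-Journal recording wins; a
#'   persisting same-date conflict within the winning table is `UNRESOLVED`.
#' * **GDPPR modal** — most frequent category within GP-Journal; persons
#'   with no GP-Journal recording at all fall back to the most frequent
#'   GP-Patient category; a tie for the maximum frequency is `UNRESOLVED`.
#'   Two distinct clinical codes resolving to one category reinforce that
#'   category: occurrences of the resolved category are counted.
#' * **HES recency** — latest date; same-date conflicts resolved in the
#'   order APC, A&E/ECDS, OP; remaining conflicts are `UNRESOLVED`.
#' * **HES modal** — most frequent category pooled across all sub-datasets,
#'   no priority; ties are `UNRESOLVED`.
#' * **TT recency** — within the most recent reporting year, the most
#'   recent recording (from the supplier holding that latest date);
#'   conflicting categories on that date are `UNRESOLVED`.
#'   `DATA_NOT_RECORDED` and `VALUE_OUTSIDE_NATIONAL_CODE` are treated as
#'   `NOT_KNOWN` before derivation. No modal derivation exists for TT.
#' * **ECIA** — the source holds one record per person, which is returned
#'   as-is (`method = "single"`); more than one record is an error.
#'
#' @param records Episodic records of a single source (a `category` column
#'   is added via [resolve_categories()] if absent).
#' @param source One of `"GDPPR"`, `"HES"`, `"TT"`, `"ECIA"`.
#' @param method `"recency"` or `"modal"` (`"single"` for ECIA).
#' @param lookup Clinical-code lookup for GP-Journal rows.
#' @return A data.frame with columns `person_id`, `source`, `method`,
#'   `category`; one row per person present in the source.
#' @export
derive_ethnicity <- function(records, source = c("GDPPR", "HES", "TT", "ECIA"),
                             method = c("recency", "modal", "single"),
                             lookup = load_code_lookup()) {
  source <- match.arg(source)
  method <- match.arg(method)
  if (source == "ECIA") method <- "single"
  if (method == "single" && source != "ECIA") {
    stop("method 'single' applies only to ECIA", call. = FALSE)
  }
  if (!"category" %in% names(records)) {
    records <- resolve_categories(records, lookup)
  }
  if ("source" %in% names(records) && !all(records$source == source)) {
    stop("records contain sources other than ", source, call. = FALSE)
  }
  cols <- intersect(c("person_id", "sub_source", "record_date", "category",
                      "year"), names(records))
  if (source == "TT" && !"year" %in% cols) {
    stop("TT derivation requires a year column", call. = FALSE)
  }
  dt <- as.data.table(as.data.frame(records)[, cols, drop = FALSE])
  out <- if (nrow(dt) == 0L) {
    data.table(person_id = character(), category = character())
  } else {
    .derive_core(dt, source, method)
  }
  setorder(out, person_id)
  data.frame(person_id = out$person_id,
             source = rep_len(source, nrow(out)),
             method = rep_len(method, nrow(out)),
             category = out$category, stringsAsFactors = FALSE)
}

.one_person <- function(records, source) {
  if (nrow(records) == 0L) {
    stop("empty record set: person absent from ", source, call. = FALSE)
  }
  if (length(unique(records$person_id)) != 1L) {
    stop("expected the records of a single person", call. = FALSE)
  }
  invisible(records)
}

#' Single-person derivation rules
#'
#' Convenience wrappers over [derive_ethnicity()] for the records of one
#' person in one source; they error on an empty record set (a person absent
#' from a source is simply omitted from that source's outputs).
#'
#' @param records The records of one person in the relevant source.
#' @param lookup Clinical-code lookup for GP-Journal rows.
#' @return A one-row data.frame (`person_id`, `source`, `method`,
#'   `category`).
#' @name derive_single
NULL

#' @rdname derive_single
#' @export
derive_recency_gdppr <- function(records, lookup = load_code_lookup()) {
  .one_person(records, "GDPPR")
  derive_ethnicity(records, "GDPPR", "recency", lookup)
}

#' @rdname derive_single
#' @export
derive_modal_gdppr <- function(records, lookup = load_code_lookup()) {
  .one_person(records, "GDPPR")
  derive_ethnicity(records, "GDPPR", "modal", lookup)
}

#' @rdname derive_single
#' @export
derive_recency_hes <- function(records) {
  .one_person(records, "HES")
  derive_ethnicity(records, "HES", "recency")
}

#' @rdname derive_single
#' @export
derive_modal_hes <- function(records) {
  .one_person(records, "HES")
  derive_ethnicity(records, "HES", "modal")
}

#' @rdname derive_single
#' @export
derive_recency_tt <- function(records) {
  .one_person(records, "TT")
  derive_ethnicity(records, "TT", "recency")
}

#' @rdname derive_single
#' @export
derive_ecia <- function(records) {
  .one_person(records, "ECIA")
  derive_ethnicity(records, "ECIA", "single")
}
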
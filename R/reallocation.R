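# Sequential reallocation of missing-data and over-coded derivations.
#
# Three cumulative levels replace a person's derived category when it is a
# reallocatable code and an alternative category exists anywhere in their
# record history — even if those records are older or less frequent. Each
# level is applied to the un-reallocated derivation, not chained onto the
# previous level; the levels differ only in which codes are reallocatable.

.REALLOC_SETS <- list(
  none = character(),
  l1 = c("NOT_KNOWN"),
  l2 = c("NOT_KNOWN", "ANY_OTHER"),
  l3 = c("NOT_KNOWN", "ANY_OTHER", "NOT_STATED")
)

#' Reallocatable categories at each cascade level
#'
#' Level `l1` reallocates `NOT_KNOWN`; `l2` adds `ANY_OTHER` (Any Other
#' Ethnic Group, reallocated because of its known over-coding); `l3` adds
#' `NOT_STATED`. The sets are nested. `UNRESOLVED` is never a reallocation
#' trigger.
#'
#' @param level One of `"none"`, `"l1"`, `"l2"`, `"l3"`.
#' @return Character vector of reallocatable category codes.
#' @export
reallocatable_categories <- function(level = c("none", "l1", "l2", "l3")) {
  .REALLOC_SETS[[match.arg(level)]]
}

# TT missing-data synonyms collapse onto NOT_KNOWN before any category logic
.normalize_tt <- function(category) {
  category[category %in% c("DATA_NOT_RECORDED",
                           "VALUE_OUTSIDE_NATIONAL_CODE")] <- "NOT_KNOWN"
  category
}

#' Reallocate derived categories using a person's full record history
#'
#' For each person whose derived category is reallocatable at `level`, all
#' records carrying reallocatable categories are removed from their history
#' and the same derivation method is re-run on the remainder (a tie in the
#' re-derivation yields `UNRESOLVED`, which stands). If no records remain,
#' the footnote destination rule applies: at levels `l2`/`l3`, a person
#' whose history contains Any Other Ethnic Group receives `ANY_OTHER`;
#' otherwise the original derived category is retained (a person with only
#' one-and-the-same code throughout is never reallocated).
#'
#' @param derived Output of [derive_ethnicity()]: one row per person.
#' @param records The full episodic records of the same source that
#'   produced `derived` (the reallocation history).
#' @param level Cascade level, `"none"`, `"l1"`, `"l2"` or `"l3"`.
#' @param lookup Clinical-code lookup for GP-Journal rows.
#' @return `derived` with categories reallocated and a `level` column added.
#' @export
reallocate <- function(derived, records, level = c("none", "l1", "l2", "l3"),
                       lookup = load_code_lookup()) {
  level <- match.arg(level)
  stopifnot(all(c("person_id", "source", "method", "category") %in%
                  names(derived)))
  source <- unique(derived$source)
  method <- unique(derived$method)
  if (length(source) != 1L || length(method) != 1L) {
    stop("`derived` must come from a single source and method", call. = FALSE)
  }
  if (source == "ECIA") {
    stop("reallocation applies to episodic sources only, not ECIA",
         call. = FALSE)
  }
  out <- derived
  out$level <- level
  set <- .REALLOC_SETS[[level]]
  if (length(set) == 0L) return(out)

  if (!"category" %in% names(records)) {
    records <- resolve_categories(records, lookup)
  }
  hist_cat <- records$category
  if (source == "TT") hist_cat <- .normalize_tt(hist_cat)
  records$category <- hist_cat

  trig <- out$person_id[out$category %in% set]
  if (length(trig) == 0L) return(out)
  missing_hist <- setdiff(trig, unique(records$person_id))
  if (length(missing_hist)) {
    stop("derived person(s) with no record history: ",
         paste(head(missing_hist, 5L), collapse = ", "), call. = FALSE)
  }

  hist <- records[records$person_id %in% trig, , drop = FALSE]
  keep <- hist[!(hist$category %in% set), , drop = FALSE]
  if (nrow(keep)) {
    redone <- derive_ethnicity(keep, source, method, lookup)
    idx <- match(redone$person_id, out$person_id)
    out$category[idx] <- redone$category
  }
  # persons whose entire history is reallocatable: footnote destination rule
  emptied <- setdiff(trig, unique(keep$person_id))
  if (length(emptied) && level %in% c("l2", "l3")) {
    has_aoeg <- unique(hist$person_id[hist$category == "ANY_OTHER"])
    dest <- intersect(emptied, has_aoeg)
    out$category[out$person_id %in% dest] <- "ANY_OTHER"
  }
  out
}

#' Run the full reallocation cascade
#'
#' Applies every cascade level to one derived table, returning the four
#' level-stamped tables (level `none` is the input unchanged).
#'
#' @inheritParams reallocate
#' @return A named list of derived tables: `none`, `l1`, `l2`, `l3`.
#' @export
run_cascade <- function(derived, records, lookup = load_code_lookup()) {
  if (anyDuplicated(derived$person_id)) {
    stop("`derived` must have one row per person", call. = FALSE)
  }
  if (!"category" %in% names(records)) {
    records <- resolve_categories(records, lookup)
  }
  stats::setNames(
    lapply(names(.REALLOC_SETS), function(lv)
      reallocate(derived, records, lv, lookup)),
    names(.REALLOC_SETS)
  )
}
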
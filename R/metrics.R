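# Concordance tables and agreement / sensitivity / PPV summaries.
#
# The crosstab rows are census categories and the columns are the source's
# categories aligned to the census scheme. Persons whose derived category is
# a missing-data or Unresolved marker are excluded from the table (tallied
# separately), because no equivalent census category exists. Agreement and
# PPV use source-side (column) totals as denominators; sensitivity uses
# census-side (row) totals.

.source_vocab_name <- function(source) {
  switch(source,
         GDPPR = "nhs_18", ECIA = "nhs_18",
         HES = "nhs_16", TT = "nhs_16",
         stop("unknown source: ", source, call. = FALSE))
}

#' Crosstabulate derived categories against the census gold standard
#'
#' Builds the census-by-source concordance table at 18- or 5-category
#' resolution. Rows span every substantive census category (including Roma,
#' which has no counterpart column in any health source); columns span the
#' source vocabulary's substantive categories aligned to the census scheme.
#' Persons derived as `NOT_STATED`, `NOT_KNOWN` or `UNRESOLVED` are counted
#' in `excluded_special`, not in the table; persons in `derived` with no
#' gold-standard row are counted in `n_unlinked`.
#'
#' @param derived A derived table (one row per person) from
#'   [derive_ethnicity()] or [reallocate()].
#' @param gold Gold-standard table (`person_id`, `census_code`).
#' @param resolution `"cat18"` or `"cat5"`.
#' @param persons Optional person subset (e.g. from
#'   [restrict_complete_case()]) applied before tabulation.
#' @return An object of class `concordance_table` with fields `counts`
#'   (matrix, census rows by source columns), `excluded_special` (named
#'   counts), `n_unlinked`, `resolution`, `source`, `method`, `level`,
#'   `sdc` (`FALSE`).
#' @export
build_crosstab <- function(derived, gold, resolution = c("cat18", "cat5"),
                           persons = NULL) {
  resolution <- match.arg(resolution)
  source <- unique(derived$source)
  stopifnot(length(source) == 1L)
  if (!is.null(persons)) {
    derived <- derived[derived$person_id %in% persons, , drop = FALSE]
    gold <- gold[gold$person_id %in% persons, , drop = FALSE]
  }
  svocab <- load_vocabulary(.source_vocab_name(source))
  cvocab <- load_vocabulary("census21_19")

  idx <- match(derived$person_id, gold$person_id)
  n_unlinked <- sum(is.na(idx))
  linked <- derived[!is.na(idx), , drop = FALSE]
  census <- gold$census_code[idx[!is.na(idx)]]

  cat <- linked$category
  if (source == "TT") cat <- .normalize_tt(cat)
  sp <- cat %in% .SPECIAL_CODES
  excluded_special <- table(factor(cat[sp], levels = .SPECIAL_CODES))
  excluded_special <- setNames(as.integer(excluded_special),
                               names(excluded_special))

  src_align <- align_to_census(cat[!sp], svocab)
  cen_align <- align_to_census(census[!sp], cvocab)
  if (resolution == "cat18") {
    row_levels <- substantive_codes(cvocab)
    col_levels <- sort(unique(stats::na.omit(
      align_to_census(substantive_codes(svocab), svocab)$code18)))
    rows <- census[!sp]            # census codes, Roma kept distinct
    cols <- src_align$code18
  } else {
    row_levels <- .CODE5
    col_levels <- .CODE5
    rows <- cen_align$code5
    cols <- src_align$code5
  }
  counts <- table(factor(rows, levels = row_levels),
                  factor(cols, levels = col_levels))
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(census = row_levels, source = col_levels))
  structure(
    list(counts = counts, excluded_special = excluded_special,
         n_unlinked = n_unlinked, resolution = resolution, source = source,
         method = unique(derived$method),
         level = if ("level" %in% names(derived)) unique(derived$level)
                 else "none",
         sdc = FALSE),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table> ", x$source, " (", x$method, ", level ", x$level,
      ", ", x$resolution, if (x$sdc) ", SDC applied" else "", ")\n", sep = "")
  cat("  persons tabulated: ", sum(x$counts, na.rm = TRUE),
      "; excluded special: ", sum(x$excluded_special),
      "; unlinked: ", x$n_unlinked, "\n", sep = "")
  invisible(x)
}

# shared diagonal machinery for raw and disclosure-controlled tables;
# suppressed cells (NA) contribute zero to numerators and denominators
.agreement_impl <- function(counts, resolution, source, sdc) {
  cm <- counts
  cm[is.na(cm)] <- 0L
  shared <- intersect(rownames(cm), colnames(cm))
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  diag_k <- setNames(cm[cbind(shared, shared)], shared)

  per <- data.frame(category = colnames(cm), stringsAsFactors = FALSE)
  per$n_source <- as.integer(colsum)
  per$n_census <- as.integer(rowsum[match(per$category, rownames(cm))])
  dk <- diag_k[per$category]
  per$agreement <- ifelse(per$n_source > 0, 100 * dk / per$n_source, NA_real_)
  per$sensitivity <- ifelse(!is.na(per$n_census) & per$n_census > 0,
                            100 * dk / per$n_census, NA_real_)
  per$ppv <- per$agreement   # identical by construction (source-side denom)
  total <- sum(cm)
  structure(
    list(per_category = per,
         overall_agreement = if (total > 0) 100 * sum(diag_k) / total
                             else NA_real_,
         n_included = total, resolution = resolution, source = source,
         sdc = sdc),
    class = "agreement_report"
  )
}

#' Agreement, sensitivity and positive predictive value
#'
#' Summarises a concordance table. Per-category agreement is the diagonal
#' count over the source-side column total (and is identical to PPV by
#' construction); sensitivity is the diagonal count over the census-side row
#' total; overall agreement is the summed diagonal over the grand total.
#' Categories absent from the source vocabulary (Roma everywhere; Arab and
#' Gypsy or Irish Traveller for the 16-category sources) yield no agreement
#' value, and zero denominators give `NA`, never 0.
#'
#' @param tab A `concordance_table` (see [build_crosstab()]); for a
#'   disclosure-controlled table use [agreement_from_sdc()].
#' @return An `agreement_report`: `per_category` data.frame (`category`,
#'   `n_source`, `n_census`, `agreement`, `sensitivity`, `ppv`) plus
#'   `overall_agreement` and `n_included`.
#' @export
agreement <- function(tab) {
  stopifnot(inherits(tab, "concordance_table"))
  if (isTRUE(tab$sdc)) {
    stop("use agreement_from_sdc() for a disclosure-controlled table",
         call. = FALSE)
  }
  .agreement_impl(tab$counts, tab$resolution, tab$source, sdc = FALSE)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$source, " (", x$resolution,
      if (x$sdc) ", from SDC table" else "", ")\n", sep = "")
  cat("  overall agreement: ",
      ifelse(is.na(x$overall_agreement), "NA",
             sprintf("%.1f%%", x$overall_agreement)),
      " over ", x$n_included, " persons\n", sep = "")
  per <- x$per_category
  per$agreement <- round(per$agreement, 1)
  per$sensitivity <- round(per$sensitivity, 1)
  per$ppv <- round(per$ppv, 1)
  print(per, row.names = FALSE)
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param report An `agreement_report`.
#' @return Long-format data.frame (`category`, `metric`, `value`,
#'   `denominator`), percentages at full precision.
#' @export
tidy_agreement <- function(report) {
  per <- report$per_category
  rbind(
    data.frame(category = per$category, metric = "agreement",
               value = per$agreement, denominator = per$n_source),
    data.frame(category = per$category, metric = "sensitivity",
               value = per$sensitivity, denominator = per$n_census),
    data.frame(category = per$category, metric = "ppv",
               value = per$ppv, denominator = per$n_source),
    data.frame(category = "OVERALL", metric = "overall_agreement",
               value = report$overall_agreement,
               denominator = report$n_included)
  )
}

#' Complete-case person subset across primary and secondary care
#'
#' Returns the persons holding a substantive (non-missing, non-Unresolved)
#' derived category in both supplied derived tables and present in the gold
#' standard — the population restriction used to compare sources on a
#' common footing.
#'
#' @param derived_a,derived_b Two derived tables (e.g. GDPPR and HES).
#' @param gold Gold-standard table.
#' @return Character vector of person ids.
#' @export
restrict_complete_case <- function(derived_a, derived_b, gold) {
  sub_ids <- function(d) {
    cat <- d$category
    if (unique(d$source) == "TT") cat <- .normalize_tt(cat)
    d$person_id[!(cat %in% .SPECIAL_CODES)]
  }
  Reduce(intersect, list(sub_ids(derived_a), sub_ids(derived_b),
                         gold$person_id))
}
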
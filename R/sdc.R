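# Statistical disclosure control for publication-style output.
#
# Counts below 10 are suppressed; counts of 10 or above are rounded to the
# nearest 5 (an integer is never equidistant between two multiples of 5, so
# the rule never ties); zero cells stay zero. Published percentages are
# computed from the rounded and suppressed values, with suppressed cells
# contributing zero — the only computation possible without the raw value.

.sdc_cells <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  out <- x
  small <- !is.na(x) & x >= 1 & x <= 9
  big <- !is.na(x) & x >= 10
  out[small] <- NA_integer_
  out[big] <- as.integer(round(x[big] / 5) * 5)
  out
}

#' Apply statistical disclosure control to a concordance table
#'
#' Cells 1–9 are suppressed (represented as `NA`, serialised as `"[c]"`),
#' cells of 10 or more are rounded to the nearest 5, zeros are unchanged.
#' The excluded-special tallies receive the same treatment. The rule is
#' idempotent, and the pre-SDC counts are retained internally (never
#' serialised) so distortion can be tested.
#'
#' @param tab A `concordance_table`.
#' @return The table with `sdc = TRUE`, suppressed/rounded `counts`, and
#'   the original counts in `raw_counts`.
#' @export
apply_sdc <- function(tab) {
  stopifnot(inherits(tab, "concordance_table"))
  if (isTRUE(tab$sdc)) return(tab)
  out <- tab
  out$raw_counts <- tab$counts
  out$counts <- .sdc_cells(tab$counts)
  out$excluded_special <- .sdc_cells(tab$excluded_special)
  out$sdc <- TRUE
  out
}

#' Agreement metrics from a disclosure-controlled table
#'
#' Identical formulas to [agreement()], computed on the rounded and
#' suppressed values; suppressed cells contribute zero to numerators and
#' denominators. A column suppressed in full yields an undefined (`NA`)
#' metric.
#'
#' @param tab A `concordance_table` with SDC applied.
#' @return An `agreement_report`.
#' @export
agreement_from_sdc <- function(tab) {
  stopifnot(inherits(tab, "concordance_table"))
  if (!isTRUE(tab$sdc)) {
    stop("apply_sdc() first; this table holds raw counts", call. = FALSE)
  }
  .agreement_impl(tab$counts, tab$resolution, tab$source, sdc = TRUE)
}

#' Write a crosstab to CSV
#'
#' Census categories as rows, source categories as columns; suppressed
#' cells are serialised as the `suppressed` token.
#'
#' @param tab A `concordance_table` (raw or SDC).
#' @param path Output path.
#' @param suppressed Token written for suppressed cells (default `"[c]"`).
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(tab, path, suppressed = "[c]") {
  m <- tab$counts
  chr <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- suppressed
  df <- data.frame(census_code = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
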
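# Long-format episodic records and the gold-standard table.
#
# One observation per row across all five sub-sources; the single-record
# asset (ECIA) is constrained to one row per person at derivation time.
# Dates are date-only: the tie-breaking rules below assume no finer
# resolution exists.

.SOURCES <- c("GDPPR", "HES", "TT", "ECIA")

.SUB_SOURCES <- list(
  GDPPR = c("GP_JOURNAL", "GP_PATIENT"),
  HES   = c("HES_APC", "HES_AE_ECDS", "HES_OP"),
  TT    = c("TT_MAIN"),
  ECIA  = c("ECIA_MAIN")
)

.RECORD_COLS <- c("person_id", "source", "sub_source", "record_date",
                  "raw_code", "supplier", "year")

#' Validate a table of episodic ethnicity records
#'
#' Checks the long-format record schema: required columns, recognised
#' source/sub-source pairs, parseable dates, and the talking-therapies rule
#' that `supplier` and `year` are present if and only if `source == "TT"`.
#'
#' @param records A data.frame of episodic records.
#' @return The validated records (dates coerced to `Date`), invisibly
#'   returned as a data.frame.
#' @export
validate_records <- function(records) {
  if (!all(.RECORD_COLS %in% names(records))) {
    stop("records must have columns ", paste(.RECORD_COLS, collapse = ","),
         call. = FALSE)
  }
  records <- as.data.frame(records)[, .RECORD_COLS]
  rowid <- seq_len(nrow(records))
  bad_src <- !(records$source %in% .SOURCES)
  if (any(bad_src)) {
    stop("unknown source at row(s) ",
         paste(head(rowid[bad_src], 5L), collapse = ", "), call. = FALSE)
  }
  ok_sub <- mapply(function(s, ss) ss %in% .SUB_SOURCES[[s]],
                   records$source, records$sub_source)
  if (nrow(records) && any(!ok_sub)) {
    stop("sub_source inconsistent with source at row(s) ",
         paste(head(rowid[!ok_sub], 5L), collapse = ", "), call. = FALSE)
  }
  if (!inherits(records$record_date, "Date")) {
    d <- as.Date(as.character(records$record_date), format = "%Y-%m-%d")
    if (anyNA(d) & nrow(records)) {
      stop("unparseable record_date at row(s) ",
           paste(head(rowid[is.na(d)], 5L), collapse = ", "), call. = FALSE)
    }
    records$record_date <- d
  }
  is_tt <- records$source == "TT"
  sup_missing <- is.na(records$supplier) | records$supplier == ""
  yr <- suppressWarnings(as.integer(records$year))
  if (any(is_tt & (sup_missing | is.na(yr)))) {
    stop("TT row(s) missing supplier/year: row(s) ",
         paste(head(rowid[is_tt & (sup_missing | is.na(yr))], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is_tt & !(sup_missing & is.na(yr)))) {
    stop("supplier/year must be empty for non-TT row(s): row(s) ",
         paste(head(rowid[!is_tt & !(sup_missing & is.na(yr))], 5L),
               collapse = ", "), call. = FALSE)
  }
  records$supplier[!is_tt] <- NA_character_
  records$supplier[is_tt & records$supplier == ""] <- NA_character_
  records$year <- yr
  invisible(records)
}

#' Read episodic ethnicity records from CSV
#'
#' Expects a header
#' `person_id,source,sub_source,record_date,raw_code,supplier,year` with
#' ISO-8601 dates; every row is validated (see [validate_records()]) and
#' errors name the offending row.
#'
#' @param path CSV path.
#' @return A data.frame of validated records.
#' @export
read_records <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(person_id = "character", source = "character",
                                 sub_source = "character",
                                 record_date = "character",
                                 raw_code = "character",
                                 supplier = "character", year = "character"),
                  na.strings = "")
  validate_records(tab)
}

#' Write episodic ethnicity records to CSV
#'
#' @param records Validated records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  out <- records
  out$record_date <- format(out$record_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read the gold-standard (census) table
#'
#' One row per person with a substantive census category; persons who did
#' not answer the census ethnicity question are excluded upstream and must
#' not appear.
#'
#' @param path CSV path with header `person_id,census_code`.
#' @param vocab Census vocabulary used to validate codes (defaults to the
#'   packaged 19-category system).
#' @return A data.frame with columns `person_id`, `census_code`.
#' @export
read_gold <- function(path, vocab = load_vocabulary("census21_19")) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_gold(tab, vocab)
}

#' Validate a gold-standard table
#'
#' @inheritParams read_gold
#' @param gold A data.frame with columns `person_id`, `census_code`.
#' @return The validated table, invisibly.
#' @export
validate_gold <- function(gold, vocab = load_vocabulary("census21_19")) {
  if (!all(c("person_id", "census_code") %in% names(gold))) {
    stop("gold table must have columns person_id,census_code", call. = FALSE)
  }
  gold <- as.data.frame(gold)[, c("person_id", "census_code")]
  if (anyDuplicated(gold$person_id)) {
    stop("gold table must have one row per person; duplicated: ",
         paste(head(unique(gold$person_id[duplicated(gold$person_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  bad <- !(gold$census_code %in% substantive_codes(vocab))
  if (any(bad)) {
    stop("non-substantive or unknown census code(s): ",
         paste(head(unique(gold$census_code[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(gold)
}

#' Write the gold-standard table to CSV
#'
#' @param gold Gold-standard table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  write.csv(gold[, c("person_id", "census_code")], path,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Restrict records to those on or before a cutoff date
#'
#' A record dated exactly on the cutoff is retained ("up to and including").
#' Row order is preserved and the filter is idempotent.
#'
#' @param records Validated records.
#' @param cutoff A `Date` (or ISO string).
#' @return The retained records.
#' @export
filter_cutoff <- function(records, cutoff) {
  cutoff <- as.Date(cutoff)
  stopifnot(length(cutoff) == 1L, !is.na(cutoff))
  records[records$record_date <= cutoff, , drop = FALSE]
}

#' Restrict records to a back-series start date
#'
#' Retains records dated on or after `start`; used for the sensitivity
#' analysis that truncates the back series of episodic data. Commutes with
#' [filter_cutoff()].
#'
#' @param records Validated records.
#' @param start A `Date` (or ISO string).
#' @return The retained records.
#' @export
filter_backseries <- function(records, start) {
  start <- as.Date(start)
  stopifnot(length(start) == 1L, !is.na(start))
  records[records$record_date >= start, , drop = FALSE]
}

#' Resolve raw record codes to vocabulary categories
#'
#' Adds a `category` column: GP-Journal rows are resolved through the
#' clinical-code lookup (unknown codes are an error), all other sub-sources
#' carry fixed-field vocabulary codes directly. Categories are validated
#' against the source's vocabulary (the 18-category system for GDPPR/ECIA,
#' the 16-category system for HES/TT); the derived-only `UNRESOLVED` marker
#' may never appear as an input code.
#'
#' @param records Validated records.
#' @param lookup A `code_lookup` (defaults to the packaged synthetic table).
#' @return The records with an additional `category` column.
#' @export
resolve_categories <- function(records, lookup = load_code_lookup()) {
  records <- validate_records(records)
  cat <- records$raw_code
  isj <- records$sub_source == "GP_JOURNAL"
  if (any(isj)) cat[isj] <- resolve_lookup(records$raw_code[isj], lookup)
  v18 <- load_vocabulary("nhs_18")
  v16 <- load_vocabulary("nhs_16")
  ok18 <- setdiff(v18$table$code, "UNRESOLVED")
  ok16 <- setdiff(v16$table$code, "UNRESOLVED")
  in18 <- records$source %in% c("GDPPR", "ECIA")
  bad <- (in18 & !(cat %in% ok18)) | (!in18 & !(cat %in% ok16))
  if (any(bad)) {
    stop("invalid category code(s) for source vocabulary: ",
         paste(head(unique(cat[bad]), 5L), collapse = ", "), call. = FALSE)
  }
  records$category <- cat
  records
}
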
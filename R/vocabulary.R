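# Category systems and harmonisation.
#
# Three vocabularies are shipped: the 19-category census system (which adds
# Roma), the 18-category system used by GP extracts and the single-record
# asset, and the 16-category system used by hospital episodes and talking
# therapies (which lacks Gypsy or Irish Traveller and Arab). All substantive
# codes are expressed as stable machine tokens; display labels are carried
# separately and are never used as join keys.

# The harmonised 18-category comparison scheme (census-2021 aligned: Chinese
# sits under Asian at the 5-category level even though health sources file it
# under "Other" in their raw layouts).
.HARMONIZED18 <- c(
  "WHITE_BRITISH", "WHITE_IRISH", "GYPSY_IRISH_TRAVELLER", "WHITE_OTHER",
  "MIXED_WHITE_BLACK_CARIBBEAN", "MIXED_WHITE_BLACK_AFRICAN",
  "MIXED_WHITE_ASIAN", "MIXED_OTHER",
  "INDIAN", "PAKISTANI", "BANGLADESHI", "CHINESE", "ASIAN_OTHER",
  "BLACK_AFRICAN", "BLACK_CARIBBEAN", "BLACK_OTHER",
  "ARAB", "ANY_OTHER"
)

.CODE5 <- c("WHITE", "MIXED", "ASIAN", "BLACK", "OTHER")

.H18_TO_5 <- c(
  WHITE_BRITISH = "WHITE", WHITE_IRISH = "WHITE",
  GYPSY_IRISH_TRAVELLER = "WHITE", WHITE_OTHER = "WHITE",
  MIXED_WHITE_BLACK_CARIBBEAN = "MIXED", MIXED_WHITE_BLACK_AFRICAN = "MIXED",
  MIXED_WHITE_ASIAN = "MIXED", MIXED_OTHER = "MIXED",
  INDIAN = "ASIAN", PAKISTANI = "ASIAN", BANGLADESHI = "ASIAN",
  CHINESE = "ASIAN", ASIAN_OTHER = "ASIAN",
  BLACK_AFRICAN = "BLACK", BLACK_CARIBBEAN = "BLACK", BLACK_OTHER = "BLACK",
  ARAB = "OTHER", ANY_OTHER = "OTHER"
)

# Non-substantive codes that can appear in records or derivations.
.SPECIAL_CODES <- c(
  "NOT_STATED", "NOT_KNOWN", "UNRESOLVED",
  "DATA_NOT_RECORDED", "VALUE_OUTSIDE_NATIONAL_CODE"
)

.VOCAB_CARDINALITY <- c(census21_19 = 19L, nhs_18 = 18L, nhs_16 = 16L)

#' Special (non-substantive) category codes
#'
#' Codes that do not denote an ethnic group: missing-data markers
#' (`NOT_STATED`, `NOT_KNOWN`, `DATA_NOT_RECORDED`,
#' `VALUE_OUTSIDE_NATIONAL_CODE`) and the `UNRESOLVED` marker assigned when
#' tie-breaking rules cannot select a unique category.
#'
#' @return Character vector of special codes.
#' @export
special_codes <- function() .SPECIAL_CODES

#' The harmonised 18-category scheme
#'
#' @return Character vector of the 18 harmonised category tokens.
#' @export
harmonized18_codes <- function() .HARMONIZED18

#' Load a category vocabulary
#'
#' Reads a vocabulary definition (CSV with columns
#' `code,label,harmonized18,code5,special`) and validates it: no duplicate
#' codes, every substantive code mapped to exactly one harmonised
#' 18-category token (or explicitly declared to have no counterpart with the
#' sentinel `NONE`, as for the census Roma category), special codes never
#' mapped, and — for the three shipped systems — the documented cardinalities
#' (19 census categories including Roma; 18 without Roma; 16 additionally
#' lacking Gypsy or Irish Traveller and Arab).
#'
#' @param name One of `"census21_19"`, `"nhs_18"`, `"nhs_16"`, or an
#'   arbitrary name when `config` supplies a custom file.
#' @param config Optional path to a vocabulary CSV overriding the packaged
#'   definition.
#' @return An object of class `ethnicity_vocabulary`.
#' @examples
#' v <- load_vocabulary("nhs_16")
#' length(substantive_codes(v))  # 16
#' @export
load_vocabulary <- function(name, config = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  path <- config
  if (is.null(path)) {
    if (!name %in% names(.VOCAB_CARDINALITY)) {
      stop("no packaged vocabulary named '", name,
           "'; supply `config` for a custom vocabulary", call. = FALSE)
    }
    path <- system.file("extdata", paste0("vocab_", name, ".csv"),
                        package = "ethnoconcord", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("vocabulary file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = character())
  validate_vocabulary_table(tab, name)
  tab$special <- toupper(tab$special) == "TRUE"
  structure(
    list(name = name, table = tab),
    class = "ethnicity_vocabulary"
  )
}

validate_vocabulary_table <- function(tab, name) {
  need <- c("code", "label", "harmonized18", "code5", "special")
  if (!all(need %in% names(tab))) {
    stop("vocabulary file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (anyDuplicated(tab$code)) {
    stop("duplicate codes in vocabulary: ",
         paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "),
         call. = FALSE)
  }
  special <- toupper(tab$special) == "TRUE"
  sub <- tab[!special, , drop = FALSE]
  if (any(sub$harmonized18 == "")) {
    stop("substantive code(s) with no harmonised mapping: ",
         paste(sub$code[sub$harmonized18 == ""], collapse = ", "),
         "; use the sentinel NONE to declare a deliberate absence",
         call. = FALSE)
  }
  bad <- !(sub$harmonized18 %in% c(.HARMONIZED18, "NONE"))
  if (any(bad)) {
    stop("unknown harmonised target(s): ",
         paste(unique(sub$harmonized18[bad]), collapse = ", "), call. = FALSE)
  }
  mapped <- sub$harmonized18[sub$harmonized18 != "NONE"]
  if (anyDuplicated(mapped)) {
    stop("two substantive codes map to the same harmonised category: ",
         paste(unique(mapped[duplicated(mapped)]), collapse = ", "),
         call. = FALSE)
  }
  badc5 <- sub$code5 != "" & !(sub$code5 %in% .CODE5)
  if (any(badc5)) {
    stop("unknown 5-category group(s): ",
         paste(unique(sub$code5[badc5]), collapse = ", "), call. = FALSE)
  }
  if (any(special & tab$harmonized18 != "")) {
    stop("special codes must not carry a harmonised mapping", call. = FALSE)
  }
  if (name %in% names(.VOCAB_CARDINALITY)) {
    expect <- .VOCAB_CARDINALITY[[name]]
    if (nrow(sub) != expect) {
      stop("vocabulary '", name, "' must have exactly ", expect,
           " substantive categories, found ", nrow(sub), call. = FALSE)
    }
    if (name == "nhs_16" &&
        any(c("GYPSY_IRISH_TRAVELLER", "ARAB") %in% sub$code)) {
      stop("nhs_16 must not contain GYPSY_IRISH_TRAVELLER or ARAB",
           call. = FALSE)
    }
    if (name != "census21_19" && "ROMA" %in% sub$code) {
      stop("Roma exists only in the census vocabulary", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.ethnicity_vocabulary <- function(x, ...) {
  n_sub <- length(substantive_codes(x))
  cat("<ethnicity_vocabulary> ", x$name, ": ", n_sub, " substantive + ",
      sum(x$table$special), " special categories\n", sep = "")
  invisible(x)
}

#' Write a vocabulary back to CSV
#'
#' Inverse of [load_vocabulary()]; the written file re-loads to an identical
#' vocabulary.
#'
#' @param vocab An `ethnicity_vocabulary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "ethnicity_vocabulary"))
  tab <- vocab$table
  tab$special <- ifelse(tab$special, "TRUE", "FALSE")
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Substantive codes of a vocabulary
#'
#' @param vocab An `ethnicity_vocabulary`.
#' @return Character vector of the vocabulary's substantive category codes.
#' @export
substantive_codes <- function(vocab) {
  stopifnot(inherits(vocab, "ethnicity_vocabulary"))
  vocab$table$code[!vocab$table$special]
}

#' Align source categories to the census comparison scheme
#'
#' Maps category codes of any vocabulary onto the harmonised 18-category
#' scheme used for census comparison, together with the 5-category collapse.
#' Special codes (Not Stated, Not Known, Unresolved, Data Not Recorded,
#' Value Outside of National Code) are flagged rather than mapped; census
#' categories with no counterpart in any health vocabulary (Roma) return an
#' absent (`NA`) harmonised code.
#'
#' @param code Character vector of codes belonging to `vocab`.
#' @param vocab The `ethnicity_vocabulary` the codes belong to.
#' @return A data.frame with columns `code`, `code18`, `code5`, `special`.
#'   `code18`/`code5` are `NA` for special codes and for declared absences.
#' @examples
#' v <- load_vocabulary("nhs_18")
#' align_to_census(c("WHITE_BRITISH", "NOT_STATED"), v)
#' @export
align_to_census <- function(code, vocab) {
  stopifnot(inherits(vocab, "ethnicity_vocabulary"))
  idx <- match(code, vocab$table$code)
  if (anyNA(idx)) {
    stop("unknown code(s) for vocabulary '", vocab$name, "': ",
         paste(unique(code[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  h18 <- vocab$table$harmonized18[idx]
  h18[h18 %in% c("", "NONE")] <- NA_character_
  sp <- vocab$table$special[idx]
  h18[sp] <- NA_character_
  data.frame(
    code = code,
    code18 = h18,
    code5 = ifelse(is.na(h18),
                   ifelse(sp, NA_character_, vocab$table$code5[idx]),
                   unname(.H18_TO_5[h18])),
    special = sp,
    stringsAsFactors = FALSE
  )
}

#' Collapse harmonised 18-category codes to the 5-category scheme
#'
#' Deterministic total map of the 18 harmonised categories onto
#' \{White, Mixed, Asian, Black, Other\}. Chinese collapses under Asian,
#' following the census-2021 alignment.
#'
#' @param code18 Character vector of harmonised 18-category codes.
#' @return Character vector of 5-category group codes.
#' @examples
#' collapse5(c("BANGLADESHI", "WHITE_BRITISH"))  # "ASIAN" "WHITE"
#' @export
collapse5 <- function(code18) {
  out <- .H18_TO_5[code18]
  if (anyNA(out)) {
    stop("collapse5() is defined only for substantive harmonised codes; got: ",
         paste(unique(code18[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Load a clinical code to category lookup
#'
#' GP-Journal records carry clinical codes rather than fixed-field category
#' codes; this lookup resolves them. The packaged table is a small synthetic
#' illustration (the codes are invented, not a real clinical terminology);
#' real deployments supply their own file with columns
#' `source_code,category`.
#'
#' @param path Optional path to a lookup CSV; defaults to the packaged
#'   synthetic table.
#' @return A data.frame with columns `source_code`, `category`, of class
#'   `code_lookup`.
#' @export
load_code_lookup <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_gp_journal_code_lookup.csv",
                        package = "ethnoconcord", mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("source_code", "category") %in% names(tab))) {
    stop("code lookup must have columns source_code,category", call. = FALSE)
  }
  if (anyDuplicated(tab$source_code)) {
    stop("duplicate source_code in lookup", call. = FALSE)
  }
  nhs18 <- load_vocabulary("nhs_18")
  bad <- !(tab$category %in% nhs18$table$code)
  if (any(bad)) {
    stop("lookup maps to unknown categories: ",
         paste(unique(tab$category[bad]), collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("code_lookup", "data.frame")
  tab
}

# Resolve a vector of GP-Journal clinical codes to categories; unknown codes
# are an error, never silently dropped.
resolve_lookup <- function(codes, lookup) {
  idx <- match(codes, lookup$source_code)
  if (anyNA(idx)) {
    stop("GP-Journal clinical code(s) absent from the code lookup: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  lookup$category[idx]
}
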
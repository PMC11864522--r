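# Fixture builders: records are always constructed in code, never stored.

# one or more record rows with defaults suitable for most tests
rec <- function(person = "P1", source = "GDPPR", sub = "GP_PATIENT",
                date = "2021-01-01", code = "WHITE_BRITISH",
                supplier = NA_character_, year = NA_integer_) {
  n <- max(lengths(list(person, sub, date, code, supplier, year)))
  data.frame(
    person_id = rep_len(person, n), source = rep_len(source, n),
    sub_source = rep_len(sub, n),
    record_date = as.Date(rep_len(date, n)),
    raw_code = rep_len(code, n),
    supplier = rep_len(supplier, n),
    year = rep_len(as.integer(year), n),
    stringsAsFactors = FALSE
  )
}

tt_rec <- function(person = "P1", date = "2021-01-01", code = "WHITE_BRITISH",
                   supplier = "S1", year = NULL) {
  date <- as.Date(date)
  if (is.null(year)) year <- as.integer(format(date, "%Y"))
  rec(person, "TT", "TT_MAIN", date, code, supplier, year)
}

# random single-person record sets of size <= max_n over a small alphabet of
# categories / dates / sub-sources, deliberately collision-heavy so every
# tie and priority path is exercised; categories are pre-resolved (the
# `category` column is set) so no clinical-code lookup is involved
random_person_records <- function(source, max_n = 8L,
                                  person = "PX") {
  out <- random_person_records_raw(source, max_n, person)
  out$category <- out$raw_code
  out
}

random_person_records_raw <- function(source, max_n = 8L,
                                      person = "PX") {
  n <- sample.int(max_n, 1L)
  cats <- c("WHITE_BRITISH", "INDIAN", "BLACK_AFRICAN", "ANY_OTHER",
            "NOT_STATED", "NOT_KNOWN")
  dates <- as.Date("2021-06-01") + 0:2
  if (source == "GDPPR") {
    rec(person, "GDPPR",
        sample(c("GP_JOURNAL", "GP_PATIENT"), n, replace = TRUE),
        sample(dates, n, replace = TRUE),
        sample(cats, n, replace = TRUE))
  } else if (source == "HES") {
    rec(person, "HES",
        sample(c("HES_APC", "HES_AE_ECDS", "HES_OP"), n, replace = TRUE),
        sample(dates, n, replace = TRUE),
        sample(cats, n, replace = TRUE))
  } else if (source == "TT") {
    tt_rec(person,
           sample(dates, n, replace = TRUE),
           sample(c(cats, "DATA_NOT_RECORDED",
                    "VALUE_OUTSIDE_NATIONAL_CODE"), n, replace = TRUE),
           sample(c("S1", "S2"), n, replace = TRUE),
           sample(c(2020L, 2021L), n, replace = TRUE))
  } else {
    rec(person, "ECIA", "ECIA_MAIN", sample(dates, 1L),
        sample(cats, 1L))
  }
}

# bulk variant: n_sets independent single-person record sets in one frame,
# same collision-heavy alphabet as random_person_records
random_records_bulk <- function(source, n_sets, max_n = 8L) {
  sizes <- sample.int(max_n, n_sets, replace = TRUE)
  total <- sum(sizes)
  cats <- c("WHITE_BRITISH", "INDIAN", "BLACK_AFRICAN", "ANY_OTHER",
            "NOT_STATED", "NOT_KNOWN")
  if (source == "TT") cats <- c(cats, "DATA_NOT_RECORDED",
                                "VALUE_OUTSIDE_NATIONAL_CODE")
  dates <- as.Date("2021-06-01") + 0:2
  subs <- switch(source,
                 GDPPR = c("GP_JOURNAL", "GP_PATIENT"),
                 HES = c("HES_APC", "HES_AE_ECDS", "HES_OP"),
                 TT = "TT_MAIN")
  out <- data.frame(
    person_id = rep(sprintf("B%05d", seq_len(n_sets)), sizes),
    source = source,
    sub_source = sample(subs, total, replace = TRUE),
    record_date = sample(dates, total, replace = TRUE),
    raw_code = sample(cats, total, replace = TRUE),
    supplier = if (source == "TT") sample(c("S1", "S2"), total, TRUE)
    else NA_character_,
    year = if (source == "TT") sample(c(2020L, 2021L), total, TRUE)
    else NA_integer_,
    stringsAsFactors = FALSE
  )
  out$category <- out$raw_code
  out
}

# GP-Journal clinical codes for a category (packaged synthetic lookup)
journal_code <- function(category, which = 1L) {
  lk <- ethnoconcord::load_code_lookup()
  lk$source_code[lk$category == category][which]
}

# small deterministic gold table
gold_for <- function(persons, codes) {
  data.frame(person_id = persons, census_code = codes,
             stringsAsFactors = FALSE)
}

# Six-person GDPPR fixture whose reallocation cascade has been worked out
# by hand from the rules:
#  P1 latest Not Known over an older Indian       -> Indian from l1 on
#  P2 latest Any Other over an older Not Known    -> trigger only at l2/l3;
#     emptied history, Any Other present -> destination Any Other
#  P3 Not Known only                              -> never reallocated
#  P4 Not Known latest, Any Other and Not Stated older
#     l1: re-derive over {NS@2019, AO@2020} -> Any Other (most recent)
#     l2: re-derive over {NS@2019}          -> Not Stated
#     l3: emptied, Any Other in history     -> Any Other
#  P5 latest Not Stated over an older Indian      -> Indian only at l3
#  P6 same-date conflict -> Unresolved, never a trigger
cascade_fixture <- function() {
  recs <- rbind(
    rec("P1", date = c("2020-01-01", "2021-01-01"),
        code = c("INDIAN", "NOT_KNOWN")),
    rec("P2", date = c("2020-01-01", "2021-01-01"),
        code = c("NOT_KNOWN", "ANY_OTHER")),
    rec("P3", date = c("2020-01-01", "2021-01-01"),
        code = c("NOT_KNOWN", "NOT_KNOWN")),
    rec("P4", date = c("2019-01-01", "2020-01-01", "2021-01-01"),
        code = c("NOT_STATED", "ANY_OTHER", "NOT_KNOWN")),
    rec("P5", date = c("2019-01-01", "2021-01-01"),
        code = c("INDIAN", "NOT_STATED")),
    rec("P6", date = c("2021-01-01", "2021-01-01"),
        code = c("INDIAN", "PAKISTANI"))
  )
  recs$category <- recs$raw_code
  expected <- list(
    none = c(P1 = "NOT_KNOWN", P2 = "ANY_OTHER", P3 = "NOT_KNOWN",
             P4 = "NOT_KNOWN", P5 = "NOT_STATED", P6 = "UNRESOLVED"),
    l1 = c(P1 = "INDIAN", P2 = "ANY_OTHER", P3 = "NOT_KNOWN",
           P4 = "ANY_OTHER", P5 = "NOT_STATED", P6 = "UNRESOLVED"),
    l2 = c(P1 = "INDIAN", P2 = "ANY_OTHER", P3 = "NOT_KNOWN",
           P4 = "NOT_STATED", P5 = "NOT_STATED", P6 = "UNRESOLVED"),
    l3 = c(P1 = "INDIAN", P2 = "ANY_OTHER", P3 = "NOT_KNOWN",
           P4 = "ANY_OTHER", P5 = "INDIAN", P6 = "UNRESOLVED")
  )
  list(records = recs, expected = expected)
}
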
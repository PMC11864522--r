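# Independent brute-force derivation oracle.
#
# Deliberately written in a different style from the package internals:
# plain loops, explicit sorting and counting on one person's records at a
# time. Takes a data.frame with columns sub_source, record_date, category
# (and year for TT) and returns the derived category string.

oracle_recency_gdppr <- function(df) {
  latest <- df[df$record_date == max(df$record_date), , drop = FALSE]
  if (length(unique(latest$category)) == 1L) return(latest$category[1L])
  win <- if ("GP_JOURNAL" %in% latest$sub_source) "GP_JOURNAL"
         else "GP_PATIENT"
  wc <- unique(latest$category[latest$sub_source == win])
  if (length(wc) == 1L) wc else "UNRESOLVED"
}

oracle_modal_table <- function(cats) {
  tab <- sort(table(cats), decreasing = TRUE)
  top <- names(tab)[tab == tab[1L]]
  if (length(top) == 1L) top else "UNRESOLVED"
}

oracle_modal_gdppr <- function(df) {
  j <- df[df$sub_source == "GP_JOURNAL", , drop = FALSE]
  if (nrow(j) > 0L) oracle_modal_table(j$category)
  else oracle_modal_table(df$category[df$sub_source == "GP_PATIENT"])
}

oracle_recency_hes <- function(df) {
  latest <- df[df$record_date == max(df$record_date), , drop = FALSE]
  for (ss in c("HES_APC", "HES_AE_ECDS", "HES_OP")) {
    if (ss %in% latest$sub_source) {
      wc <- unique(latest$category[latest$sub_source == ss])
      return(if (length(wc) == 1L) wc else "UNRESOLVED")
    }
  }
}

oracle_modal_hes <- function(df) oracle_modal_table(df$category)

oracle_recency_tt <- function(df) {
  cat <- df$category
  cat[cat %in% c("DATA_NOT_RECORDED", "VALUE_OUTSIDE_NATIONAL_CODE")] <-
    "NOT_KNOWN"
  df$category <- cat
  df <- df[df$year == max(df$year), , drop = FALSE]
  df <- df[df$record_date == max(df$record_date), , drop = FALSE]
  wc <- unique(df$category)
  if (length(wc) == 1L) wc else "UNRESOLVED"
}

oracle_derive <- function(df, source, method) {
  switch(paste(source, method),
         "GDPPR recency" = oracle_recency_gdppr(df),
         "GDPPR modal" = oracle_modal_gdppr(df),
         "HES recency" = oracle_recency_hes(df),
         "HES modal" = oracle_modal_hes(df),
         "TT recency" = oracle_recency_tt(df),
         stop("no oracle for ", source, " ", method))
}

# batch comparison: build n_sets random single-person record sets, derive
# them all in one vectorised call, and compare person by person with the
# oracle; returns the number of mismatches
oracle_mismatches <- function(source, method, n_sets, max_n = 8L) {
  sets <- lapply(seq_len(n_sets), function(i)
    random_person_records(source, max_n, person = sprintf("P%05d", i)))
  all_recs <- do.call(rbind, sets)
  got <- ethnoconcord::derive_ethnicity(all_recs, source, method)
  expected <- vapply(sets, oracle_derive, character(1),
                     source = source, method = method)
  names(expected) <- vapply(sets, function(s) s$person_id[1L], character(1))
  sum(got$category != expected[got$person_id])
}
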
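test_that("GDPPR recency: latest date wins, GP-Journal has same-date priority, ties are Unresolved", {
  # unique latest date
  r <- rec(person = "P1", date = c("2019-03-01", "2021-03-01"),
           code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_gdppr(r)$category, "PAKISTANI")

  # same-date cross-table conflict: journal wins
  r <- rec(person = "P1", sub = c("GP_JOURNAL", "GP_PATIENT"),
           date = "2021-03-01", code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_gdppr(r)$category, "INDIAN")

  # conflict persists within the winning table
  r <- rec(person = "P1", sub = "GP_JOURNAL", date = "2021-03-01",
           code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_gdppr(r)$category, "UNRESOLVED")

  # an older journal record never outranks a newer patient record
  r <- rec(person = "P1", sub = c("GP_JOURNAL", "GP_PATIENT"),
           date = c("2019-01-01", "2021-01-01"),
           code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_gdppr(r)$category, "PAKISTANI")
})

test_that("GDPPR modal: journal-first with table-level fallback; frequency ties are Unresolved", {
  r <- rec(person = "P1", sub = "GP_JOURNAL", date = "2020-01-01",
           code = c("INDIAN", "INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_modal_gdppr(r)$category, "INDIAN")

  r <- rec(person = "P1", sub = "GP_JOURNAL", date = "2020-01-01",
           code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_modal_gdppr(r)$category, "UNRESOLVED")

  # no journal records at all: fall back to the patient table
  r <- rec(person = "P1", sub = "GP_PATIENT", date = "2020-01-01",
           code = c("BANGLADESHI", "BANGLADESHI", "INDIAN"))
  r$category <- r$raw_code
  expect_equal(derive_modal_gdppr(r)$category, "BANGLADESHI")

  # a single journal record pre-empts any number of patient records
  r <- rec(person = "P1", sub = c("GP_JOURNAL", rep("GP_PATIENT", 3)),
           date = "2020-01-01",
           code = c("INDIAN", rep("PAKISTANI", 3)))
  r$category <- r$raw_code
  expect_equal(derive_modal_gdppr(r)$category, "INDIAN")
})

test_that("GDPPR modal counts resolved categories, so distinct codes for one category reinforce it", {
  r <- rec(person = "P1", sub = "GP_JOURNAL", date = "2020-01-01",
           code = c(journal_code("INDIAN", 1), journal_code("INDIAN", 2),
                    journal_code("PAKISTANI", 1)))
  expect_equal(derive_modal_gdppr(r)$category, "INDIAN")
})

test_that("HES recency: APC > A&E/ECDS > OP on the latest date only", {
  r <- rec(person = "P1", source = "HES", sub = "HES_OP",
           date = "2021-01-01", code = "INDIAN")
  r$category <- r$raw_code
  expect_equal(derive_recency_hes(r)$category, "INDIAN")

  r <- rec(person = "P1", source = "HES", sub = c("HES_APC", "HES_OP"),
           date = "2021-01-01", code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_hes(r)$category, "INDIAN")

  r <- rec(person = "P1", source = "HES", sub = "HES_APC",
           date = "2021-01-01", code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_hes(r)$category, "UNRESOLVED")

  # priority is confined to the latest date
  r <- rec(person = "P1", source = "HES", sub = c("HES_APC", "HES_OP"),
           date = c("2019-01-01", "2021-01-01"),
           code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_recency_hes(r)$category, "PAKISTANI")
})

test_that("HES modal pools sub-datasets without priority", {
  r <- rec(person = "P1", source = "HES",
           sub = c("HES_APC", "HES_OP", "HES_AE_ECDS"),
           date = "2021-01-01", code = c("INDIAN", "INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_modal_hes(r)$category, "INDIAN")

  r <- rec(person = "P1", source = "HES", sub = c("HES_APC", "HES_OP"),
           date = "2021-01-01", code = c("INDIAN", "PAKISTANI"))
  r$category <- r$raw_code
  expect_equal(derive_modal_hes(r)$category, "UNRESOLVED")
})

test_that("TT recency: most recent supplier within the most recent year; missing-data synonyms become Not Known", {
  r <- tt_rec(code = "INDIAN")
  expect_equal(derive_recency_tt(r)$category, "INDIAN")

  r <- tt_rec(code = "DATA_NOT_RECORDED")
  expect_equal(derive_recency_tt(r)$category, "NOT_KNOWN")
  r <- tt_rec(code = "VALUE_OUTSIDE_NATIONAL_CODE")
  expect_equal(derive_recency_tt(r)$category, "NOT_KNOWN")

  # two suppliers in the max year: the later-dated supplier's record wins
  r <- rbind(tt_rec(date = "2021-02-01", code = "INDIAN", supplier = "S1"),
             tt_rec(date = "2021-05-01", code = "PAKISTANI", supplier = "S2"))
  expect_equal(derive_recency_tt(r)$category, "PAKISTANI")

  # an older year never wins, whatever its dates
  r <- rbind(tt_rec(date = "2020-12-31", code = "INDIAN", year = 2021),
             tt_rec(date = "2021-06-01", code = "PAKISTANI", year = 2020))
  expect_equal(derive_recency_tt(r)$category, "INDIAN")

  # conflicting categories on the winning date
  r <- rbind(tt_rec(date = "2021-05-01", code = "INDIAN", supplier = "S1"),
             tt_rec(date = "2021-05-01", code = "PAKISTANI", supplier = "S2"))
  expect_equal(derive_recency_tt(r)$category, "UNRESOLVED")
})

test_that("ECIA passes through its single record and rejects multiples", {
  r <- rec(person = "P1", source = "ECIA", sub = "ECIA_MAIN", code = "INDIAN")
  r$category <- r$raw_code
  expect_equal(derive_ecia(r)$category, "INDIAN")

  r2 <- rbind(r, r)
  expect_error(derive_ecia(r2), "single record")

  # a person with no records is simply absent from the derived table
  d <- derive_ethnicity(r[0, ], "ECIA")
  expect_equal(nrow(d), 0L)
  expect_error(derive_ecia(r[0, ]), "empty record set")
})

test_that("unanimous histories give the same answer under every method", {
  set.seed(5)
  for (i in 1:50) {
    src <- sample(c("GDPPR", "HES", "TT"), 1L)
    r <- random_person_records(src)
    one <- sample(c("INDIAN", "WHITE_BRITISH", "NOT_STATED"), 1L)
    r$category <- one
    methods <- if (src == "TT") "recency" else c("recency", "modal")
    for (m in methods) {
      expect_equal(derive_ethnicity(r, src, m)$category, one,
                   info = paste(src, m, i))
    }
  }
})

test_that("derivation is permutation-invariant and deterministic", {
  set.seed(6)
  for (i in 1:40) {
    src <- sample(c("GDPPR", "HES", "TT"), 1L)
    r <- random_person_records(src)
    m <- if (src == "TT") "recency" else sample(c("recency", "modal"), 1L)
    base <- derive_ethnicity(r, src, m)$category
    shuffled <- r[sample.int(nrow(r)), , drop = FALSE]
    expect_equal(derive_ethnicity(shuffled, src, m)$category, base,
                 info = paste(src, m, i))
    expect_equal(derive_ethnicity(r, src, m)$category, base)
  }
})

test_that("vectorised derivation matches the brute-force oracle on collision-heavy record sets", {
  set.seed(7)
  combos <- list(c("GDPPR", "recency"), c("GDPPR", "modal"),
                 c("HES", "recency"), c("HES", "modal"), c("TT", "recency"))
  for (cm in combos) {
    expect_equal(oracle_mismatches(cm[1], cm[2], n_sets = 400), 0L,
                 info = paste(cm, collapse = " "))
  }
})
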
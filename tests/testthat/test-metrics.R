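derived_tab <- function(persons, cats, source = "GDPPR",
                        method = "recency") {
  data.frame(person_id = persons, source = source, method = method,
             category = cats, stringsAsFactors = FALSE)
}

test_that("crosstab counts pairs and routes special derivations to the excluded tally", {
  d <- derived_tab(sprintf("P%02d", 1:10), rep("INDIAN", 10))
  g <- gold_for(sprintf("P%02d", 1:10), rep("INDIAN", 10))
  tab <- build_crosstab(d, g, "cat18")
  expect_equal(tab$counts["INDIAN", "INDIAN"], 10L)
  expect_equal(sum(tab$counts), 10L)
  expect_equal(sum(tab$excluded_special), 0L)

  d$category[1] <- "UNRESOLVED"
  d$category[2] <- "NOT_STATED"
  tab <- build_crosstab(d, g, "cat18")
  expect_equal(sum(tab$counts), 8L)
  expect_equal(tab$excluded_special[["UNRESOLVED"]], 1L)
  expect_equal(tab$excluded_special[["NOT_STATED"]], 1L)

  # a person with no gold row is counted, not fatal
  d2 <- rbind(d, derived_tab("GHOST", "INDIAN"))
  tab2 <- build_crosstab(d2, g, "cat18")
  expect_equal(tab2$n_unlinked, 1L)
  expect_equal(sum(tab2$counts), 8L)
})

test_that("crosstab counts equal a brute-force group-by on random fixtures", {
  set.seed(41)
  n <- 500
  cats <- c("WHITE_BRITISH", "INDIAN", "BLACK_AFRICAN", "ANY_OTHER",
            "NOT_KNOWN", "UNRESOLVED")
  census <- c("WHITE_BRITISH", "INDIAN", "BLACK_AFRICAN", "ROMA")
  d <- derived_tab(sprintf("P%04d", 1:n), sample(cats, n, TRUE))
  g <- gold_for(sprintf("P%04d", 1:n), sample(census, n, TRUE))
  tab <- build_crosstab(d, g, "cat18")
  # oracle: plain merge + table on the substantive subset
  m <- merge(d, g, by = "person_id")
  m <- m[!(m$category %in% special_codes()), ]
  for (i in seq_len(nrow(m))) {
    expect_true(tab$counts[m$census_code[i], m$category[i]] ==
                  sum(m$census_code == m$census_code[i] &
                        m$category == m$category[i]))
  }
  expect_equal(sum(tab$counts), nrow(m))
})

test_that("agreement, sensitivity and PPV use the documented denominators", {
  # census row A: 90 recorded A, 10 recorded B; nothing else
  d <- derived_tab(sprintf("P%03d", 1:100),
                   c(rep("INDIAN", 90), rep("PAKISTANI", 10)))
  g <- gold_for(sprintf("P%03d", 1:100), rep("INDIAN", 100))
  rep_ <- agreement(build_crosstab(d, g, "cat18"))
  per <- rep_$per_category
  expect_equal(per$sensitivity[per$category == "INDIAN"], 90)   # 90/100
  expect_equal(per$agreement[per$category == "INDIAN"], 100)    # 90/90
  expect_equal(per$agreement[per$category == "PAKISTANI"], 0)   # 0/10
  expect_equal(rep_$overall_agreement, 90)
  # PPV is per-category agreement by construction
  expect_equal(per$ppv, per$agreement)
  # empty columns are undefined, never zero
  expect_true(is.na(per$agreement[per$category == "CHINESE"]))
})

test_that("categories missing from a source vocabulary yield no metric entry", {
  d <- derived_tab("P1", "WHITE_BRITISH", source = "HES")
  g <- gold_for("P1", "WHITE_BRITISH")
  rep_ <- agreement(build_crosstab(d, g, "cat18"))
  expect_false(any(c("ARAB", "GYPSY_IRISH_TRAVELLER", "ROMA") %in%
                     rep_$per_category$category))
  # for an 18-category source, Arab is reportable but Roma still is not
  d2 <- derived_tab("P1", "WHITE_BRITISH", source = "GDPPR")
  rep2 <- agreement(build_crosstab(d2, g, "cat18"))
  expect_true("ARAB" %in% rep2$per_category$category)
  expect_false("ROMA" %in% rep2$per_category$category)
})

test_that("a perfect table scores 100 everywhere defined, at both resolutions", {
  cats <- c("WHITE_BRITISH", "INDIAN", "BLACK_AFRICAN")
  d <- derived_tab(sprintf("P%02d", 1:30), rep(cats, each = 10))
  g <- gold_for(sprintf("P%02d", 1:30), rep(cats, each = 10))
  for (res in c("cat18", "cat5")) {
    rep_ <- agreement(build_crosstab(d, g, res))
    per <- rep_$per_category
    expect_true(all(per$agreement[!is.na(per$agreement)] == 100))
    expect_true(all(per$sensitivity[!is.na(per$sensitivity)] == 100))
    expect_equal(rep_$overall_agreement, 100)
  }
})

test_that("collapsing to 5 categories never lowers overall agreement", {
  set.seed(43)
  for (trial in 1:10) {
    n <- 400
    census <- substantive_codes(load_vocabulary("census21_19"))
    src_cats <- c(substantive_codes(load_vocabulary("nhs_18")),
                  "NOT_KNOWN", "UNRESOLVED")
    d <- derived_tab(sprintf("P%04d", 1:n), sample(src_cats, n, TRUE))
    g <- gold_for(sprintf("P%04d", 1:n), sample(census, n, TRUE))
    a18 <- agreement(build_crosstab(d, g, "cat18"))$overall_agreement
    a5 <- agreement(build_crosstab(d, g, "cat5"))$overall_agreement
    expect_gte(a5, a18)
  }
})

test_that("reports are invariant to person order", {
  set.seed(44)
  n <- 200
  d <- derived_tab(sprintf("P%03d", 1:n),
                   sample(c("INDIAN", "CHINESE", "NOT_STATED"), n, TRUE))
  g <- gold_for(sprintf("P%03d", 1:n),
                sample(c("INDIAN", "CHINESE"), n, TRUE))
  r1 <- agreement(build_crosstab(d, g, "cat18"))
  perm <- sample.int(n)
  r2 <- agreement(build_crosstab(d[perm, ], g[sample.int(n), ], "cat18"))
  expect_equal(r1$per_category, r2$per_category)
  expect_equal(r1$overall_agreement, r2$overall_agreement)
})

test_that("the complete-case restriction is the three-way substantive intersection", {
  dg <- derived_tab(c("P1", "P2", "P3", "P4"),
                    c("INDIAN", "NOT_KNOWN", "INDIAN", "INDIAN"),
                    source = "GDPPR")
  dh <- derived_tab(c("P1", "P2", "P3", "P5"),
                    c("INDIAN", "INDIAN", "UNRESOLVED", "INDIAN"),
                    source = "HES")
  g <- gold_for(c("P1", "P2", "P3"), rep("INDIAN", 3))
  keep <- restrict_complete_case(dg, dh, g)
  expect_setequal(keep, "P1")   # P2 missing in GDPPR, P3 unresolved in HES,
                                # P4/P5 absent from a source or from gold
  # brute force
  oracle <- intersect(
    intersect(dg$person_id[!(dg$category %in% special_codes())],
              dh$person_id[!(dh$category %in% special_codes())]),
    g$person_id)
  expect_setequal(keep, oracle)
})

test_that("tidy reports expose all metrics in long format", {
  d <- derived_tab(c("P1", "P2"), c("INDIAN", "INDIAN"))
  g <- gold_for(c("P1", "P2"), c("INDIAN", "CHINESE"))
  td <- tidy_agreement(agreement(build_crosstab(d, g, "cat18")))
  expect_setequal(unique(td$metric),
                  c("agreement", "sensitivity", "ppv", "overall_agreement"))
  expect_equal(td$value[td$metric == "overall_agreement"], 50)
})
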
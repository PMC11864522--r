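# Preset simulation specifications.
#
# "clean" is the identity limit (no misclassification, no missingness, full
# coverage): every defined agreement metric must be 100%. "paper_like"
# emulates the qualitative structure of English linked census/health data:
# the census population distribution, high White British concordance, very
# low Gypsy or Irish Traveller / Other Black / Any Other Ethnic Group
# concordance, and hospital-episode-heavy missingness. It is shaped on the
# published patterns, not calibrated to reproduce any published figure
# (those depend on confidential linked records). "adversarial" concentrates
# records on few categories and few dates with low within-person
# consistency, to exercise every Unresolved tie path.

# Census-2021-like population shares (percent; normalised on use).
.CENSUS_SHARES <- c(
  WHITE_BRITISH = 75, WHITE_OTHER = 6, INDIAN = 3.2, PAKISTANI = 2.7,
  BLACK_AFRICAN = 2.3, ASIAN_OTHER = 1.6, ANY_OTHER = 1.5, BANGLADESHI = 1.1,
  BLACK_CARIBBEAN = 1.0, WHITE_IRISH = 0.9, MIXED_WHITE_BLACK_CARIBBEAN = 0.8,
  MIXED_WHITE_ASIAN = 0.8, MIXED_OTHER = 0.8, CHINESE = 0.7, ARAB = 0.5,
  BLACK_OTHER = 0.5, MIXED_WHITE_BLACK_AFRICAN = 0.4, ROMA = 0.2,
  GYPSY_IRISH_TRAVELLER = 0.1
)

# Qualitative within-category recording accuracies (high for White British
# and South Asian categories, low for Mixed/Other, very low for Gypsy or
# Irish Traveller and Other Black).
.PAPERLIKE_ACCURACY <- c(
  WHITE_BRITISH = 0.96, BANGLADESHI = 0.93, PAKISTANI = 0.90, INDIAN = 0.86,
  CHINESE = 0.82, BLACK_AFRICAN = 0.80, BLACK_CARIBBEAN = 0.76,
  WHITE_OTHER = 0.75, WHITE_IRISH = 0.72, MIXED_WHITE_BLACK_CARIBBEAN = 0.65,
  MIXED_WHITE_ASIAN = 0.60, MIXED_WHITE_BLACK_AFRICAN = 0.55,
  ASIAN_OTHER = 0.55, MIXED_OTHER = 0.50, ARAB = 0.35, ANY_OTHER = 0.22,
  BLACK_OTHER = 0.15, GYPSY_IRISH_TRAVELLER = 0.05, ROMA = 0
)

#' Preset simulation specifications
#'
#' @param n_persons Number of persons (defaults chosen per preset: the
#'   identity limit needs few persons; the paper-like preset uses 100,000 so
#'   per-category Monte-Carlo error is small even for rare categories).
#' @param seed Integer seed.
#' @return A `simulation_spec`.
#' @name presets
NULL

#' @rdname presets
#' @export
sim_spec_clean <- function(n_persons = 2000, seed = 1) {
  common <- setdiff(.HARMONIZED18, c("GYPSY_IRISH_TRAVELLER", "ARAB"))
  dist <- setNames(rep(1 / length(common), length(common)), common)
  mk <- function(src) list(
    confusion = make_confusion(src, common, accuracy = 1,
                               miss = c(NOT_STATED = 0)),
    records_per_person = if (src == "ECIA") c("1" = 1)
    else c("1" = 0.4, "2" = 0.4, "3" = 0.2)
  )
  simulation_spec(
    n_persons = n_persons, census_dist = dist,
    sources = list(GDPPR = mk("GDPPR"), HES = mk("HES"), TT = mk("TT"),
                   ECIA = mk("ECIA")),
    rho = 1, seed = seed
  )
}

#' @rdname presets
#' @export
sim_spec_paper_like <- function(n_persons = 100000, seed = 1) {
  dist <- .CENSUS_SHARES / sum(.CENSUS_SHARES)
  cats <- names(dist)
  # per-source shifts: hospital episodes code worst, the single-record asset
  # close to primary care, talking therapies best
  acc <- function(f) pmin(.PAPERLIKE_ACCURACY[cats] * f, 0.99)
  sources <- list(
    GDPPR = list(
      confusion = make_confusion("GDPPR", cats, acc(1.00),
                                 miss = c(NOT_STATED = 0.026,
                                          NOT_KNOWN = 0.001)),
      records_per_person = c("0" = 0.05, "1" = 0.20, "2" = 0.30, "3" = 0.25,
                             "4" = 0.15, "5" = 0.05)
    ),
    HES = list(
      confusion = make_confusion("HES", cats, acc(0.90),
                                 miss = c(NOT_STATED = 0.120,
                                          NOT_KNOWN = 0.099)),
      records_per_person = c("0" = 0.12, "1" = 0.25, "2" = 0.28, "3" = 0.20,
                             "4" = 0.10, "5" = 0.05)
    ),
    TT = list(
      confusion = make_confusion("TT", cats, acc(1.02),
                                 miss = c(NOT_STATED = 0.057,
                                          NOT_KNOWN = 0.076,
                                          DATA_NOT_RECORDED = 0.013,
                                          VALUE_OUTSIDE_NATIONAL_CODE = 0.001)),
      records_per_person = c("0" = 0.70, "1" = 0.12, "2" = 0.10, "3" = 0.08)
    ),
    ECIA = list(
      confusion = make_confusion("ECIA", cats, acc(0.98),
                                 miss = c(NOT_STATED = 0)),
      records_per_person = c("0" = 0.03, "1" = 0.97)
    )
  )
  simulation_spec(
    n_persons = n_persons, census_dist = dist, sources = sources,
    rho = 1,
    date_range = as.Date(c("2010-01-01", "2022-01-29")),
    seed = seed
  )
}

#' @rdname presets
#' @export
sim_spec_adversarial <- function(n_persons = 5000, seed = 1) {
  dist <- c(WHITE_BRITISH = 0.4, INDIAN = 0.3, BLACK_AFRICAN = 0.2,
            ANY_OTHER = 0.1)
  mk <- function(src) list(
    confusion = make_confusion(src, names(dist), accuracy = 0.6,
                               miss = c(NOT_STATED = 0.10,
                                        NOT_KNOWN = 0.15)),
    records_per_person = if (src == "ECIA") c("0" = 0.1, "1" = 0.9)
    else c("0" = 0.1, "2" = 0.2, "3" = 0.2, "4" = 0.2, "5" = 0.2, "6" = 0.1)
  )
  simulation_spec(
    n_persons = n_persons, census_dist = dist,
    sources = list(GDPPR = mk("GDPPR"), HES = mk("HES"), TT = mk("TT"),
                   ECIA = mk("ECIA")),
    rho = 0.2,
    date_range = as.Date(c("2021-12-01", "2021-12-31")),
    seed = seed
  )
}
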
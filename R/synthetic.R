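# Synthetic linked gold-standard + episodic records with known
# misclassification structure.
#
# Each person receives a census category from a population distribution;
# each of their records in a source draws a recorded category from that
# source's census-row confusion distribution (which includes Not Stated /
# Not Known mass). A within-person consistency probability rho makes
# successive records repeat the person's first recorded category rather
# than re-draw, so rho = 1 produces unanimous histories whose derivation is
# a single confusion draw — the regime in which analytic sensitivity / PPV
# are available as an oracle.

.SUBSOURCE_DEFAULTS <- list(
  GDPPR = c(GP_JOURNAL = 0.7, GP_PATIENT = 0.3),
  HES = c(HES_APC = 0.4, HES_AE_ECDS = 0.35, HES_OP = 0.25),
  TT = c(TT_MAIN = 1),
  ECIA = c(ECIA_MAIN = 1)
)

.check_dist <- function(p, what, tol = 1e-9) {
  if (is.null(names(p)) || any(names(p) == "") || anyNA(p) || any(p < 0)) {
    stop(what, " must be a named non-negative probability vector",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Specify a synthetic linked-data simulation
#'
#' @param n_persons Number of persons.
#' @param census_dist Named probability vector over census categories.
#' @param sources Named list (`GDPPR`, `HES`, `TT`, `ECIA` — any subset);
#'   each element a list with `confusion` (matrix: census rows by
#'   recorded-category columns, rows summing to 1), `records_per_person`
#'   (named probability vector over `"0","1",...`; mass on `"0"` makes the
#'   person absent from the source), and optionally `subsource_probs`.
#' @param rho Within-person consistency: probability that each record after
#'   the first repeats the person's first recorded category instead of
#'   re-drawing from the confusion distribution.
#' @param date_range Length-2 `Date` vector `[start, cutoff]`; record dates
#'   are uniform over the range (the derivation rules depend only on date
#'   order, not spacing).
#' @param tt_suppliers Number of talking-therapies suppliers.
#' @param seed Mandatory integer seed.
#' @return A validated object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_persons, census_dist, sources, rho = 1,
                            date_range = as.Date(c("2010-01-01",
                                                   "2022-01-29")),
                            tt_suppliers = 3L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_persons >= 1, rho >= 0, rho <= 1, tt_suppliers >= 1)
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || anyNA(date_range) ||
      date_range[1] > date_range[2]) {
    stop("date_range must be an ordered pair of dates", call. = FALSE)
  }
  .check_dist(census_dist, "census_dist")
  cvocab <- load_vocabulary("census21_19")
  if (!all(names(census_dist) %in% substantive_codes(cvocab))) {
    stop("census_dist names must be substantive census codes", call. = FALSE)
  }
  if (!length(sources) || is.null(names(sources)) ||
      !all(names(sources) %in% .SOURCES)) {
    stop("sources must be a named list over GDPPR/HES/TT/ECIA", call. = FALSE)
  }
  for (src in names(sources)) {
    cfg <- sources[[src]]
    C <- cfg$confusion
    if (!is.matrix(C) || is.null(rownames(C)) || is.null(colnames(C))) {
      stop(src, ": confusion must be a matrix with row/col names",
           call. = FALSE)
    }
    if (!setequal(rownames(C), names(census_dist))) {
      stop(src, ": confusion rows must match census_dist categories",
           call. = FALSE)
    }
    svocab <- load_vocabulary(.source_vocab_name(src))
    ok_cols <- setdiff(svocab$table$code, "UNRESOLVED")
    if (!all(colnames(C) %in% ok_cols)) {
      stop(src, ": confusion columns must be codes of ", svocab$name,
           " (UNRESOLVED cannot be recorded)", call. = FALSE)
    }
    for (r in rownames(C)) .check_dist(setNames(C[r, ], colnames(C)),
                                       paste0(src, " confusion row ", r))
    .check_dist(cfg$records_per_person,
                paste0(src, " records_per_person"))
    kk <- suppressWarnings(as.integer(names(cfg$records_per_person)))
    if (anyNA(kk) || any(kk < 0)) {
      stop(src, ": records_per_person names must be counts 0,1,2,...",
           call. = FALSE)
    }
    if (src == "ECIA" && any(kk > 1 & cfg$records_per_person > 0)) {
      stop("ECIA holds at most one record per person", call. = FALSE)
    }
    if (is.null(cfg$subsource_probs)) {
      sources[[src]]$subsource_probs <- .SUBSOURCE_DEFAULTS[[src]]
    } else {
      .check_dist(cfg$subsource_probs, paste0(src, " subsource_probs"))
      if (!all(names(cfg$subsource_probs) %in% .SUB_SOURCES[[src]])) {
        stop(src, ": unknown sub_source in subsource_probs", call. = FALSE)
      }
    }
  }
  structure(
    list(n_persons = as.integer(n_persons), census_dist = census_dist,
         sources = sources, rho = rho, date_range = date_range,
         tt_suppliers = as.integer(tt_suppliers), seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> ", x$n_persons, " persons, sources: ",
      paste(names(x$sources), collapse = ", "), ", rho = ", x$rho,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build a confusion matrix from accuracies and missingness rates
#'
#' Constructs a census-by-recorded confusion matrix for one source: each
#' census row gives probability `accuracy * (1 - missingness)` to its own
#' category (when the source's vocabulary contains it), splits the remaining
#' substantive mass between the other categories of the same 5-category
#' group (weight `1 - other_weight`) and Any Other Ethnic Group (weight
#' `other_weight`, reflecting its over-coding), and assigns the `miss`
#' rates to the missing-data columns. Census categories absent from the
#' source vocabulary (Roma; Arab and Gypsy or Irish Traveller in 16-category
#' sources) have accuracy 0 and all their substantive mass spread.
#'
#' @param source Source name (fixes the recorded vocabulary).
#' @param census_categories Census categories forming the rows.
#' @param accuracy Named vector of within-category accuracies (recycled
#'   scalar allowed).
#' @param miss Named vector of missing-data rates, e.g.
#'   `c(NOT_STATED = 0.03, NOT_KNOWN = 0.01)`.
#' @param other_weight Share of the spread mass routed to `ANY_OTHER`.
#' @return Confusion matrix with rows summing to 1.
#' @export
make_confusion <- function(source, census_categories, accuracy,
                           miss = c(NOT_STATED = 0, NOT_KNOWN = 0),
                           other_weight = 0.3) {
  svocab <- load_vocabulary(.source_vocab_name(source))
  cvocab <- load_vocabulary("census21_19")
  sub_cols <- substantive_codes(svocab)
  miss <- miss[miss > 0]
  if (length(miss) && !all(names(miss) %in% svocab$table$code)) {
    stop("miss names must be special codes of the source vocabulary",
         call. = FALSE)
  }
  cols <- c(sub_cols, names(miss))
  if (length(accuracy) == 1L && is.null(names(accuracy))) {
    accuracy <- setNames(rep(accuracy, length(census_categories)),
                         census_categories)
  }
  cen5 <- align_to_census(census_categories, cvocab)$code5
  src5 <- align_to_census(sub_cols, svocab)$code5
  C <- matrix(0, nrow = length(census_categories), ncol = length(cols),
              dimnames = list(census_categories, cols))
  m_total <- sum(miss)
  for (i in seq_along(census_categories)) {
    k <- census_categories[i]
    sub_mass <- 1 - m_total
    acc <- if (k %in% sub_cols) unname(accuracy[k]) else 0
    if (is.na(acc)) stop("no accuracy given for ", k, call. = FALSE)
    self <- acc * sub_mass
    spread <- sub_mass - self
    group <- setdiff(sub_cols[src5 == cen5[i]], k)
    aoeg <- "ANY_OTHER" %in% sub_cols && k != "ANY_OTHER"
    w_group <- if (aoeg) 1 - other_weight else 1
    if (!length(group)) {
      group <- setdiff(sub_cols, c(k, "ANY_OTHER"))
      w_group <- if (aoeg) 1 - other_weight else 1
    }
    if (k %in% sub_cols) C[k, k] <- self
    C[k, group] <- C[k, group] + spread * w_group / length(group)
    if (aoeg) C[k, "ANY_OTHER"] <- C[k, "ANY_OTHER"] + spread * other_weight
    if (length(miss)) C[k, names(miss)] <- miss
  }
  C
}

#' Generate linked synthetic data
#'
#' Draws a gold-standard table and long-format episodic records according to
#' a [simulation_spec()]. Output is reproducible for a fixed seed. GP-Journal
#' rows carry clinical codes drawn from the packaged synthetic lookup;
#' all other rows carry category codes directly. The returned `truth` table
#' keeps the latent recorded category of every record alongside the census
#' category, for oracle testing.
#'
#' @param spec A `simulation_spec`.
#' @param seed Override of `spec$seed`.
#' @return A list with elements `gold`, `records`, `truth` (data.frames).
#' @export
generate_linked_data <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_persons
  persons <- sprintf("P%07d", seq_len(n))
  census <- sample(names(spec$census_dist), n, replace = TRUE,
                   prob = spec$census_dist)
  gold <- data.frame(person_id = persons, census_code = census,
                     stringsAsFactors = FALSE)
  lookup <- load_code_lookup()
  days <- seq(spec$date_range[1], spec$date_range[2], by = "day")

  blocks <- lapply(names(spec$sources), function(src) {
    cfg <- spec$sources[[src]]
    rpp <- cfg$records_per_person
    k <- as.integer(names(rpp))[sample.int(length(rpp), n, replace = TRUE,
                                           prob = rpp)]
    present <- which(k > 0L)
    if (!length(present)) return(NULL)
    total <- sum(k[present])
    pidx <- rep(present, k[present])
    rid <- sequence(k[present])
    cen_row <- census[pidx]
    # iid draws from the person's confusion row, then within-person repeats
    C <- cfg$confusion
    draw <- character(total)
    for (r in unique(cen_row)) {
      at <- cen_row == r
      draw[at] <- colnames(C)[sample.int(ncol(C), sum(at), replace = TRUE,
                                         prob = C[r, ])]
    }
    first_pos <- match(pidx, pidx)          # index of each person's first row
    repeat_first <- rid > 1L & stats::runif(total) < spec$rho
    category <- ifelse(repeat_first, draw[first_pos], draw)
    dates <- sample(days, total, replace = TRUE)
    sub <- names(cfg$subsource_probs)[
      sample.int(length(cfg$subsource_probs), total, replace = TRUE,
                 prob = cfg$subsource_probs)]
    raw <- category
    isj <- sub == "GP_JOURNAL"
    if (any(isj)) {
      # invert the lookup: pick one clinical code per drawn category,
      # uniformly among the codes mapping to it
      cb <- split(lookup$source_code, lookup$category)
      wid <- max(lengths(cb))
      codemat <- do.call(rbind, lapply(cb, function(x) rep_len(x, wid)))
      rownames(codemat) <- names(cb)
      sel <- match(category[isj], rownames(codemat))
      pick <- sample.int(wid, sum(isj), replace = TRUE)
      pick <- pmin(pick, lengths(cb)[sel])
      raw[isj] <- codemat[cbind(sel, pick)]
    }
    data.frame(
      person_id = persons[pidx], source = src, sub_source = sub,
      record_date = dates, raw_code = raw,
      supplier = if (src == "TT")
        paste0("S", sample.int(spec$tt_suppliers, total, replace = TRUE))
      else NA_character_,
      year = if (src == "TT") as.integer(format(dates, "%Y"))
      else NA_integer_,
      latent_category = category, census_code = cen_row,
      stringsAsFactors = FALSE
    )
  })
  truth <- do.call(rbind, blocks)
  if (is.null(truth)) stop("no source produced any records", call. = FALSE)
  records <- validate_records(truth[, .RECORD_COLS])
  list(gold = gold, records = records, truth = truth)
}

#' Analytic sensitivity and PPV under unanimous histories
#'
#' With within-person consistency `rho = 1`, every record of a person
#' carries one category, so every derivation method returns the person's
#' single confusion draw and closed forms exist: sensitivity of category
#' \eqn{k} is \eqn{C[k,k] / \sum_{j \in S} C[k,j]} (renormalised over
#' substantive outcomes \eqn{S}, because missing-data derivations are
#' excluded from the metrics), and PPV follows from Bayes' rule over the
#' census distribution, \eqn{\pi_k C[k,k] / \sum_r \pi_r C[r,k]}.
#'
#' @param spec A `simulation_spec` with `rho = 1`.
#' @param source Which source's confusion matrix to use.
#' @return data.frame with columns `category`, `sensitivity`, `ppv`
#'   (percentages); one row per census category present in the source
#'   vocabulary.
#' @export
expected_metrics <- function(spec, source) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$rho != 1) {
    stop("analytic metrics require rho = 1 (unanimous person histories)",
         call. = FALSE)
  }
  if (!source %in% names(spec$sources)) {
    stop("source '", source, "' not in spec", call. = FALSE)
  }
  C <- spec$sources[[source]]$confusion
  pi_ <- spec$census_dist[rownames(C)]
  sub_cols <- setdiff(colnames(C), .SPECIAL_CODES)
  cats <- intersect(rownames(C), sub_cols)
  sens <- vapply(cats, function(k) {
    denom <- sum(C[k, sub_cols])
    if (denom > 0) 100 * C[k, k] / denom else NA_real_
  }, numeric(1))
  ppv <- vapply(cats, function(k) {
    denom <- sum(pi_ * C[, k])
    if (denom > 0) 100 * pi_[k] * C[k, k] / denom else NA_real_
  }, numeric(1))
  data.frame(category = cats, sensitivity = unname(sens), ppv = unname(ppv),
             stringsAsFactors = FALSE)
}
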
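# Orchestration: simulate/read -> derive -> reallocate -> metrics -> SDC,
# with a persisted config and per-stage person-count logging.

.VALID_METHODS <- list(GDPPR = c("recency", "modal"),
                       HES = c("recency", "modal"),
                       TT = "recency",        # extract structure rules out modal
                       ECIA = "single")

#' Configure a pipeline run
#'
#' Either a `simulation` spec or paths to `records`/`gold` CSVs must be
#' supplied. The configuration is validated up front and persisted verbatim
#' into the output bundle, so any published-style run is reproducible from
#' the bundle alone.
#'
#' @param simulation A [simulation_spec()], or `NULL` when reading files.
#' @param records_path,gold_path Input CSVs (ignored when simulating).
#' @param sources Sources to audit.
#' @param methods Derivation methods to attempt (silently reduced to the
#'   methods each source supports; ECIA always uses its single record).
#' @param levels Reallocation cascade levels to compute.
#' @param resolutions `"cat18"`, `"cat5"` or both.
#' @param cutoff Optional cutoff date (records after it are dropped).
#' @param backseries_start Optional back-series start date (records before
#'   it are dropped), as in the back-series sensitivity analysis.
#' @param sdc Also compute disclosure-controlled tables and published-style
#'   metrics?
#' @param seed Seed (overrides the simulation spec's seed when simulating).
#' @return A validated object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, records_path = NULL,
                       gold_path = NULL,
                       sources = c("GDPPR", "HES", "TT", "ECIA"),
                       methods = c("recency", "modal"),
                       levels = c("none", "l1", "l2", "l3"),
                       resolutions = c("cat18", "cat5"),
                       cutoff = NULL, backseries_start = NULL,
                       sdc = TRUE, seed = NULL) {
  if (is.null(simulation) && (is.null(records_path) || is.null(gold_path))) {
    stop("supply either `simulation` or both `records_path` and `gold_path`",
         call. = FALSE)
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_spec"))
  sources <- match.arg(sources, .SOURCES, several.ok = TRUE)
  methods <- match.arg(methods, c("recency", "modal"), several.ok = TRUE)
  levels <- match.arg(levels, names(.REALLOC_SETS), several.ok = TRUE)
  resolutions <- match.arg(resolutions, c("cat18", "cat5"),
                           several.ok = TRUE)
  structure(
    list(simulation = simulation, records_path = records_path,
         gold_path = gold_path, sources = sources, methods = methods,
         levels = levels, resolutions = resolutions,
         cutoff = if (!is.null(cutoff)) as.Date(cutoff),
         backseries_start = if (!is.null(backseries_start))
           as.Date(backseries_start),
         sdc = isTRUE(sdc),
         seed = if (!is.null(seed)) as.integer(seed)
                else if (!is.null(simulation)) simulation$seed),
    class = "run_config"
  )
}

#' Run the full audit pipeline
#'
#' Executes every configured stage and returns a report bundle: per
#' (source, method, level, resolution) the raw and (optionally)
#' disclosure-controlled concordance tables with their agreement reports,
#' plus tidy summary tables and a person-count flow log.
#'
#' @param config A [run_config()].
#' @return An object of class `ethnoconcord_bundle`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) {
    log[[length(log) + 1L]] <<- paste0(...)
    invisible(NULL)
  }

  if (!is.null(config$simulation)) {
    dat <- generate_linked_data(config$simulation, seed = config$seed)
    gold <- dat$gold
    records <- dat$records
    say("simulated ", nrow(gold), " persons, ", nrow(records), " records")
  } else {
    records <- read_records(config$records_path)
    gold <- read_gold(config$gold_path)
    say("read ", nrow(records), " records, ", nrow(gold), " gold persons")
  }
  if (!is.null(config$cutoff)) {
    records <- filter_cutoff(records, config$cutoff)
    say("cutoff ", format(config$cutoff), ": ", nrow(records),
        " records retained")
  }
  if (!is.null(config$backseries_start)) {
    records <- filter_backseries(records, config$backseries_start)
    say("back-series start ", format(config$backseries_start), ": ",
        nrow(records), " records retained")
  }
  records <- resolve_categories(records)

  results <- list()
  derived_tables <- list()
  for (src in config$sources) {
    recs <- records[records$source == src, , drop = FALSE]
    say(src, ": ", length(unique(recs$person_id)), " persons with records")
    for (m in intersect(if (src == "ECIA") "single" else config$methods,
                        .VALID_METHODS[[src]])) {
      derived0 <- derive_ethnicity(recs, src, m)
      levels <- if (src == "ECIA") "none" else config$levels
      for (lv in levels) {
        d <- if (src == "ECIA") {
          cbind(derived0, level = "none", stringsAsFactors = FALSE)
        } else {
          reallocate(derived0, recs, lv)
        }
        key0 <- paste(src, m, lv, sep = ".")
        derived_tables[[key0]] <- d
        n_special <- sum(d$category %in% .SPECIAL_CODES)
        say(key0, ": derived ", nrow(d), " persons (",
            nrow(d) - n_special, " substantive, ", n_special,
            " special/unresolved)")
        for (res in config$resolutions) {
          tab <- build_crosstab(d, gold, res)
          entry <- list(crosstab = tab, agreement = agreement(tab))
          if (config$sdc) {
            entry$sdc_crosstab <- apply_sdc(tab)
            entry$sdc_agreement <- agreement_from_sdc(entry$sdc_crosstab)
          }
          results[[paste(key0, res, sep = ".")]] <- entry
        }
      }
    }
  }
  bundle <- structure(
    list(config = config, gold = gold, derived = derived_tables,
         results = results, log = log),
    class = "ethnoconcord_bundle"
  )
  bundle$summary <- summarize_bundle(bundle)
  bundle
}

#' @export
print.ethnoconcord_bundle <- function(x, ...) {
  cat("<ethnoconcord_bundle> ", length(x$results),
      " (source, method, level, resolution) result sets\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy summary of every result set in a bundle
#'
#' @param bundle An `ethnoconcord_bundle`.
#' @return Long-format data.frame: `source`, `method`, `level`,
#'   `resolution`, `category`, `agreement`, `sensitivity`, `ppv`,
#'   `n_source`, `n_census`, plus `OVERALL` rows carrying the overall
#'   agreement.
#' @export
summarize_bundle <- function(bundle) {
  out <- lapply(names(bundle$results), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rep_ <- bundle$results[[key]]$agreement
    per <- rep_$per_category
    per <- rbind(per, data.frame(category = "OVERALL",
                                 n_source = rep_$n_included,
                                 n_census = rep_$n_included,
                                 agreement = rep_$overall_agreement,
                                 sensitivity = NA_real_,
                                 ppv = NA_real_))
    cbind(source = parts[1], method = parts[2], level = parts[3],
          resolution = parts[4], per, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Agreement and coverage across the reallocation cascade
#'
#' The tidy table behind a levels-of-reallocation comparison: one row per
#' (source, method, level, resolution, category) with the category's
#' agreement and the level's coverage — the proportion of the source's
#' derived persons holding a substantive category.
#'
#' @param bundle An `ethnoconcord_bundle`.
#' @return Long-format data.frame with columns `source`, `method`, `level`,
#'   `resolution`, `category`, `agreement`, `coverage`.
#' @export
summarize_cascade <- function(bundle) {
  cov <- vapply(bundle$derived, function(d)
    mean(!(d$category %in% .SPECIAL_CODES)), numeric(1))
  s <- bundle$summary
  key <- paste(s$source, s$method, s$level, sep = ".")
  data.frame(source = s$source, method = s$method, level = s$level,
             resolution = s$resolution, category = s$category,
             agreement = s$agreement, coverage = unname(cov[key]),
             stringsAsFactors = FALSE)
}

# serialisable form of the config (dates/specs flattened for YAML)
.config_as_list <- function(config) {
  sim <- config$simulation
  list(
    simulation = if (!is.null(sim)) list(
      n_persons = sim$n_persons, rho = sim$rho,
      seed = sim$seed, tt_suppliers = sim$tt_suppliers,
      date_range = as.character(sim$date_range),
      census_dist = as.list(sim$census_dist),
      sources = lapply(sim$sources, function(cfg) list(
        confusion = list(rows = rownames(cfg$confusion),
                         cols = colnames(cfg$confusion),
                         values = as.vector(cfg$confusion)),
        records_per_person = as.list(cfg$records_per_person),
        subsource_probs = as.list(cfg$subsource_probs)
      ))
    ),
    records_path = config$records_path, gold_path = config$gold_path,
    sources = config$sources, methods = config$methods,
    levels = config$levels, resolutions = config$resolutions,
    cutoff = if (!is.null(config$cutoff)) as.character(config$cutoff),
    backseries_start = if (!is.null(config$backseries_start))
      as.character(config$backseries_start),
    sdc = config$sdc, seed = config$seed
  )
}

#' Write a report bundle to a directory
#'
#' Serialises every concordance table (raw and SDC), every tidy agreement
#' report, the run summary, the cascade summary, the stage log, and the
#' configuration (YAML).
#'
#' @param bundle An `ethnoconcord_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(bundle$results)) {
    entry <- bundle$results[[key]]
    base <- gsub(".", "_", key, fixed = TRUE)
    write_crosstab(entry$crosstab,
                   file.path(out_dir, paste0("crosstab_", base, ".csv")))
    write.csv(tidy_agreement(entry$agreement),
              file.path(out_dir, paste0("report_", base, ".csv")),
              row.names = FALSE)
    if (!is.null(entry$sdc_crosstab)) {
      write_crosstab(entry$sdc_crosstab,
                     file.path(out_dir, paste0("sdc_crosstab_", base, ".csv")))
      write.csv(tidy_agreement(entry$sdc_agreement),
                file.path(out_dir, paste0("sdc_report_", base, ".csv")),
                row.names = FALSE)
    }
  }
  write.csv(bundle$summary, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  write.csv(summarize_cascade(bundle), file.path(out_dir,
                                                 "cascade_summary.csv"),
            row.names = FALSE)
  writeLines(bundle$log, file.path(out_dir, "log.txt"))
  yaml::write_yaml(.config_as_list(bundle$config),
                   file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
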
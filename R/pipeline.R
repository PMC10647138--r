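# End-to-end orchestration: derive cut-offs on a set of cohorts
# (subsample selection -> percentile tables -> both search strategies ->
# consolidation) and validate proposed cut-offs on held-out cohorts.
# Derivation and validation cohorts are always separate inputs; the
# pipeline never auto-splits.

#' Pipeline run configuration
#'
#' @param criteria `"IDF"` or `"NCEP"`.
#' @param k clustering threshold (2 primary, 3 sensitivity).
#' @param strategy `"both"`, `"percentile"`, or `"grid"`.
#' @param candidates percentile candidate set.
#' @param grid static candidate grid.
#' @param grouping named character vector cohort-label -> group; used by
#'   consolidation and to pick each test cohort's proposed cut-off.
#' @param sex_specific evaluate country x sex strata (as in the
#'   sex-stratified analyses) or country strata pooled over sex.
#' @param min_cell_n minimum (sex, age) cell size for percentile tables.
#' @return a `run_config` list.
#' @export
run_config <- function(criteria = c("IDF", "NCEP"), k = 2,
                       strategy = c("both", "percentile", "grid"),
                       candidates = c(75, 80, 85, 90, 95),
                       grid = static_grid(), grouping = NULL,
                       sex_specific = TRUE, min_cell_n = 10) {
  criteria <- match.arg(criteria)
  strategy <- match.arg(strategy)
  stopifnot(k %in% c(2, 3), min_cell_n >= 1)
  structure(list(criteria = criteria, k = k, strategy = strategy,
                 candidates = candidates, grid = grid,
                 grouping = grouping, sex_specific = sex_specific,
                 min_cell_n = min_cell_n),
            class = "run_config")
}

#' Derive optimal WHtR cut-offs across cohorts
#'
#' For each cohort: selects the minimum-prevalence weight-status
#' reference subsample, estimates the sex/age WHtR percentile table on
#' it, evaluates percentile candidates and/or the static grid on the
#' full cohort (per sex stratum when `sex_specific`), and selects the
#' Youden-optimal candidate per stratum. Static optima are then
#' consolidated into proposed cut-offs by grouped median. Per-stratum
#' failures (e.g. degenerate outcomes) are logged and skipped; the run
#' fails only if every stratum fails.
#'
#' @param cohorts named list of `whtr_cohort`s (name = country label).
#' @param config a [run_config()].
#' @param growth_ref a `growth_reference`.
#' @param bp_ref a `bp_reference` (required for NCEP).
#' @return list: `strata` (per-stratum optima table), `percentile_evals`
#'   and `grid_evals` (full evaluation tables), `subsamples`
#'   (per-cohort reference-subsample report), `proposed`
#'   (a `proposed_cutoffs` data frame or NULL), `log` (character).
#' @export
run_derivation <- function(cohorts, config, growth_ref, bp_ref = NULL) {
  stopifnot(length(cohorts) >= 1L, !is.null(names(cohorts)))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  strata_rows <- list(); pct_evals <- list(); grid_evals <- list()
  sub_reports <- list()
  optima <- numeric(0)

  for (country in names(cohorts)) {
    cohort <- cohorts[[country]]
    res <- tryCatch({
      sel <- select_reference_subsample(cohort, config$criteria, config$k,
                                        bp_ref, growth_ref)
      note("%s: reference subsample %s (prevalence %.4f)", country,
           sel$reference,
           sel$proportions$proportion[sel$proportions$subsample == sel$reference])
      reference <- build_subsample(cohort, sel$reference, growth_ref)
      ptab <- whtr_percentile_table(reference, config$candidates,
                                    min_n = config$min_cell_n)
      sub_reports[[country]] <- cbind(country = country, sel$proportions)
      strata <- if (config$sex_specific) {
        lapply(SEX_LEVELS, function(s) {
          list(label = paste0(country, ":", s),
               cohort = cohort[cohort$sex == s, , drop = FALSE])
        })
      } else {
        list(list(label = country, cohort = cohort))
      }
      for (st in strata) {
        stc <- st$cohort
        class(stc) <- class(cohort)
        stres <- tryCatch({
          row <- data.frame(stratum = st$label, country = country,
                            criteria = config$criteria, k = config$k,
                            n = nrow(stc), stringsAsFactors = FALSE)
          if (config$strategy %in% c("both", "percentile")) {
            pe <- evaluate_percentile_candidates(stc, ptab,
                                                 config$candidates,
                                                 config$criteria, config$k,
                                                 bp_ref)
            pbest <- select_optimal(pe)
            note("%s: percentile optimum %s (%s)", st$label,
                 pbest$cutoff_spec, attr(pbest, "tie_break"))
            pct_evals[[st$label]] <- cbind(stratum = st$label, pe)
            row$percentile_optimum <- pbest$cutoff_spec
            row$percentile_youden <- pbest$youden
          }
          if (config$strategy %in% c("both", "grid")) {
            ge <- evaluate_static_grid(stc, config$grid, config$criteria,
                                       config$k, bp_ref)
            gbest <- select_optimal(ge)
            note("%s: static optimum %s (%s)", st$label,
                 gbest$cutoff_spec, attr(gbest, "tie_break"))
            grid_evals[[st$label]] <- cbind(stratum = st$label, ge)
            row$static_optimum <- as.numeric(gbest$cutoff_spec)
            row$static_youden <- gbest$youden
            optima[st$label] <- as.numeric(gbest$cutoff_spec)
          }
          row
        }, error = function(e) {
          note("%s: SKIPPED (%s)", st$label, conditionMessage(e))
          NULL
        })
        if (!is.null(stres)) strata_rows[[st$label]] <- stres
      }
      TRUE
    }, error = function(e) {
      note("%s: COHORT FAILED (%s)", country, conditionMessage(e))
      FALSE
    })
  }
  if (length(strata_rows) == 0L) {
    stop("derivation failed in every stratum:\n",
         paste(log, collapse = "\n"), call. = FALSE)
  }
  proposed <- NULL
  if (length(optima) > 0L && !is.null(config$grouping)) {
    # strata inherit their country's group
    stratum_group <- vapply(names(optima), function(lbl) {
      unname(config$grouping[[strsplit(lbl, ":", fixed = TRUE)[[1]][1]]])
    }, character(1))
    proposed <- consolidate(optima, stats::setNames(stratum_group,
                                                    names(optima)))
    note("proposed cut-offs: %s",
         paste(sprintf("%s=%.2f", proposed$group, proposed$proposed),
               collapse = ", "))
  }
  list(strata = do.call(rbind, c(strata_rows, list(make.row.names = FALSE))),
       percentile_evals = if (length(pct_evals))
         do.call(rbind, c(pct_evals, list(make.row.names = FALSE))) else NULL,
       grid_evals = if (length(grid_evals))
         do.call(rbind, c(grid_evals, list(make.row.names = FALSE))) else NULL,
       subsamples = if (length(sub_reports))
         do.call(rbind, c(sub_reports, list(make.row.names = FALSE))) else NULL,
       optima = optima, proposed = proposed, log = log)
}

#' Validate proposed cut-offs on held-out test cohorts
#'
#' Per test cohort and per k in `ks`: the group's proposed cut-off is
#' evaluated as a dichotomized classifier and as an exposure in a
#' sex/age-adjusted logistic model. A pooled model over all test
#' cohorts is additionally adjusted for survey year (when present).
#' Degenerate cohorts are reported as skipped rows, not errors.
#'
#' @param test_cohorts named list of `whtr_cohort`s.
#' @param proposed a `proposed_cutoffs` data frame ([consolidate()]).
#' @param config a [run_config()]; `config$grouping` maps test cohort
#'   names to groups in `proposed`.
#' @param bp_ref a `bp_reference` (required for NCEP).
#' @param ks clustering thresholds to report (default 2 and 3).
#' @return list: `results` (one row per cohort x k: cut-off, n, OR, CI,
#'   AUC, sens, spec, or skip reason), `pooled` (same columns for the
#'   survey-year-adjusted pooled model), `log`.
#' @export
run_validation <- function(test_cohorts, proposed, config, bp_ref = NULL,
                           ks = c(2, 3)) {
  stopifnot(inherits(proposed, "proposed_cutoffs"), nrow(proposed) >= 1L)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  cut_for <- function(label) {
    g <- config$grouping[[label]]
    if (is.null(g)) stop("no group assigned for test cohort ", label,
                         call. = FALSE)
    v <- proposed$proposed[proposed$group == g]
    if (length(v) != 1L) stop("no proposed cut-off for group ", g,
                              call. = FALSE)
    v
  }
  one_row <- function(label, cohort, cutoff, k, extra = NULL) {
    tryCatch({
      v <- validate_proposed(cohort, cutoff, config$criteria, k, bp_ref,
                             extra)
      data.frame(cohort = label, criteria = config$criteria, k = k,
                 cutoff = cutoff, n = v$or$n,
                 or = v$or$odds_ratio, or_lo = v$or$ci[1],
                 or_hi = v$or$ci[2], converged = v$or$converged,
                 auc = v$evaluation$auc, sens = v$evaluation$sens,
                 spec = v$evaluation$spec, skipped = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      note("%s k=%d: skipped (%s)", label, k, conditionMessage(e))
      data.frame(cohort = label, criteria = config$criteria, k = k,
                 cutoff = cutoff, n = nrow(cohort),
                 or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                 converged = NA, auc = NA_real_, sens = NA_real_,
                 spec = NA_real_, skipped = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  rows <- list()
  for (label in names(test_cohorts)) {
    cohort <- test_cohorts[[label]]
    cutoff <- cut_for(label)
    for (k in ks) rows[[paste(label, k)]] <- one_row(label, cohort,
                                                     cutoff, k)
  }
  # pooled model: stack cohorts, exposure at each cohort's own cut-off,
  # additionally adjusted for survey year when available
  pooled <- lapply(ks, function(k) {
    stacked <- do.call(rbind, lapply(names(test_cohorts), function(label) {
      cohort <- as.data.frame(test_cohorts[[label]])
      cohort$.cutoff <- cut_for(label)
      cohort
    }))
    class(stacked) <- c("whtr_cohort", "data.frame")
    tryCatch({
      exposure <- stacked$whtr >= stacked$.cutoff
      outcome <- outcome_vector(stacked, config$criteria, k, bp_ref)
      covars <- data.frame(sex = as.integer(stacked$sex == "female"),
                           age = as.numeric(stacked$age_years))
      if (!is.null(stacked$survey_year) &&
          length(unique(stacked$survey_year)) > 1L) {
        covars$survey_year <- as.numeric(stacked$survey_year)
      }
      or <- fit_logistic(outcome, exposure, covars)
      ev <- evaluate_cutoff(confusion_counts(exposure, outcome),
                            cutoff_spec = "pooled")
      data.frame(cohort = "pooled", criteria = config$criteria, k = k,
                 cutoff = NA_real_, n = or$n, or = or$odds_ratio,
                 or_lo = or$ci[1], or_hi = or$ci[2],
                 converged = or$converged, auc = ev$auc, sens = ev$sens,
                 spec = ev$spec, skipped = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      note("pooled k=%d: skipped (%s)", k, conditionMessage(e))
      NULL
    })
  })
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pooled = do.call(rbind, pooled), log = log)
}
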
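# Candidate cut-off evaluation. A single dichotomizing cut-off yields one
# (sensitivity, specificity) operating point, so its ROC "curve" is the
# two segments through that point and AUC = (sens + spec)/2 =
# (Youden + 1)/2 exactly; maximizing Youden and maximizing AUC are the
# same search.

#' Confusion counts for a classifier against an outcome
#'
#' @param classifier logical vector (test-positive indicator).
#' @param outcome logical vector (true condition), same length.
#' @return a `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(classifier, outcome) {
  stopifnot(is.logical(classifier), is.logical(outcome),
            length(classifier) == length(outcome))
  if (length(outcome) == 0L) stop("empty evaluation", call. = FALSE)
  if (anyNA(classifier) || anyNA(outcome)) {
    stop("NA in classifier or outcome", call. = FALSE)
  }
  if (!any(outcome) || all(outcome)) {
    stop("degenerate outcome: need at least one positive and one ",
         "negative (ROC undefined)", call. = FALSE)
  }
  structure(list(
    tp = sum(classifier & outcome),
    fp = sum(classifier & !outcome),
    tn = sum(!classifier & !outcome),
    fn = sum(!classifier & outcome)
  ), class = "confusion_counts")
}

#' Evaluate one cut-off from its confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, Youden
#' index `sens + spec - 1` and the single-cut-off AUC `(sens + spec)/2`.
#' The 95% AUC CI is the binomial-combination Wald interval
#' `auc +/- 1.96 * sqrt(sens(1-sens)/(4 n_pos) + spec(1-spec)/(4 n_neg))`
#' clipped to `[0, 1]`; sensitivity and specificity get Wald intervals on
#' their own denominators.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @param cutoff_spec label for the candidate (static WHtR value or
#'   percentile label such as `"P85"`); carried through for reporting.
#' @return one-row `cutoff_evaluation` data frame: `cutoff_spec`, `auc`,
#'   `auc_lo`, `auc_hi`, `sens`, `sens_lo`, `sens_hi`, `spec`, `spec_lo`,
#'   `spec_hi`, `youden`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
evaluate_cutoff <- function(counts, cutoff_spec = NA) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  npos <- tp + fn; nneg <- tn + fp
  if (npos == 0L || nneg == 0L) {
    stop("degenerate outcome: zero positives or zero negatives",
         call. = FALSE)
  }
  sens <- tp / npos
  spec <- tn / nneg
  auc <- (sens + spec) / 2
  youden <- sens + spec - 1
  se_auc <- sqrt(sens * (1 - sens) / (4 * npos) +
                 spec * (1 - spec) / (4 * nneg))
  wald <- function(p, n) {
    se <- sqrt(p * (1 - p) / n)
    c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  }
  s_ci <- wald(sens, npos); p_ci <- wald(spec, nneg)
  structure(data.frame(
    cutoff_spec = as.character(cutoff_spec),
    auc = auc,
    auc_lo = max(0, auc - 1.96 * se_auc),
    auc_hi = min(1, auc + 1.96 * se_auc),
    sens = sens, sens_lo = s_ci[1], sens_hi = s_ci[2],
    spec = spec, spec_lo = p_ci[1], spec_hi = p_ci[2],
    youden = youden,
    tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
    stringsAsFactors = FALSE
  ), class = c("cutoff_evaluation", "data.frame"))
}

#' Single-cut-off AUC and Youden index from sensitivity and specificity
#'
#' The arithmetic identity for a one-threshold binary classifier:
#' `auc = (sens + spec)/2`, `youden = sens + spec - 1`. Useful for
#' checking reported operating points.
#'
#' @param sens,spec fractions in `[0, 1]`.
#' @return data frame with `auc` and `youden`.
#' @export
auc_from_rates <- function(sens, spec) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  data.frame(auc = (sens + spec) / 2, youden = sens + spec - 1)
}

outcome_vector <- function(cohort, criteria, k, bp_ref) {
  clustering(component_flags(cohort, criteria, bp_ref), k)
}

#' Evaluate percentile-indexed candidate cut-offs
#'
#' For each candidate percentile p, the classifier is
#' [exceeds_percentile()] against the supplied percentile table
#' (estimated on the reference subsample); evaluation runs on the full
#' cohort passed here.
#'
#' @param cohort a `whtr_cohort` (full evaluation cohort).
#' @param table a `percentile_table`.
#' @param candidates percentile labels present in `table`.
#' @inheritParams clustering_proportion
#' @return a `cutoff_evaluation` data frame, one row per candidate, with
#'   `cutoff_spec` `"P75"` etc.
#' @export
evaluate_percentile_candidates <- function(cohort, table,
                                           candidates = c(75, 80, 85, 90, 95),
                                           criteria = c("IDF", "NCEP"),
                                           k = 2, bp_ref = NULL) {
  criteria <- match.arg(criteria)
  outcome <- outcome_vector(cohort, criteria, k, bp_ref)
  rows <- lapply(candidates, function(p) {
    cls <- exceeds_percentile(cohort, table, p)
    evaluate_cutoff(confusion_counts(cls, outcome),
                    cutoff_spec = paste0("P", p))
  })
  do.call(rbind, rows)
}

#' The default static candidate grid
#'
#' Grid values are built in integer hundredths so there is no
#' floating-point drift: defaults give exactly the 15 values
#' 0.42, 0.43, ..., 0.56.
#'
#' @param lo,hi inclusive grid bounds (WHtR).
#' @param step increment (default 0.01).
#' @return numeric vector of candidate cut-offs.
#' @export
static_grid <- function(lo = 0.42, hi = 0.56, step = 0.01) {
  stopifnot(lo < hi, step > 0)
  seq(round(lo * 100), round(hi * 100), by = round(step * 100)) / 100
}

#' Evaluate a grid of static WHtR cut-offs
#'
#' The classifier at cut-off c is `whtr >= c` (positive at the boundary,
#' matching [exceeds_percentile()]).
#'
#' @inheritParams evaluate_percentile_candidates
#' @param grid candidate cut-offs, default [static_grid()].
#' @return a `cutoff_evaluation` data frame, one row per grid value.
#' @export
evaluate_static_grid <- function(cohort, grid = static_grid(),
                                 criteria = c("IDF", "NCEP"), k = 2,
                                 bp_ref = NULL) {
  criteria <- match.arg(criteria)
  outcome <- outcome_vector(cohort, criteria, k, bp_ref)
  rows <- lapply(grid, function(cut) {
    cls <- cohort$whtr >= cut
    evaluate_cutoff(confusion_counts(cls, outcome),
                    cutoff_spec = format(cut, nsmall = 2))
  })
  do.call(rbind, rows)
}

cutoff_sort_key <- function(spec) {
  # "P85" -> 85 for percentile candidates; numeric strings as-is
  ifelse(grepl("^P", spec), as.numeric(sub("^P", "", spec)),
         suppressWarnings(as.numeric(spec)))
}

#' Select the optimal candidate cut-off
#'
#' Argmax of the Youden index (equivalently of the single-cut-off AUC,
#' since `auc = (youden + 1)/2`). Exact ties break toward higher
#' sensitivity, then toward the lower cut-off; the tie-break path is
#' recorded in the `"tie_break"` attribute.
#'
#' @param evals a `cutoff_evaluation` data frame (>= 1 row).
#' @return the selected row (a one-row `cutoff_evaluation`), with
#'   attribute `tie_break` describing how any tie was resolved.
#' @export
select_optimal <- function(evals) {
  if (is.null(evals) || nrow(evals) == 0L) {
    stop("no evaluations to select from", call. = FALSE)
  }
  best <- which(evals$youden == max(evals$youden))
  note <- "unique Youden maximum"
  if (length(best) > 1L) {
    note <- sprintf("Youden tie among {%s}; broke toward higher sensitivity",
                    paste(evals$cutoff_spec[best], collapse = ", "))
    best <- best[evals$sens[best] == max(evals$sens[best])]
    if (length(best) > 1L) {
      note <- paste0(note, ", then lower cutoff")
      key <- cutoff_sort_key(evals$cutoff_spec[best])
      best <- best[order(key)][1L]
    }
  }
  out <- evals[best[1L], , drop = FALSE]
  attr(out, "tie_break") <- note
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Consolidate per-stratum optima into proposed static cut-offs
#'
#' Makes the "visible tendency to cluster" algorithmic: within each
#' group of strata (e.g. the two region groups), the proposed static
#' cut-off is the median of the member optima, rounded half-up to 2
#' decimals; dispersion (min, max, IQR) is reported so the clustering
#' tendency is inspectable.
#'
#' @param optima named numeric vector: stratum -> optimal static cut-off.
#' @param grouping named character vector: stratum -> group label; every
#'   stratum in `optima` must be assigned.
#' @return a `proposed_cutoffs` data frame: `group`, `proposed`,
#'   `n_strata`, `min`, `max`, `iqr`.
#' @export
consolidate <- function(optima, grouping) {
  unassigned <- setdiff(names(optima), names(grouping))
  if (length(unassigned) > 0L) {
    stop("strata without group assignment: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  groups <- unique(unname(grouping[names(optima)]))
  rows <- lapply(groups, function(g) {
    vals <- optima[names(optima)[grouping[names(optima)] == g]]
    if (length(vals) == 0L) stop("empty group: ", g, call. = FALSE)
    data.frame(group = g,
               proposed = round_half_up(stats::median(vals), 2),
               n_strata = length(vals),
               min = min(vals), max = max(vals),
               iqr = unname(stats::IQR(vals, type = 7)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$proposed < 0.40 | out$proposed > 0.60)) {
    warning("proposed cut-off outside the plausible WHtR range ",
            "[0.40, 0.60]", call. = FALSE)
  }
  structure(out, class = c("proposed_cutoffs", "data.frame"))
}
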
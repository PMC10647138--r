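# Weight-status subsamples and WHtR percentile tables. Percentile values
# are estimated on the reference subsample (the one with the lowest
# clustering prevalence, normal weight in practice) but candidate
# cut-offs are always EVALUATED on the full cohort.

#' Weight-status membership of the six subsamples
#'
#' S1 = everyone; S2 = normal weight; S3 = normal + thinness grade 1 +
#' overweight; S4 = normal + overweight + obese; S5 = normal + overweight;
#' S6 = normal + overweight + obese + morbidly obese. As record sets the
#' nesting chain S2 in S5 in S4 in S6 in S1 and S2 in S3 in S1 holds on
#' any cohort.
#' @export
SUBSAMPLE_MEMBERS <- list(
  S1 = WEIGHT_STATUS_LEVELS,
  S2 = "NORMAL",
  S3 = c("NORMAL", "THIN1", "OVERWEIGHT"),
  S4 = c("NORMAL", "OVERWEIGHT", "OBESE"),
  S5 = c("NORMAL", "OVERWEIGHT"),
  S6 = c("NORMAL", "OVERWEIGHT", "OBESE", "MORBID_OBESE")
)

cohort_weight_status <- function(cohort, growth_ref) {
  classify_weight_status(cohort$sex, cohort$age_years, cohort$bmi,
                         growth_ref)
}

#' Restrict a cohort to one weight-status subsample
#'
#' @param cohort a `whtr_cohort`.
#' @param id subsample id, `"S1"` ... `"S6"` (see [SUBSAMPLE_MEMBERS]).
#' @param growth_ref a `growth_reference`.
#' @return the subsetted `whtr_cohort`.
#' @export
build_subsample <- function(cohort, id, growth_ref) {
  id <- match.arg(id, names(SUBSAMPLE_MEMBERS))
  status <- cohort_weight_status(cohort, growth_ref)
  keep <- status %in% SUBSAMPLE_MEMBERS[[id]]
  out <- cohort[keep, , drop = FALSE]
  attr(out, "label") <- paste0(attr(cohort, "label"), ":", id)
  attr(out, "rejected") <- NULL
  class(out) <- class(cohort)
  out
}

#' Select the reference subsample by minimum clustering prevalence
#'
#' Computes the k-component clustering prevalence in each of the six
#' weight-status subsamples and returns the argmin. Exact ties break
#' toward the subsample with the smaller weight-status membership set
#' (evaluation order S2, S5, S3, S4, S6, S1).
#'
#' @inheritParams build_subsample
#' @inheritParams clustering_proportion
#' @return list: `reference` (subsample id), `proportions` (data frame
#'   `subsample`, `proportion`, `numerator`, `denominator`).
#' @export
select_reference_subsample <- function(cohort, criteria = c("IDF", "NCEP"),
                                       k = 2, bp_ref = NULL,
                                       growth_ref) {
  criteria <- match.arg(criteria)
  order_ids <- c("S2", "S5", "S3", "S4", "S6", "S1")
  rows <- lapply(order_ids, function(id) {
    sub <- build_subsample(cohort, id, growth_ref)
    if (nrow(sub) == 0L) {
      stop("subsample ", id, " is empty; cannot select reference",
           call. = FALSE)
    }
    pr <- clustering_proportion(sub, criteria, k, bp_ref)
    data.frame(subsample = id, proportion = pr$proportion,
               numerator = pr$numerator, denominator = pr$denominator,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- tab$subsample[which.min(tab$proportion)]  # first min = tie-break
  tab <- tab[match(names(SUBSAMPLE_MEMBERS), tab$subsample), ]
  rownames(tab) <- NULL
  list(reference = best, proportions = tab)
}

#' Sex- and age-specific WHtR percentile table
#'
#' Estimates empirical WHtR percentiles in every (sex, completed-age)
#' cell of the reference cohort. The quantile convention is linear
#' interpolation between closest order statistics (`stats::quantile`
#' type 7) by default; the `type` argument selects any of the
#' `stats::quantile` conventions and is recorded in the result. Cells
#' below `min_n` raise an error listing the offending cells — sparse
#' cells are never silently pooled.
#'
#' @param reference a `whtr_cohort` (typically the reference subsample).
#' @param candidates percentile labels, numbers in (0, 100); default
#'   `c(75, 80, 85, 90, 95)`.
#' @param min_n minimum per-cell sample size (default 10).
#' @param type `stats::quantile` type (default 7).
#' @return a `percentile_table` data frame: `sex`, `age`, `p`, `value`,
#'   `n`, with attribute `quantile_type`.
#' @export
whtr_percentile_table <- function(reference, candidates = c(75, 80, 85, 90, 95),
                                  min_n = 10, type = 7) {
  stopifnot(all(candidates > 0 & candidates < 100))
  candidates <- sort(unique(candidates))
  key <- interaction(reference$sex, reference$age_years, drop = TRUE)
  cells <- split(reference$whtr, key)
  sizes <- vapply(cells, length, integer(1))
  if (any(sizes < min_n)) {
    stop("percentile cells below minimum n=", min_n, ": ",
         paste(names(sizes)[sizes < min_n], collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(cells), function(cl) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1L]]
    q <- stats::quantile(cells[[cl]], probs = candidates / 100,
                         type = type, names = FALSE)
    data.frame(sex = parts[1L], age = as.integer(parts[2L]),
               p = candidates, value = q, n = length(cells[[cl]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sex, out$age, out$p), ]
  rownames(out) <- NULL
  structure(out, class = c("percentile_table", "data.frame"),
            quantile_type = type)
}

#' Does a participant's WHtR reach a percentile cut-off?
#'
#' True when the record's WHtR is at or above the (sex, age)-cell value
#' for percentile `p` (`>=`, positive at the boundary). Vectorized over
#' the cohort.
#'
#' @param cohort a `whtr_cohort`.
#' @param table a `percentile_table`.
#' @param p a single percentile label present in the table.
#' @return logical vector.
#' @export
exceeds_percentile <- function(cohort, table, p) {
  stopifnot(inherits(table, "percentile_table"), length(p) == 1L)
  sub <- table[table$p == p, ]
  if (nrow(sub) == 0L) {
    stop("percentile ", p, " not present in table", call. = FALSE)
  }
  idx <- match(paste(cohort$sex, cohort$age_years),
               paste(sub$sex, sub$age))
  if (anyNA(idx)) {
    miss <- unique(paste(cohort$sex, cohort$age_years)[is.na(idx)])
    stop("percentile table has no cell for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cohort$whtr >= sub$value[idx]
}
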
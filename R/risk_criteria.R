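# Component risk-factor flags under the IDF and modified NCEP pediatric
# MetS definitions. The waist-circumference component is deliberately
# excluded everywhere: the outcome is clustering of the four non-WC
# components (high BP, high TG, low HDL-C, high FBG), which the WHtR
# cut-offs are meant to discriminate.

CRITERIA_IDS <- c("IDF", "NCEP")

flags_frame <- function(cohort, high_bp, high_tg, low_hdl, high_fbg,
                        criteria) {
  out <- data.frame(
    id = cohort$id,
    criteria = criteria,
    high_bp = high_bp, high_tg = high_tg,
    low_hdl = low_hdl, high_fbg = high_fbg,
    stringsAsFactors = FALSE
  )
  out$count <- as.integer(high_bp) + as.integer(high_tg) +
    as.integer(low_hdl) + as.integer(high_fbg)
  structure(out, class = c("component_flags", "data.frame"))
}

#' Flag MetS component risk factors under the IDF criteria
#'
#' Thresholds (all analytes mg/dL, BP mmHg):
#' * high TG: TG >= 150
#' * low HDL-C: HDL < 40 for ages 6--15; at 16+ HDL < 40 (boys) or
#'   HDL < 50 (girls)
#' * high BP: SBP >= 120 or DBP >= 80 at ages 6--9; SBP >= 130 or
#'   DBP >= 85 at ages 10+ ("SBP/DBP >= X/Y" is read as OR, the standard
#'   hypertension convention)
#' * high FBG: FBG >= 100
#'
#' @param cohort a `whtr_cohort` (or data frame with the same columns).
#' @return a `component_flags` data frame: `id`, `criteria`, the four
#'   logical flags and their `count` (0--4).
#' @export
flag_idf <- function(cohort) {
  age <- cohort$age_years
  high_tg <- cohort$tg_mgdl >= 150
  hdl_thr <- ifelse(age <= 15, 40,
                    ifelse(cohort$sex == "male", 40, 50))
  low_hdl <- cohort$hdl_mgdl < hdl_thr
  young <- age <= 9
  high_bp <- ifelse(young,
                    cohort$sbp_mmHg >= 120 | cohort$dbp_mmHg >= 80,
                    cohort$sbp_mmHg >= 130 | cohort$dbp_mmHg >= 85)
  high_fbg <- cohort$fbg_mgdl >= 100
  flags_frame(cohort, high_bp, high_tg, low_hdl, high_fbg, "IDF")
}

#' Flag MetS component risk factors under the modified NCEP criteria
#'
#' Thresholds:
#' * high TG: TG >= 110
#' * low HDL-C: HDL <= 40 (note `<=`, vs the IDF strict `<`)
#' * high BP: SBP or DBP at/above the age-, sex-, and height-specific
#'   90th percentile from `bp_ref` for ages 6--17; SBP >= 130 or
#'   DBP >= 85 at age 18
#' * high FBG: FBG >= 110
#'
#' @inheritParams flag_idf
#' @param bp_ref a `bp_reference` from [load_bp_reference()].
#' @return a `component_flags` data frame.
#' @export
flag_ncep <- function(cohort, bp_ref) {
  age <- cohort$age_years
  high_tg <- cohort$tg_mgdl >= 110
  low_hdl <- cohort$hdl_mgdl <= 40
  high_fbg <- cohort$fbg_mgdl >= 110
  high_bp <- logical(nrow(cohort))
  adult <- age >= 18
  high_bp[adult] <- cohort$sbp_mmHg[adult] >= 130 |
    cohort$dbp_mmHg[adult] >= 85
  if (any(!adult)) {
    thr <- bp_thresholds(cohort$sex[!adult], age[!adult],
                         cohort$height_cm[!adult], bp_ref)
    high_bp[!adult] <- cohort$sbp_mmHg[!adult] >= thr$sbp90 |
      cohort$dbp_mmHg[!adult] >= thr$dbp90
  }
  flags_frame(cohort, high_bp, high_tg, low_hdl, high_fbg, "NCEP")
}

#' Flag component risk factors under a named criteria set
#'
#' @inheritParams flag_ncep
#' @param criteria `"IDF"` or `"NCEP"`.
#' @return a `component_flags` data frame.
#' @export
component_flags <- function(cohort, criteria = c("IDF", "NCEP"),
                            bp_ref = NULL) {
  criteria <- match.arg(criteria)
  if (criteria == "IDF") {
    flag_idf(cohort)
  } else {
    if (is.null(bp_ref)) stop("NCEP criteria require bp_ref", call. = FALSE)
    flag_ncep(cohort, bp_ref)
  }
}

#' Cardiometabolic risk-factor clustering
#'
#' A participant clusters when at least `k` of the four component flags
#' are present (`k = 2` is the primary outcome; `k = 3` the sensitivity
#' analysis).
#'
#' @param flags a `component_flags` data frame.
#' @param k minimum number of components, one of 2, 3, 4.
#' @return logical vector, one element per participant.
#' @export
clustering <- function(flags, k = 2) {
  if (!(length(k) == 1L && k %in% c(2, 3, 4))) {
    stop("k must be one of 2, 3, 4", call. = FALSE)
  }
  flags$count >= k
}

#' Clustering prevalence in a cohort
#'
#' @inheritParams component_flags
#' @inheritParams clustering
#' @return list with `proportion`, `numerator`, `denominator`.
#' @export
clustering_proportion <- function(cohort, criteria = c("IDF", "NCEP"),
                                  k = 2, bp_ref = NULL) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  fl <- component_flags(cohort, criteria, bp_ref)
  pos <- clustering(fl, k)
  list(proportion = mean(pos), numerator = sum(pos),
       denominator = length(pos))
}
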
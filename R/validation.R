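# External validation of proposed static cut-offs: dichotomized-classifier
# performance plus covariate-adjusted logistic-regression odds ratios
# (exposed = WHtR >= cut-off, reference group = below-cut-off, outcome =
# risk-factor clustering).

#' Dichotomize a cohort at a static WHtR cut-off
#'
#' @param cohort a `whtr_cohort`.
#' @param cutoff static WHtR value in (0, 1).
#' @return logical exposure indicator, `whtr >= cutoff`.
#' @export
dichotomize <- function(cohort, cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff > 0, cutoff < 1)
  cohort$whtr >= cutoff
}

#' Logistic regression odds ratio for a binary exposure
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`, convergence when the relative deviance
#' change is below 1e-8 or after 25 iterations). The reported odds ratio
#' is `exp` of the exposure coefficient with a 95% Wald CI,
#' `exp(coef +/- 1.96 SE)`, SE from the observed information matrix.
#' Outcome coding: clustering = 1, with the unexposed as reference.
#'
#' @param outcome logical/0-1 vector.
#' @param exposure logical/0-1 vector, same length.
#' @param covariates optional data frame of adjustment terms (e.g. sex,
#'   continuous age in completed years, survey year).
#' @return an `or_result` list: `odds_ratio`, `ci` (length-2), `coefficients`
#'   (data frame: term, estimate, se), `n`, `converged`,
#'   `adjustment_terms`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL) {
  outcome <- as.integer(outcome)
  exposure <- as.integer(exposure)
  stopifnot(length(outcome) == length(exposure),
            all(outcome %in% 0:1), all(exposure %in% 0:1))
  dat <- data.frame(.outcome = outcome, exposure = exposure)
  terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    terms <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  if (length(unique(exposure)) < 2L) {
    stop("degenerate exposure: all participants on one side of the ",
         "cut-off", call. = FALSE)
  }
  if (length(unique(outcome)) < 2L) {
    stop("degenerate outcome: no variation in clustering", call. = FALSE)
  }
  const <- vapply(dat[terms], function(x) length(unique(x)) < 2L,
                  logical(1))
  if (any(const)) {
    stop("constant covariate column(s): ",
         paste(terms[const], collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(c("exposure", terms), response = ".outcome")
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix; collinear columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10 | mu > 1 - 1e-10) && any(abs(cf) > 15)) {
    stop("complete or quasi-complete separation detected (fitted ",
         "probabilities at 0/1 with diverging coefficients)", call. = FALSE)
  }
  b <- cf[["exposure"]]
  s <- se[["exposure"]]
  structure(list(
    odds_ratio = exp(b),
    ci = c(exp(b - 1.96 * s), exp(b + 1.96 * s)),
    coefficients = data.frame(term = names(cf), estimate = unname(cf),
                              se = unname(se), stringsAsFactors = FALSE),
    n = length(outcome),
    converged = fit$converged,
    adjustment_terms = terms
  ), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), n = %d%s%s\n",
              x$odds_ratio, x$ci[1], x$ci[2], x$n,
              if (length(x$adjustment_terms))
                paste0(", adjusted for ",
                       paste(x$adjustment_terms, collapse = " + ")) else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Validate a proposed cut-off on an independent test cohort
#'
#' Bundles the dichotomized-classifier evaluation (AUC, sensitivity,
#' specificity at the fixed cut-off) with a logistic-regression odds
#' ratio adjusted for sex and continuous age, plus any extra covariates
#' (e.g. survey year when pooling test populations). The caller is
#' responsible for the test cohort being independent of derivation.
#'
#' @param test_cohort a `whtr_cohort`.
#' @param cutoff proposed static WHtR cut-off.
#' @inheritParams clustering_proportion
#' @param extra_covariates optional data frame of additional adjustment
#'   columns aligned with `test_cohort` rows.
#' @return list with `evaluation` (one-row `cutoff_evaluation`) and `or`
#'   (an `or_result`).
#' @export
validate_proposed <- function(test_cohort, cutoff,
                              criteria = c("IDF", "NCEP"), k = 2,
                              bp_ref = NULL, extra_covariates = NULL) {
  criteria <- match.arg(criteria)
  exposure <- dichotomize(test_cohort, cutoff)
  outcome <- outcome_vector(test_cohort, criteria, k, bp_ref)
  eval_row <- evaluate_cutoff(confusion_counts(exposure, outcome),
                              cutoff_spec = format(cutoff, nsmall = 2))
  covars <- data.frame(sex = as.integer(test_cohort$sex == "female"),
                       age = as.numeric(test_cohort$age_years))
  if (!is.null(extra_covariates)) covars <- cbind(covars, extra_covariates)
  or <- fit_logistic(outcome, exposure, covars)
  list(evaluation = eval_row, or = or)
}
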
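# Seeded synthetic multi-region pediatric cohorts with a planted
# WHtR-risk threshold. Two region archetypes mirror the headline
# contrast: region A (planted cut-off 0.50, higher WHtR location) and
# region B (planted cut-off 0.46, WHtR location shifted down). Component
# flags are drawn FIRST from a logistic model in WHtR and biomarkers are
# back-filled by truncated draws on the correct side of the generating
# criteria's thresholds, so re-flagging a generated cohort reproduces
# the drawn flags exactly.

COMPONENTS <- c("bp", "tg", "hdl", "fbg")

height_mean <- function(sex, age) {
  ifelse(sex == "male", 116.5 + 5.6 * (age - 6), 115.5 + 5.0 * (age - 6))
}

# smooth (unjittered) growth-boundary curves shared by the reference
# generator and the BMI model: linear from a fraction of the adult
# boundary at age 6 to the adult boundary at 18
GROWTH_ADULT <- c(thin3 = 16, thin2 = 17, thin1 = 18.5,
                  overweight = 25, obesity = 30, morbid_obesity = 35)
GROWTH_START_FRAC <- c(thin3 = 0.78, thin2 = 0.77, thin1 = 0.75,
                       overweight = 0.70, obesity = 0.66,
                       morbid_obesity = 0.63)
growth_boundary <- function(bound, age) {
  f <- GROWTH_START_FRAC[[bound]] +
    (1 - GROWTH_START_FRAC[[bound]]) * (age - 6) / 12
  GROWTH_ADULT[[bound]] * f
}

# log-BMI location/scale anchored to the boundary curves so that about
# 13% fall below the thinness-grade-1 boundary and about 24% at/above
# the overweight boundary at every age (a realistic pediatric mix)
bmi_curve <- function(age) {
  b1 <- growth_boundary("thin1", age)
  bow <- growth_boundary("overweight", age)
  z_thin <- stats::qnorm(0.13)   # -1.126
  z_ow <- stats::qnorm(0.76)     #  0.706
  s <- log(bow / b1) / (z_ow - z_thin)
  list(median_log = log(b1) - z_thin * s, sd = s)
}

#' Synthetic cohort configuration
#'
#' Bundles and validates the generator's parameters. Defaults define the
#' study conditions the rest of the package is tested under: planted
#' cut-offs 0.50 (region A) / 0.46 (region B), a jump of 1.6 log-odds in
#' every component's probability at the planted cut-off plus a slope of
#' 1 per WHtR unit above it, and pooled k=2 clustering prevalence
#' calibrated to 7.8% (IDF-like) or 14.8% (NCEP-like).
#'
#' @param n cohort size (>= 0).
#' @param seed integer seed; all randomness flows from it.
#' @param region `"A"` or `"B"`.
#' @param criteria generating criteria, `"IDF"` or `"NCEP"`; biomarkers
#'   are back-filled consistently with this set's thresholds.
#' @param planted_cutoff the WHtR threshold c* at which component risk
#'   jumps; default 0.50 for region A, 0.46 for region B.
#' @param prevalence_target pooled k=2 clustering prevalence the
#'   generator calibrates to (common log-odds shift on the baselines);
#'   default 0.078 under IDF, 0.148 under NCEP. `NA` disables
#'   calibration and uses `p0` as-is.
#' @param p0 named baseline (below-c*) component probabilities for
#'   `bp`, `tg`, `hdl`, `fbg`, before calibration.
#' @param jump log-odds increase at `whtr >= planted_cutoff`.
#' @param slope additional log-odds per WHtR unit above the cut-off.
#' @param whtr_mu6,whtr_age_slope region-A WHtR mean at age 6 and its
#'   linear decline per year of age.
#' @param region_offset downward WHtR location shift for region B.
#' @param whtr_sd WHtR standard deviation (truncated to (0.30, 0.80)).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n = 10000, seed = 1, region = c("A", "B"),
                             criteria = c("IDF", "NCEP"),
                             planted_cutoff = NULL,
                             prevalence_target = NULL,
                             p0 = NULL,
                             jump = 1.6, slope = 1,
                             whtr_mu6 = 0.492, whtr_age_slope = 0.002,
                             region_offset = 0.035, whtr_sd = 0.05) {
  region <- match.arg(region)
  criteria <- match.arg(criteria)
  if (is.null(planted_cutoff)) {
    planted_cutoff <- if (region == "A") 0.50 else 0.46
  }
  if (is.null(prevalence_target)) {
    prevalence_target <- if (criteria == "IDF") 0.078 else 0.148
  }
  if (is.null(p0)) {
    p0 <- if (criteria == "IDF") {
      c(bp = 0.06, tg = 0.05, hdl = 0.10, fbg = 0.06)
    } else {
      c(bp = 0.08, tg = 0.12, hdl = 0.14, fbg = 0.02)
    }
  }
  stopifnot(n >= 0, length(seed) == 1L,
            planted_cutoff >= 0.40, planted_cutoff <= 0.56,
            all(p0 > 0 & p0 < 1), identical(sort(names(p0)), sort(COMPONENTS)),
            whtr_sd > 0, jump >= 0, slope >= 0)
  structure(list(
    n = as.integer(n), seed = as.integer(seed), region = region,
    criteria = criteria, planted_cutoff = planted_cutoff,
    prevalence_target = prevalence_target, p0 = p0[COMPONENTS],
    jump = jump, slope = slope, whtr_mu6 = whtr_mu6,
    whtr_age_slope = whtr_age_slope, region_offset = region_offset,
    whtr_sd = whtr_sd
  ), class = "synthetic_config")
}

whtr_mu <- function(config, age) {
  config$whtr_mu6 - config$whtr_age_slope * (age - 6) -
    (config$region == "B") * config$region_offset
}

component_prob <- function(config, whtr, delta = 0) {
  # matrix [length(whtr) x 4] of flag probabilities
  excess <- pmax(0, whtr - config$planted_cutoff)
  shift <- config$jump * (whtr >= config$planted_cutoff) +
    config$slope * excess + delta
  vapply(COMPONENTS, function(k) {
    stats::plogis(stats::qlogis(config$p0[[k]]) + shift)
  }, numeric(length(whtr)))
}

prob_at_least <- function(p, k) {
  # P(>= k of 4 independent flags), rows of p are per-record probabilities
  q <- 1 - p
  none <- q[, 1] * q[, 2] * q[, 3] * q[, 4]
  one <- rowSums(vapply(1:4, function(i) {
    p[, i] * apply(q[, -i, drop = FALSE], 1L, prod)
  }, numeric(nrow(p))))
  if (k == 2) 1 - none - one
  else if (k == 3) {
    two <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      rest <- setdiff(1:4, c(i, j))
      two <- two + p[, i] * p[, j] * q[, rest[1]] * q[, rest[2]]
    }
    1 - none - one - two
  } else stop("k must be 2 or 3")
}

analytic_prevalence <- function(config, delta = 0, k = 2, grid_n = 201) {
  ages <- 6:18
  lo <- 0.30; hi <- 0.80
  x <- seq(lo, hi, length.out = grid_n)
  prev <- vapply(ages, function(a) {
    mu <- whtr_mu(config, a)
    d <- stats::dnorm(x, mu, config$whtr_sd)
    d <- d / sum(d)
    sum(prob_at_least(component_prob(config, x, delta), k) * d)
  }, numeric(1))
  mean(prev)
}

#' Calibrate the generator's baseline shift to a prevalence target
#'
#' Solves for the common log-odds shift delta applied to every
#' component baseline so that the analytic pooled k=2 clustering
#' prevalence (integrated over the age-specific truncated-normal WHtR
#' distribution) equals `config$prevalence_target`. Errors when the
#' target is unreachable for the configured effects.
#'
#' @param config a `synthetic_config`.
#' @return the calibrated shift delta (0 when calibration is disabled).
#' @export
calibrate_shift <- function(config) {
  tgt <- config$prevalence_target
  if (is.null(tgt) || is.na(tgt)) return(0)
  f <- function(d) analytic_prevalence(config, d) - tgt
  lo <- -8; hi <- 8
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "calibration error: prevalence target %.3f unreachable (achievable range %.4f-%.4f)",
      tgt, analytic_prevalence(config, lo), analytic_prevalence(config, hi)),
      call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

rtnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  mean <- rep_len(mean, n); lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  out <- stats::qnorm(u, mean, sd)
  out <- pmin(pmax(out, lo), hi)
  # degenerate truncation (interval mass underflows): pin to the nearer
  # boundary inside the interval
  bad <- phi - plo < 1e-12
  if (any(bad)) out[bad] <- ifelse(plo[bad] > 0.5, lo[bad], hi[bad])
  out
}

EPS <- 1e-6

#' Generate synthetic anthropometric reference tables
#'
#' Builds a growth reference (strictly ordered IOTF-style BMI boundaries
#' over ages 6--18, both sexes, converging linearly to the adult
#' boundaries 16/17/18.5/25/30/35 at age 18) and a BP reference (5
#' height bands per sex and age 6--17) with a small seeded jitter.
#' Deterministic given `seed`; both tables pass the references-module
#' validators. These are synthetic fixtures, not published tables.
#'
#' @param seed integer seed.
#' @return list with elements `growth` (a `growth_reference`) and `bp`
#'   (a `bp_reference`).
#' @export
generate_reference_tables <- function(seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (s in SEX_LEVELS) {
    sex_mult <- if (s == "male") 1 else 0.995
    for (a in 6:18) {
      b <- vapply(names(GROWTH_ADULT), growth_boundary, numeric(1),
                  age = a) * sex_mult +
        pmin(pmax(stats::rnorm(6, 0, 0.05), -0.15), 0.15)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age = a, t(b), stringsAsFactors = FALSE)
    }
  }
  growth <- do.call(rbind, rows)
  names(growth) <- c("sex", "age", GROWTH_BOUNDS)

  rows <- list()
  for (s in SEX_LEVELS) {
    for (a in 6:17) {
      h <- height_mean(s, a)
      edges <- h + c(-40, -15, -5, 5, 15, 40)
      mid <- (edges[-6] + edges[-1]) / 2
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age = a,
        height_low = edges[-6], height_high = edges[-1],
        sbp90 = 104 + 1.1 * (a - 6) + 0.06 * (mid - h) +
          (s == "male") * 1 + round(stats::rnorm(5, 0, 0.3), 1),
        dbp90 = 64 + 0.5 * (a - 6) + 0.03 * (mid - h) +
          round(stats::rnorm(5, 0, 0.2), 1),
        stringsAsFactors = FALSE)
    }
  }
  bp <- do.call(rbind, rows)
  list(growth = validate_growth_reference(growth),
       bp = validate_bp_reference(bp))
}

#' Generate a synthetic cohort with planted WHtR-risk structure
#'
#' Per record: completed age uniform on 6--18 and sex by fair coin;
#' height from a sex/age linear growth curve plus Gaussian noise; WHtR
#' from a truncated normal whose location declines slightly with age and
#' is shifted down in region B; waist = WHtR x height; BMI lognormal,
#' positively linked to the record's WHtR excess over its age mean;
#' component flags Bernoulli with probability
#' `plogis(qlogis(p0_k) + delta + jump * [whtr >= c*] + slope * max(0, whtr - c*))`
#' (delta from [calibrate_shift()]); biomarkers back-filled by truncated
#' draws strictly on the flag's side of the generating criteria's
#' thresholds. Identical config (including seed) gives an identical
#' cohort.
#'
#' @param config a `synthetic_config`.
#' @param bp_ref BP reference used for NCEP back-filling; defaults to
#'   `generate_reference_tables(config$seed)$bp`.
#' @return list with `cohort` (a `whtr_cohort`) and `truth` (a
#'   `synthetic_truth` list: planted cut-off, effects, calibrated shift,
#'   post-calibration baselines, analytic prevalence and component
#'   marginals — enough to recompute every record's flag probabilities).
#' @export
generate_cohort <- function(config, bp_ref = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  delta <- calibrate_shift(config)
  if (is.null(bp_ref) && config$criteria == "NCEP") {
    bp_ref <- generate_reference_tables(config$seed)$bp
  }
  set.seed(config$seed)
  n <- config$n
  truth <- structure(list(
    region = config$region, criteria = config$criteria,
    c_star = config$planted_cutoff, jump = config$jump,
    slope = config$slope, delta = delta,
    p0_calibrated = stats::plogis(stats::qlogis(config$p0) + delta),
    whtr = list(mu6 = config$whtr_mu6, age_slope = config$whtr_age_slope,
                region_offset = config$region_offset, sd = config$whtr_sd),
    analytic_prevalence_k2 = analytic_prevalence(config, delta, k = 2),
    component_marginals = {
      x <- seq(0.30, 0.80, length.out = 201)
      m <- vapply(6:18, function(a) {
        d <- stats::dnorm(x, whtr_mu(config, a), config$whtr_sd)
        colSums(component_prob(config, x, delta) * d / sum(d))
      }, numeric(4))
      rowMeans(m)
    },
    seed = config$seed, n = n
  ), class = "synthetic_truth")

  if (n == 0L) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(COHORT_FIELDS)), COHORT_FIELDS))
    empty$id <- character(0); empty$sex <- character(0)
    return(list(cohort = as_cohort(empty, quiet = TRUE,
                                   label = paste0("synthetic-", config$region)),
                truth = truth))
  }

  age <- sample(6:18, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  height <- stats::rnorm(n, height_mean(sex, age),
                         ifelse(sex == "male", 7, 6.5))
  height <- pmin(pmax(height, 95), 205)
  mu <- whtr_mu(config, age)
  whtr <- rtnorm(n, mu, config$whtr_sd, rep(0.30, n) + EPS,
                 rep(0.80, n) - EPS)
  waist <- whtr * height
  bc <- bmi_curve(age)
  link <- 2.2  # log-BMI per WHtR unit; ties weight status to adiposity
  resid_sd <- sqrt(pmax(bc$sd^2 - (link * config$whtr_sd)^2, 0.03^2))
  log_bmi <- bc$median_log + link * (whtr - mu) +
    stats::rnorm(n, 0, 1) * resid_sd
  bmi <- exp(log_bmi)
  weight <- bmi * (height / 100)^2

  p <- component_prob(config, whtr, delta)
  flags <- matrix(stats::runif(n * 4), n, 4) < p
  colnames(flags) <- COMPONENTS

  idf <- config$criteria == "IDF"
  # threshold per record under the generating criteria
  tg_thr <- if (idf) rep(150, n) else rep(110, n)
  fbg_thr <- if (idf) rep(100, n) else rep(110, n)
  hdl_thr <- if (idf) ifelse(age <= 15, 40, ifelse(sex == "male", 40, 50))
             else rep(40, n)
  if (idf) {
    sbp_thr <- ifelse(age <= 9, 120, 130)
    dbp_thr <- ifelse(age <= 9, 80, 85)
  } else {
    sbp_thr <- dbp_thr <- numeric(n)
    minor <- age <= 17
    if (any(minor)) {
      thr <- bp_thresholds(sex[minor], age[minor], height[minor], bp_ref,
                           warn_clamp = FALSE)
      sbp_thr[minor] <- thr$sbp90; dbp_thr[minor] <- thr$dbp90
    }
    sbp_thr[!minor] <- 130; dbp_thr[!minor] <- 85
  }

  tg_mean <- 80 + 1.2 * (age - 6)
  fbg_mean <- 88 + 0.2 * (age - 6)
  sbp_mean <- 98 + 1.3 * (age - 6)
  dbp_mean <- 60 + 0.5 * (age - 6)

  draw_side <- function(flag, thr, mean, sd, lo, hi, high_is_flag,
                        closed_on_flag) {
    # closed_on_flag: threshold value itself carries the flag (>= or <=)
    out <- numeric(length(flag))
    e <- if (closed_on_flag) 0 else EPS
    if (high_is_flag) {
      out[flag] <- rtnorm(sum(flag), mean[flag], sd, thr[flag] + e,
                          hi[flag])
      out[!flag] <- rtnorm(sum(!flag), mean[!flag], sd, lo[!flag],
                           thr[!flag] - EPS)
    } else {
      out[flag] <- rtnorm(sum(flag), mean[flag], sd, lo[flag],
                          thr[flag] - e)
      out[!flag] <- rtnorm(sum(!flag), mean[!flag], sd,
                           thr[!flag] + EPS, hi[!flag])
    }
    out
  }
  # TG/FBG: flag at >= thr (closed on the flag side, so no nudge there)
  tg <- draw_side(flags[, "tg"], tg_thr, tg_mean, 30, rep(25, n),
                  rep(600, n), TRUE, TRUE)
  fbg <- draw_side(flags[, "fbg"], fbg_thr, fbg_mean, 7, rep(55, n),
                   rep(250, n), TRUE, TRUE)
  # HDL: IDF flags hdl < thr (open on flag side); NCEP flags hdl <= thr
  hdl <- draw_side(flags[, "hdl"], hdl_thr, rep(53, n), 10, rep(18, n),
                   rep(120, n), FALSE, !idf)
  # BP: flag true -> at least one of SBP/DBP at/above its threshold
  hb <- flags[, "bp"]
  mode <- stats::runif(n)  # which pressure carries a true flag
  sbp_high <- hb & (mode < 0.45 | mode >= 0.75)
  dbp_high <- hb & (mode >= 0.45)
  sbp <- numeric(n); dbp <- numeric(n)
  sbp[sbp_high] <- rtnorm(sum(sbp_high), sbp_mean[sbp_high], 9,
                          sbp_thr[sbp_high], rep(200, n)[sbp_high])
  sbp[!sbp_high] <- rtnorm(sum(!sbp_high), sbp_mean[!sbp_high], 9,
                           rep(65, n)[!sbp_high],
                           sbp_thr[!sbp_high] - EPS)
  dbp[dbp_high] <- rtnorm(sum(dbp_high), dbp_mean[dbp_high], 7,
                          dbp_thr[dbp_high], rep(130, n)[dbp_high])
  dbp[!dbp_high] <- rtnorm(sum(!dbp_high), dbp_mean[!dbp_high], 7,
                           rep(38, n)[!dbp_high],
                           dbp_thr[!dbp_high] - EPS)

  df <- data.frame(
    id = sprintf("%s-%06d", config$region, seq_len(n)),
    age_years = age, sex = sex,
    height_cm = height, weight_kg = weight, waist_cm = waist,
    sbp_mmHg = sbp, dbp_mmHg = dbp,
    tg_mgdl = tg, hdl_mgdl = hdl, fbg_mgdl = fbg,
    country = paste0("SYN-", config$region),
    survey_year = sample(2008:2016, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cohort <- as_cohort(df, invalid = "error", quiet = TRUE,
                      label = paste0("synthetic-", config$region))
  truth$flags <- as.data.frame(flags)  # drawn flags, for consistency audits
  list(cohort = cohort, truth = truth)
}

#' Recover the planted cut-off by grid search
#'
#' Generates a cohort from `config`, flags it under the generating
#' criteria, runs the static-grid search and returns the selected
#' optimal cut-off, for comparison against the planted `c*`.
#'
#' @param config a `synthetic_config` (use n >= 10,000 for stable
#'   recovery).
#' @param grid candidate grid, default [static_grid()].
#' @param k clustering threshold (2 or 3).
#' @return list: `recovered` (numeric cut-off), `planted` (c*),
#'   `youden` at the optimum, `evaluations` (full grid table).
#' @export
recover_cutoff <- function(config, grid = static_grid(), k = 2) {
  bp_ref <- if (config$criteria == "NCEP")
    generate_reference_tables(config$seed)$bp else NULL
  gen <- generate_cohort(config, bp_ref)
  evals <- evaluate_static_grid(gen$cohort, grid, config$criteria, k,
                                bp_ref)
  best <- select_optimal(evals)
  list(recovered = as.numeric(best$cutoff_spec),
       planted = config$planted_cutoff,
       youden = best$youden,
       evaluations = evals)
}
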
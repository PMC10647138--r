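# Pluggable anthropometric references: an IOTF-style BMI growth reference
# (weight-status classification) and an age/sex/height-band child BP
# 90th-percentile table (NCEP high-BP rule). The package bundles synthetic
# fixture tables of the correct shape; published tables in the same CSV
# layout can be dropped in.

GROWTH_BOUNDS <- c("thin3", "thin2", "thin1", "overweight", "obesity",
                   "morbid_obesity")

#' Weight-status categories
#'
#' Ordered factor levels used throughout: thinness grades 3/2/1, normal
#' weight, overweight, obesity, morbid obesity (IOTF-style, lightest to
#' heaviest).
#' @export
WEIGHT_STATUS_LEVELS <- c("THIN3", "THIN2", "THIN1", "NORMAL",
                          "OVERWEIGHT", "OBESE", "MORBID_OBESE")

validate_growth_reference <- function(tab) {
  need <- c("sex", "age", GROWTH_BOUNDS)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("growth reference missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$sex <- parse_sex(tab$sex)
  if (anyNA(tab$sex)) stop("growth reference: unrecognized sex codes",
                           call. = FALSE)
  for (f in c("age", GROWTH_BOUNDS)) tab[[f]] <- as.numeric(tab[[f]])
  bounds <- as.matrix(tab[, GROWTH_BOUNDS])
  non_mono <- which(apply(bounds, 1L, function(r) any(diff(r) <= 0)))
  if (length(non_mono) > 0L) {
    i <- non_mono[1L]
    stop(sprintf(
      "growth reference: BMI boundaries not strictly increasing at sex=%s age=%g",
      tab$sex[i], tab$age[i]), call. = FALSE)
  }
  for (s in SEX_LEVELS) {
    ages <- tab$age[tab$sex == s]
    if (length(ages) == 0L || min(ages) > 6 || max(ages) < 18) {
      stop("growth reference: age grid must cover [6, 18] for sex ", s,
           call. = FALSE)
    }
    if (anyDuplicated(ages)) {
      stop("growth reference: duplicated age grid points for sex ", s,
           call. = FALSE)
    }
  }
  tab <- tab[order(tab$sex, tab$age), c("sex", "age", GROWTH_BOUNDS)]
  rownames(tab) <- NULL
  structure(tab, class = c("growth_reference", "data.frame"))
}

#' Load an IOTF-style BMI growth reference table
#'
#' CSV layout: `sex,age,thin3,thin2,thin1,overweight,obesity,morbid_obesity`
#' where each boundary column holds the BMI value separating the category
#' below from the one named (e.g. `overweight` is the normal/overweight
#' boundary, the age-specific analogue of adult BMI 25). Boundaries must
#' strictly increase within every row and the age grid must cover 6--18
#' for both sexes.
#'
#' @param path CSV path, or a data frame already in that layout.
#' @return a validated `growth_reference` data frame.
#' @export
load_growth_reference <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  validate_growth_reference(tab)
}

#' Classify weight status from BMI against a growth reference
#'
#' Boundaries are linearly interpolated in age between adjacent grid
#' points; a BMI exactly equal to a boundary belongs to the heavier
#' category. Vectorized over `sex`, `age_years`, `bmi`.
#'
#' @param sex `"male"`/`"female"` (any code accepted by [parse_sex()]).
#' @param age_years age in completed years; must lie within the table's
#'   age grid.
#' @param bmi body-mass index, kg/m^2.
#' @param ref a `growth_reference` from [load_growth_reference()].
#' @return character vector of [WEIGHT_STATUS_LEVELS].
#' @export
classify_weight_status <- function(sex, age_years, bmi, ref) {
  stopifnot(inherits(ref, "growth_reference"))
  sex <- parse_sex(sex)
  n <- max(length(sex), length(age_years), length(bmi))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  bmi <- rep_len(bmi, n)
  out <- character(n)
  for (s in unique(sex)) {
    sel <- sex == s
    grid <- ref[ref$sex == s, ]
    if (any(age_years[sel] < min(grid$age) | age_years[sel] > max(grid$age))) {
      stop("age outside growth-reference coverage for sex ", s,
           call. = FALSE)
    }
    # interpolate each boundary at the queried ages
    b <- vapply(GROWTH_BOUNDS, function(col) {
      stats::approx(grid$age, grid[[col]], xout = age_years[sel])$y
    }, numeric(sum(sel)))
    b <- matrix(b, nrow = sum(sel))
    # boundary membership to the heavier category: bmi >= boundary k
    # advances past it, which is exactly findInterval's convention
    idx <- rowSums(bmi[sel] >= b)
    out[sel] <- WEIGHT_STATUS_LEVELS[idx + 1L]
  }
  out
}

validate_bp_reference <- function(tab) {
  need <- c("sex", "age", "height_low", "height_high", "sbp90", "dbp90")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("BP reference missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$sex <- parse_sex(tab$sex)
  if (anyNA(tab$sex)) stop("BP reference: unrecognized sex codes",
                           call. = FALSE)
  for (f in setdiff(need, "sex")) tab[[f]] <- as.numeric(tab[[f]])
  if (any(tab$sbp90 <= 0 | tab$dbp90 <= 0)) {
    stop("BP reference: thresholds must be strictly positive", call. = FALSE)
  }
  if (any(tab$sbp90 <= tab$dbp90)) {
    stop("BP reference: sbp90 must exceed dbp90 in every cell",
         call. = FALSE)
  }
  covered <- unique(tab[, c("sex", "age")])
  for (s in SEX_LEVELS) {
    ages <- covered$age[covered$sex == s]
    if (!all(6:17 %in% ages)) {
      stop("BP reference must cover ages 6-17 for sex ", s, call. = FALSE)
    }
  }
  tab <- tab[order(tab$sex, tab$age, tab$height_low), ]
  rownames(tab) <- NULL
  structure(tab, class = c("bp_reference", "data.frame"))
}

#' Load a child blood-pressure 90th-percentile reference table
#'
#' CSV layout: `sex,age,height_low,height_high,sbp90,dbp90`; one row per
#' height band, bands half-open `[height_low, height_high)`. Must cover
#' ages 6--17 for both sexes.
#'
#' @param path CSV path, or a data frame already in that layout.
#' @return a validated `bp_reference` data frame.
#' @export
load_bp_reference <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bp_reference(tab)
}

#' Look up age/sex/height-specific BP 90th percentiles
#'
#' Returns the `(sbp90, dbp90)` cell for the half-open height band
#' containing `height_cm`. Heights outside all bands are clamped to the
#' nearest band with a warning. Age 18 is an error: the static 130/85
#' mmHg rule applies there, not the reference table.
#'
#' @inheritParams classify_weight_status
#' @param height_cm standing height in cm.
#' @param ref a `bp_reference` from [load_bp_reference()].
#' @param warn_clamp warn when a height falls outside all bands.
#' @return data frame with columns `sbp90`, `dbp90` (one row per query).
#' @export
bp_thresholds <- function(sex, age_years, height_cm, ref,
                          warn_clamp = TRUE) {
  stopifnot(inherits(ref, "bp_reference"))
  sex <- parse_sex(sex)
  n <- max(length(sex), length(age_years), length(height_cm))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  height_cm <- rep_len(height_cm, n)
  if (any(age_years < 6 | age_years > 17)) {
    stop("bp_thresholds covers ages 6-17 only; use the static 130/85 rule ",
         "at age 18", call. = FALSE)
  }
  sbp90 <- numeric(n); dbp90 <- numeric(n)
  clamped <- 0L
  key <- paste(sex, age_years)
  for (k in unique(key)) {
    sel <- key == k
    cell <- ref[paste(ref$sex, ref$age) == k, ]
    if (nrow(cell) == 0L) {
      stop("BP reference has no rows for (sex, age) = ", k, call. = FALSE)
    }
    h <- height_cm[sel]
    # half-open bands [low, high); out-of-range heights clamp to nearest
    band <- findInterval(h, cell$height_low)
    low <- band == 0L
    high <- band > 0L & h >= max(cell$height_high)
    clamped <- clamped + sum(low | high)
    band[low] <- 1L
    band[high] <- nrow(cell)
    sbp90[sel] <- cell$sbp90[band]
    dbp90[sel] <- cell$dbp90[band]
  }
  if (clamped > 0L && warn_clamp) {
    warning(sprintf(
      "%d height(s) outside BP-reference bands; clamped to nearest band",
      clamped), call. = FALSE)
  }
  data.frame(sbp90 = sbp90, dbp90 = dbp90)
}

#' Path to the bundled synthetic reference fixtures
#'
#' The packaged growth/BP reference tables are synthetic fixtures of the
#' correct shape (generated by [generate_reference_tables()]), not the
#' published IOTF or child-BP tables; substitute the published CSVs for
#' real analyses.
#'
#' @param which `"growth"` or `"bp"`.
#' @return file path.
#' @export
synthetic_reference_path <- function(which = c("growth", "bp")) {
  which <- match.arg(which)
  system.file("extdata",
              paste0("synthetic_", which, "_reference.csv"),
              package = "whtrcut", mustWork = TRUE)
}
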
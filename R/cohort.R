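#' @keywords internal
"_PACKAGE"

# Canonical participant fields (internal units: cm, kg, mmHg, mg/dL).
COHORT_FIELDS <- c(
  "id", "age_years", "sex", "height_cm", "weight_kg", "waist_cm",
  "sbp_mmHg", "dbp_mmHg", "tg_mgdl", "hdl_mgdl", "fbg_mgdl"
)
COHORT_OPTIONAL <- c("country", "survey_year")

SEX_LEVELS <- c("male", "female")

#' Parse sex codes
#'
#' Accepts `"M"`, `"F"`, `"male"`, `"female"`, `"1"`, `"2"` (1 = male),
#' case-insensitively, returning `"male"`/`"female"` (`NA` if unrecognized).
#'
#' @param x character or numeric vector of sex codes.
#' @return character vector with values in `c("male", "female")` or `NA`.
#' @export
parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

#' Construct a validated cohort from a participant data frame
#'
#' Validates each row against the participant invariants (positive physical
#' quantities, completed age 6--18 years, waist < 2 x height), truncates age
#' to completed years, normalizes sex codes, and computes the derived
#' indices BMI (kg/m^2) and WHtR (waist/height, dimensionless). Rows that
#' fail validation are rejected with row-indexed diagnostics, never imputed.
#'
#' @param df data frame with columns `id`, `age_years`, `sex`, `height_cm`,
#'   `weight_kg`, `waist_cm`, `sbp_mmHg`, `dbp_mmHg`, `tg_mgdl`, `hdl_mgdl`,
#'   `fbg_mgdl`, optionally `country` and `survey_year`.
#' @param invalid what to do with invalid rows: `"drop"` (default; rejected
#'   rows are reported via a message and attached as the `"rejected"`
#'   attribute) or `"error"`.
#' @param label optional cohort label stored as an attribute.
#' @param quiet suppress the accepted/rejected message.
#' @return a `whtr_cohort` data frame (one row per accepted participant)
#'   with derived columns `bmi` and `whtr`, unique `id`s, and attributes
#'   `label` and `rejected` (data frame with `row` and `reason`).
#' @export
as_cohort <- function(df, invalid = c("drop", "error"), label = NULL,
                      quiet = FALSE) {
  invalid <- match.arg(invalid)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_FIELDS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  df$id <- as.character(df$id)
  df$sex <- parse_sex(df$sex)
  num_fields <- setdiff(COHORT_FIELDS, c("id", "sex"))
  for (f in num_fields) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  # completed years on ingest; fractional ages are truncated, not rounded
  df$age_years <- floor(df$age_years)

  reason <- character(n)
  bad <- function(cond, msg) {
    cond <- !is.na(cond) & cond
    reason[cond & reason == ""] <<- msg
  }
  for (f in num_fields) {
    bad(is.na(df[[f]]), paste0("unparseable or missing ", f))
  }
  bad(is.na(df$sex), "unrecognized sex code")
  bad(is.na(df$id) | df$id == "", "missing id")
  phys <- c("height_cm", "weight_kg", "waist_cm", "sbp_mmHg", "dbp_mmHg",
            "tg_mgdl", "hdl_mgdl", "fbg_mgdl")
  for (f in phys) {
    bad(df[[f]] <= 0, paste0(f, " must be strictly positive"))
  }
  bad(df$age_years < 6 | df$age_years > 18,
      "age_years outside 6-18 (completed years)")
  bad(df$waist_cm >= 2 * df$height_cm, "waist_cm must be < 2 * height_cm")

  keep <- reason == ""
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (invalid == "error" && nrow(rejected) > 0L) {
    stop("invalid participant rows: ",
         paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
               collapse = "; "), call. = FALSE)
  }
  out <- df[keep, intersect(c(COHORT_FIELDS, COHORT_OPTIONAL), names(df)),
            drop = FALSE]
  if (anyDuplicated(out$id)) {
    stop("duplicate participant ids within cohort: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  out$age_years <- as.integer(out$age_years)
  if ("survey_year" %in% names(out)) {
    out$survey_year <- suppressWarnings(as.integer(out$survey_year))
  }
  out$bmi <- out$weight_kg / (out$height_cm / 100)^2
  out$whtr <- out$waist_cm / out$height_cm
  if (any(out$whtr <= 0 | out$whtr >= 2)) {
    stop("derived WHtR outside (0, 2); check units", call. = FALSE)
  }
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf("cohort: %d accepted, %d rejected", nrow(out),
                    nrow(rejected)))
  }
  structure(out, class = c("whtr_cohort", "data.frame"),
            label = label, rejected = rejected)
}

#' @export
print.whtr_cohort <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<whtr_cohort> %d participants%s\n", nrow(x),
              if (is.null(lbl)) "" else paste0(" [", lbl, "]")))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) {
    cat(sprintf("  (%d rows rejected on ingest)\n", nrow(rej)))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

read_schema <- function(schema) {
  if (is.null(schema)) return(NULL)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
  }
  schema <- unlist(schema)
  unknown <- setdiff(names(schema), c(COHORT_FIELDS, COHORT_OPTIONAL))
  if (length(unknown) > 0L) {
    stop("schema maps unknown fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  schema
}

#' Read a cohort from CSV
#'
#' Reads a UTF-8 CSV with header (decimal point `.`) and validates it into
#' a [as_cohort()] cohort. Column names may be remapped through `schema`, a
#' named vector/list `canonical_field = csv_column` or the path of a
#' YAML/JSON file holding such a mapping; fields not mentioned keep their
#' canonical names.
#'
#' @param path CSV file path.
#' @param schema optional column mapping (see details).
#' @inheritParams as_cohort
#' @return a `whtr_cohort`; see [as_cohort()] for rejection handling.
#' @export
read_cohort <- function(path, schema = NULL, invalid = c("drop", "error"),
                        label = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  schema <- read_schema(schema)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0L) {
      stop("schema refers to absent CSV columns: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(schema)) {
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(COHORT_FIELDS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing mapped columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_cohort(raw, invalid = invalid,
            label = if (is.null(label)) basename(path) else label,
            quiet = quiet)
}

#' Write a cohort (raw + derived fields) to CSV
#'
#' @param cohort a `whtr_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "whtr_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

# mg/dL per mmol/L
UNIT_FACTORS <- c(tg = 88.57, hdl = 38.67, fbg = 18.016)

#' Convert analyte concentrations between mg/dL and mmol/L
#'
#' Fixed molar conversion factors: triglycerides 88.57, cholesterol (HDL)
#' 38.67, glucose 18.016 mg/dL per mmol/L. The package's internal unit is
#' mg/dL throughout; conversion belongs at the I/O boundary only.
#'
#' @param value numeric vector.
#' @param analyte one of `"tg"`, `"hdl"`, `"fbg"`.
#' @param from,to units, each one of `"mg/dL"`, `"mmol/L"`.
#' @return converted numeric vector.
#' @export
convert_units <- function(value, analyte = c("tg", "hdl", "fbg"),
                          from = c("mmol/L", "mg/dL"),
                          to = c("mg/dL", "mmol/L")) {
  analyte <- match.arg(analyte)
  from <- match.arg(from)
  to <- match.arg(to)
  f <- UNIT_FACTORS[[analyte]]
  if (from == to) return(value)
  if (from == "mmol/L") value * f else value / f
}
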
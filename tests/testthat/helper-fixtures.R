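# Shared fixtures, all built in code.

# deterministic reference tables used across test files
test_refs <- generate_reference_tables(seed = 99)

GROWTH_BOUNDS_TEST <- c("thin3", "thin2", "thin1", "overweight",
                        "obesity", "morbid_obesity")

# one participant row with healthy defaults; override any field
participant <- function(id = "p1", age_years = 10, sex = "male",
                        height_cm = 140, weight_kg = 35, waist_cm = 60,
                        sbp_mmHg = 100, dbp_mmHg = 60, tg_mgdl = 70,
                        hdl_mgdl = 55, fbg_mgdl = 85, ...) {
  data.frame(id = id, age_years = age_years, sex = sex,
             height_cm = height_cm, weight_kg = weight_kg,
             waist_cm = waist_cm, sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
             tg_mgdl = tg_mgdl, hdl_mgdl = hdl_mgdl, fbg_mgdl = fbg_mgdl,
             ..., stringsAsFactors = FALSE)
}

# cohort from a list of participant() rows
mini_cohort <- function(...) {
  as_cohort(do.call(rbind, list(...)), quiet = TRUE)
}

# a cohort with chosen BMI targets: weight back-computed so that
# classify_weight_status lands where the test wants it
cohort_with_bmi <- function(bmis, sex = "male", age = 10, height = 140,
                            whtr = 0.45, ...) {
  n <- length(bmis)
  df <- participant(id = sprintf("b%03d", seq_len(n)), age_years = age,
                    sex = sex, height_cm = height,
                    weight_kg = bmis * (height / 100)^2,
                    waist_cm = whtr * height, ...)
  as_cohort(df, quiet = TRUE)
}
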
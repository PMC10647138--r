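# helper: cohort with one record per requested weight status, using the
# test growth reference to pick BMIs inside each category
status_bmi <- function(status, sex = "male", age = 10) {
  row <- test_refs$growth[test_refs$growth$sex == sex &
                          test_refs$growth$age == age, ]
  switch(status,
         THIN1 = (row$thin2 + row$thin1) / 2,
         NORMAL = (row$thin1 + row$overweight) / 2,
         OVERWEIGHT = (row$overweight + row$obesity) / 2,
         OBESE = (row$obesity + row$morbid_obesity) / 2,
         MORBID_OBESE = row$morbid_obesity + 2)
}

test_that("subsample membership matches the weight-status sets", {
  statuses <- c("THIN1", "NORMAL", "NORMAL", "OVERWEIGHT", "OBESE")
  co <- cohort_with_bmi(vapply(statuses, status_bmi, numeric(1)))
  expect_equal(nrow(build_subsample(co, "S2", test_refs$growth)), 2L)
  expect_equal(nrow(build_subsample(co, "S3", test_refs$growth)), 4L)
  expect_equal(nrow(build_subsample(co, "S5", test_refs$growth)), 3L)
  expect_equal(nrow(build_subsample(co, "S4", test_refs$growth)), 4L)
  # S1 is the identity
  s1 <- build_subsample(co, "S1", test_refs$growth)
  expect_equal(s1$id, co$id)
})

test_that("nesting chain S2 in S5 in S4 in S6 in S1 and S2 in S3 in S1 holds on fuzzed cohorts", {
  for (seed in 1:8) {
    co <- generate_cohort(synthetic_config(n = 400, seed = seed,
                                           region = sample(c("A", "B"), 1)))$cohort
    ids <- lapply(names(SUBSAMPLE_MEMBERS), function(s)
      build_subsample(co, s, test_refs$growth)$id)
    names(ids) <- names(SUBSAMPLE_MEMBERS)
    expect_true(all(ids$S2 %in% ids$S5))
    expect_true(all(ids$S5 %in% ids$S4))
    expect_true(all(ids$S4 %in% ids$S6))
    expect_true(all(ids$S6 %in% ids$S1))
    expect_true(all(ids$S2 %in% ids$S3))
    expect_true(all(ids$S3 %in% ids$S1))
  }
})

test_that("reference selection returns the prevalence argmin, S2 on obesity-driven risk", {
  # plant risk in the obese and (mildly) thin records so the normal-weight
  # subsample carries the least clustering
  risky <- function(p) transform(p, tg_mgdl = 200, hdl_mgdl = 30)
  rows <- list()
  for (i in 1:6) rows[[length(rows) + 1L]] <-
    participant(paste0("n", i), weight_kg = status_bmi("NORMAL") * 1.96)
  for (i in 1:3) rows[[length(rows) + 1L]] <-
    risky(participant(paste0("o", i),
                      weight_kg = status_bmi("OBESE") * 1.96))
  for (i in 1:2) rows[[length(rows) + 1L]] <-
    risky(participant(paste0("t", i),
                      weight_kg = status_bmi("THIN1") * 1.96))
  co <- do.call(mini_cohort, rows)
  sel <- select_reference_subsample(co, "IDF", 2, growth_ref = test_refs$growth)
  expect_equal(sel$reference, "S2")
  expect_true(all(sel$proportions$proportion >= 0 &
                  sel$proportions$proportion <= 1))
  # the returned argmin is <= every tabulated proportion
  best <- sel$proportions$proportion[sel$proportions$subsample == "S2"]
  expect_true(all(best <= sel$proportions$proportion))
})

test_that("an all-tied cohort breaks toward S2", {
  co <- cohort_with_bmi(rep(status_bmi("NORMAL"), 3) + c(0, 1, -1))
  # add one member of every other status so no subsample is empty
  extra <- cohort_with_bmi(vapply(c("THIN1", "OVERWEIGHT", "OBESE",
                                    "MORBID_OBESE"), status_bmi,
                                  numeric(1)), whtr = 0.44)
  extra$id <- paste0("e", seq_len(nrow(extra)))
  all <- suppressMessages(as_cohort(rbind(as.data.frame(co),
                                          as.data.frame(extra))))
  sel <- select_reference_subsample(all, "IDF", 2,
                                    growth_ref = test_refs$growth)
  expect_equal(sel$reference, "S2")  # all proportions zero -> tie-break
  expect_error(select_reference_subsample(co[0, ], "IDF", 2,
                                          growth_ref = test_refs$growth),
               "empty")
})

test_that("percentile table matches the order-statistic formula on a split cell", {
  whtrs <- c(rep(0.40, 50), rep(0.60, 50))
  co <- cohort_with_bmi(rep(status_bmi("NORMAL"), 100))
  co$waist_cm <- whtrs * co$height_cm
  co$whtr <- whtrs
  tab <- whtr_percentile_table(co)
  # type-7: h = (n-1)p + 1; for n=100, p=.75 -> h=75.25 -> x[75]=0.60
  expect_equal(tab$value[tab$p == 75], 0.60)
  expect_true(all(tab$n == 100))
})

test_that("constant cells give the constant at every percentile", {
  co <- cohort_with_bmi(rep(status_bmi("NORMAL"), 20), whtr = 0.45)
  tab <- whtr_percentile_table(co)
  expect_true(all(tab$value == 0.45))
})

test_that("large uniform samples put P90 near 0.90", {
  set.seed(31)
  n <- 20000
  co <- suppressMessages(as_cohort(participant(
    id = sprintf("u%05d", 1:n), height_cm = 100,
    waist_cm = runif(n) * 99 + 0.5, weight_kg = 30)))
  co$whtr <- co$waist_cm / 100
  tab <- whtr_percentile_table(co, candidates = 90)
  expect_equal(tab$value[1], 0.90 * 0.99 + 0.005, tolerance = 0.01)
})

test_that("quantiles agree with a sort-based oracle and are monotone in p", {
  oracle_q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(10:1000, 1)
    co <- suppressMessages(as_cohort(participant(
      id = sprintf("q%04d", 1:n),
      age_years = sample(6:18, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE),
      height_cm = 140, weight_kg = 35,
      waist_cm = 140 * runif(n, 0.35, 0.70))))
    tab <- tryCatch(whtr_percentile_table(co),
                    error = function(e) NULL)
    if (is.null(tab)) next  # sparse cells rejected; covered below
    for (i in sample(nrow(tab), min(10, nrow(tab)))) {
      cell <- co$whtr[co$sex == tab$sex[i] & co$age_years == tab$age[i]]
      expect_equal(tab$value[i], oracle_q7(cell, tab$p[i] / 100))
    }
    mono <- tapply(tab$value, paste(tab$sex, tab$age),
                   function(v) all(diff(v) >= 0))
    expect_true(all(mono))
  }
})

test_that("sparse cells raise an error listing them", {
  co <- cohort_with_bmi(rep(status_bmi("NORMAL"), 5))
  expect_error(whtr_percentile_table(co), "minimum n=10")
  expect_silent(tab <- whtr_percentile_table(co, min_n = 5))
})

test_that("duplication leaves inverse-ECDF quantiles unchanged", {
  # exact sample-weight invariance under duplication holds for the
  # inverse-ECDF convention (type 1); interpolating conventions shift
  # within one order-statistic gap
  set.seed(77)
  n <- 60
  base <- participant(id = sprintf("d%03d", 1:n), height_cm = 140,
                      weight_kg = 35,
                      waist_cm = 140 * runif(n, 0.38, 0.62))
  co <- suppressMessages(as_cohort(base))
  doubled <- base
  doubled$id <- paste0(doubled$id, "x")
  co2 <- suppressMessages(as_cohort(rbind(base, doubled)))
  t1 <- whtr_percentile_table(co, type = 1)
  t2 <- whtr_percentile_table(co2, type = 1)
  expect_equal(t1$value, t2$value)
})

test_that("exceeds_percentile uses >= at the cell value and errors on gaps", {
  co <- cohort_with_bmi(rep(status_bmi("NORMAL"), 12), whtr = 0.45)
  tab <- whtr_percentile_table(co)
  expect_true(all(exceeds_percentile(co, tab, 75)))  # whtr == cell value
  low <- co; low$whtr <- rep(0.40, 12)
  for (p in c(75, 80, 85, 90, 95)) {
    expect_false(any(exceeds_percentile(low, tab, p)))
  }
  older <- co; older$age_years <- rep(17L, 12)
  expect_error(exceeds_percentile(older, tab, 75), "no cell")
  expect_error(exceeds_percentile(co, tab, 99), "not present")
})
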
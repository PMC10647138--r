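test_that("confusion counts tally exhaustively and reject degenerate outcomes", {
  cls <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  out <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  cc <- confusion_counts(cls, out)
  # hand tally: tp rows 1,5; fp rows 2,7; fn rows 3,8; tn rows 4,6
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 2L, tn = 2L, fn = 2L))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, length(out))
  ident <- confusion_counts(out, out)
  expect_equal(ident$fp + ident$fn, 0L)
  flipped <- confusion_counts(!out, out)
  expect_equal(flipped$tp + flipped$tn, 0L)
  expect_error(confusion_counts(cls, rep(TRUE, 8)), "degenerate")
  expect_error(confusion_counts(cls, rep(FALSE, 8)), "degenerate")
})

test_that("evaluation satisfies the single-cut-off identities exactly", {
  ev <- evaluate_cutoff(list(tp = 11, fn = 1, tn = 29, fp = 10))
  expect_identical(ev$sens, 11 / 12)
  expect_identical(ev$spec, 29 / 39)
  expect_identical(ev$auc, (ev$sens + ev$spec) / 2)
  expect_identical(ev$youden, ev$sens + ev$spec - 1)
  expect_identical(ev$auc, (ev$youden + 1) / 2)
  # Wald CI on the binomial combination
  se <- sqrt(ev$sens * (1 - ev$sens) / (4 * 12) +
             ev$spec * (1 - ev$spec) / (4 * 39))
  expect_equal(ev$auc_lo, ev$auc - 1.96 * se)
  expect_equal(ev$auc_hi, ev$auc + 1.96 * se)
  perfect <- evaluate_cutoff(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden, 1)
  chance <- evaluate_cutoff(list(tp = 5, fn = 5, tn = 10, fp = 10))
  expect_equal(chance$auc, 0.5)
  expect_equal(chance$youden, 0)
  expect_error(evaluate_cutoff(list(tp = 0, fn = 0, tn = 5, fp = 5)),
               "degenerate")
})

test_that("default static grid is the fifteen hundredth-steps 0.42-0.56", {
  g <- static_grid()
  expect_identical(g, seq(42, 56) / 100)
  expect_length(g, 15L)
  expect_length(static_grid(0.44, 0.50, 0.02), 4L)
  expect_error(static_grid(0.5, 0.4), "lo < hi")
})

test_that("grid evaluation matches a brute-force tally and is threshold-monotone", {
  co <- generate_cohort(synthetic_config(n = 50, seed = 21))$cohort
  outcome <- clustering(flag_idf(co), 2)
  if (!any(outcome) || all(outcome)) skip("fixture cohort degenerate")
  evals <- evaluate_static_grid(co, criteria = "IDF")
  expect_equal(nrow(evals), 15L)
  for (i in seq_len(nrow(evals))) {
    cut <- as.numeric(evals$cutoff_spec[i])
    expect_equal(evals$tp[i], sum(co$whtr >= cut & outcome))
    expect_equal(evals$fp[i], sum(co$whtr >= cut & !outcome))
    expect_equal(evals$tn[i], sum(co$whtr < cut & !outcome))
    expect_equal(evals$fn[i], sum(co$whtr < cut & outcome))
  }
  expect_true(all(diff(evals$sens) <= 0))
  expect_true(all(diff(evals$spec) >= 0))
})

test_that("percentile candidates evaluate per p with sens non-increasing", {
  co <- generate_cohort(synthetic_config(n = 3000, seed = 22))$cohort
  ref <- build_subsample(co, "S2", test_refs$growth)
  tab <- whtr_percentile_table(ref, min_n = 5)
  evals <- evaluate_percentile_candidates(co, tab, criteria = "IDF")
  expect_equal(evals$cutoff_spec, paste0("P", c(75, 80, 85, 90, 95)))
  expect_true(all(diff(evals$sens) <= 0))
  one <- evaluate_percentile_candidates(co, tab, candidates = 85,
                                        criteria = "IDF")
  expect_equal(nrow(one), 1L)
})

test_that("record order never changes evaluation output", {
  co <- generate_cohort(synthetic_config(n = 400, seed = 23))$cohort
  shuffled <- co[sample(nrow(co)), ]
  class(shuffled) <- class(co)
  a <- evaluate_static_grid(co, criteria = "IDF")
  b <- evaluate_static_grid(shuffled, criteria = "IDF")
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("optimum selection is the Youden argmax with the stated tie-breaks", {
  mk <- function(spec, sens, spec_) {
    evaluate_cutoff(list(tp = round(sens * 100), fn = round((1 - sens) * 100),
                         tn = round(spec_ * 100), fp = round((1 - spec_) * 100)),
                    cutoff_spec = spec)
  }
  evals <- rbind(mk("0.42", 0.6, 0.6), mk("0.43", 0.9, 0.6),
                 mk("0.44", 0.6, 0.7))
  expect_equal(select_optimal(evals)$cutoff_spec, "0.43")
  # tie on youden -> higher sensitivity
  tie <- rbind(mk("0.45", 0.8, 0.5), mk("0.46", 0.5, 0.8))
  expect_equal(select_optimal(tie)$cutoff_spec, "0.45")
  # full tie -> lower cutoff
  full <- rbind(mk("0.50", 0.7, 0.6), mk("0.44", 0.7, 0.6))
  best <- select_optimal(full)
  expect_equal(best$cutoff_spec, "0.44")
  expect_match(attr(best, "tie_break"), "lower cutoff")
  expect_error(select_optimal(full[0, ]), "no evaluations")
})

test_that("selection agrees with exhaustive scan on random evaluation lists", {
  set.seed(91)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    evals <- do.call(rbind, lapply(seq_len(n), function(i) {
      evaluate_cutoff(list(tp = sample(1:50, 1), fn = sample(1:50, 1),
                           tn = sample(1:50, 1), fp = sample(1:50, 1)),
                      cutoff_spec = sprintf("0.%02d", 41 + i))
    }))
    got <- select_optimal(evals)
    brute <- evals[order(-evals$youden, -evals$sens,
                         as.numeric(evals$cutoff_spec)), ][1, ]
    expect_equal(got$cutoff_spec, brute$cutoff_spec)
    # maximizing auc is the same search
    expect_equal(which.max(evals$youden), which.max(evals$auc))
  }
})

test_that("consolidation takes grouped medians rounded half-up", {
  expect_equal(consolidate(c(a = 0.50, b = 0.50, c = 0.50),
                           c(a = "G", b = "G", c = "G"))$proposed, 0.50)
  got <- consolidate(c(a = 0.45, b = 0.46, c = 0.46, d = 0.46, e = 0.47),
                     c(a = "G", b = "G", c = "G", d = "G", e = "G"))
  expect_equal(got$proposed, 0.46)
  expect_equal(got$min, 0.45)
  expect_equal(got$max, 0.47)
  two <- consolidate(c(a = 0.50, b = 0.52, x = 0.46, y = 0.44),
                     c(a = "EU", b = "EU", x = "AS", y = "AS"))
  expect_equal(two$proposed[two$group == "EU"], 0.51)
  expect_equal(two$proposed[two$group == "AS"], 0.45)
  # median exactly on a half-hundredth rounds up
  expect_equal(consolidate(c(a = 0.45, b = 0.46),
                           c(a = "G", b = "G"))$proposed, 0.46)
  expect_error(consolidate(c(a = 0.5), c(b = "G")), "without group")
})

test_that("k=3 positives nest inside k=2 positives and can go degenerate", {
  co <- generate_cohort(synthetic_config(n = 4000, seed = 24))$cohort
  fl <- flag_idf(co)
  expect_true(all(!clustering(fl, 3) | clustering(fl, 2)))
  ev2 <- select_optimal(evaluate_static_grid(co, criteria = "IDF", k = 2))
  ev3 <- select_optimal(evaluate_static_grid(co, criteria = "IDF", k = 3))
  expect_lte(abs(as.numeric(ev3$cutoff_spec) - as.numeric(ev2$cutoff_spec)),
             0.02 + 1e-12)
  healthy <- do.call(mini_cohort, lapply(1:30, function(i)
    participant(paste0("h", i))))
  expect_error(evaluate_static_grid(healthy, criteria = "IDF", k = 3),
               "degenerate")
})
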
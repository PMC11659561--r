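test_that("confusion tables classify each unit into exactly one cell", {
  one_pos <- make_eyes(35L, ai = "detected", pid = "A")
  t1 <- build_table(one_pos, "eye", "level1")
  expect_equal(c(t1$tp, t1$fp, t1$fn, t1$tn, t1$insufficient_pos,
                 t1$insufficient_neg), c(1, 0, 0, 0, 0, 0))

  one_ins <- make_eyes(35L, ai = "insufficient_quality", pid = "A")
  t2 <- build_table(one_ins, "eye", "level1")
  expect_equal(t2$insufficient_pos, 1)
  expect_equal(t2$tp + t2$fp + t2$fn + t2$tn, 0)

  ds <- random_trial(n = 80, seed = 21)
  for (unit in c("eye", "participant")) {
    tab <- build_table(ds, unit, "level1")
    n_expect <- if (unit == "eye") n_eyes(ds) else n_participants(ds)
    expect_equal(drdscreen:::total_units(tab), n_expect)
  }
})

test_that("tabulation matches exhaustive per-unit classification on tiny sets", {
  for (seed in 1:4) {
    ds <- random_trial(n = 6, seed = seed)
    tab <- build_table(ds, "eye", "level1")
    truth <- is_drd_positive(ds$etdrs_base, ds$dme_level1)
    cells <- table(factor(paste0(
      ifelse(ds$ai_output == "insufficient_quality", "ins_",
             ifelse(ds$ai_output == "detected", "det_", "not_")),
      ifelse(truth, "pos", "neg")),
      levels = c("det_pos", "det_neg", "not_pos", "not_neg",
                 "ins_pos", "ins_neg")))
    expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn, tab$insufficient_pos,
                   tab$insufficient_neg), unname(as.vector(cells)))
  }
})

test_that("accuracy metrics use only diagnosable units", {
  t <- confusion_counts(tp = 220, fp = 134, fn = 121, tn = 696)
  expect_equal(sensitivity(t), 220 / 341)
  expect_equal(specificity(t), 696 / 830)
  expect_equal(sensitivity(confusion_counts(tp = 5, fp = 0, fn = 0, tn = 0)), 1)

  chance <- confusion_counts(tp = 25, fp = 25, fn = 25, tn = 25)
  expect_equal(unname(predictive_values(chance)), c(0.5, 0.5))
  expect_equal(unname(likelihood_ratios(chance)), c(1, 1))
  expect_equal(predictive_values(
    confusion_counts(tp = 3, fp = 0, fn = 1, tn = 2))[["ppv"]], 1)

  expect_warning(out <- sensitivity(confusion_counts(0, 1, 0, 1)), "undefined")
  expect_true(is.na(out))
})

test_that("likelihood-ratio identities hold to 1e-12 on random tables", {
  set.seed(99)
  for (i in 1:50) {
    t <- confusion_counts(tp = sample(1:200, 1), fp = sample(1:200, 1),
                          fn = sample(1:200, 1), tn = sample(1:200, 1))
    lr <- likelihood_ratios(t)
    se <- t$tp / (t$tp + t$fn)
    sp <- t$tn / (t$tn + t$fp)
    expect_equal(lr[["plr"]], se / (1 - sp), tolerance = 1e-12)
    expect_equal(lr[["nlr"]], (1 - se) / sp, tolerance = 1e-12)
  }
})

test_that("worst-case imputation folds insufficient counts and never helps", {
  t <- confusion_counts(tp = 220, fp = 91, fn = 56, tn = 696,
                        insufficient_pos = 65, insufficient_neg = 43)
  w <- worst_case_impute(t)
  expect_equal(sensitivity(w), 220 / 341)
  expect_equal(specificity(w), 696 / 830)
  expect_equal(drdscreen:::total_units(w), drdscreen:::total_units(t))
  expect_equal(w$insufficient_pos + w$insufficient_neg, 0)

  clean <- confusion_counts(tp = 10, fp = 2, fn = 3, tn = 20)
  expect_equal(worst_case_impute(clean)$fn, clean$fn)

  set.seed(12)
  for (i in 1:50) {
    t <- confusion_counts(tp = sample(1:50, 1), fp = sample(1:50, 1),
                          fn = sample(0:50, 1), tn = sample(1:50, 1),
                          insufficient_pos = sample(1:20, 1),
                          insufficient_neg = sample(1:20, 1))
    w <- worst_case_impute(t)
    expect_lte(sensitivity(w), sensitivity(t))
    expect_lte(specificity(w), specificity(t))
  }
})

test_that("diagnosability counts disease-level outputs at both units", {
  all_ins <- make_eyes(c(10L, 10L), ai = "insufficient_quality")
  expect_equal(diagnosability(all_ins, "eye"), 0)
  all_ok <- make_eyes(c(10L, 35L), ai = "not_detected")
  expect_equal(diagnosability(all_ok, "eye"), 1)
  mixed <- make_eyes(c(10L, 10L), ai = c("detected", "insufficient_quality"))
  expect_equal(diagnosability(mixed, "eye"), 0.5)
  expect_equal(diagnosability(mixed, "participant"), 1)
})

test_that("Level II ungradable eyes are excluded and counted", {
  ds <- make_eyes(c(35L, 35L, 10L, 10L),
                  ai = "detected",
                  level2 = c("detected", "ungradable", "not_detected",
                             "ungradable"))
  tab <- build_table(ds, "eye", "level2")
  expect_equal(tab$n_excluded_ungradable, 2)
  expect_equal(tab$tp, 1)
  expect_equal(tab$fp, 1)
})
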
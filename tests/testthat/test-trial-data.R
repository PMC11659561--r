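subset_participants <- drdscreen:::subset_participants
participant_ids <- drdscreen:::participant_ids

test_that("constructor enforces the structural invariants", {
  ok <- make_eyes(c(35L, 10L))
  expect_s3_class(ok, "trial_dataset")
  expect_equal(n_participants(ok), 1)

  dup <- data.frame(participant_id = c("A", "A"), laterality = c("left", "left"),
                    etdrs_base = c(10L, 10L), dme_level1 = FALSE)
  expect_error(trial_dataset(dup), "duplicate")

  three <- data.frame(participant_id = "A", laterality = c("left", "right", "left"),
                      etdrs_base = 10L, dme_level1 = FALSE)
  expect_error(trial_dataset(three), "duplicate|more than two")

  bad_ai <- data.frame(participant_id = "A", laterality = "left",
                       etdrs_base = 10L, dme_level1 = FALSE,
                       ai_output = "maybe")
  expect_error(trial_dataset(bad_ai), "row 1.*ai_output.*maybe")

  incons <- data.frame(participant_id = "A", laterality = "left",
                       etdrs_base = 10L, dme_level1 = FALSE,
                       cidme = TRUE, csdme = FALSE)
  expect_error(trial_dataset(incons), "dme_level1 inconsistent")

  expect_error(trial_dataset(data.frame(participant_id = "A")),
               "missing required")
})

test_that("participant reference positivity matches brute-force OR over eyes", {
  combos <- expand.grid(b1 = c(10L, 35L, 60L), b2 = c(10L, 20L, 43L),
                        d1 = c(TRUE, FALSE), d2 = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    ds <- make_eyes(c(combos$b1[i], combos$b2[i]),
                    dme = c(combos$d1[i], combos$d2[i]))
    expect_identical(
      unname(participant_reference_positive(ds)),
      is_drd_positive(combos$b1[i], combos$d1[i]) ||
        is_drd_positive(combos$b2[i], combos$d2[i]))
  }
  single <- make_eyes(53L, pid = "X")
  expect_true(participant_reference_positive(single)[["X"]])
})

test_that("participant AI output requires only one diagnosable eye", {
  expect_equal(unname(participant_ai_output(
    make_eyes(c(35L, 35L), ai = c("detected", "insufficient_quality")))),
    "detected")
  expect_equal(unname(participant_ai_output(
    make_eyes(c(10L, 10L), ai = c("not_detected", "not_detected")))),
    "not_detected")
  expect_equal(unname(participant_ai_output(
    make_eyes(c(10L, 10L), ai = "insufficient_quality"))),
    "insufficient_quality")
  expect_equal(unname(participant_ai_output(
    make_eyes(c(10L, 10L), ai = c("not_detected", "insufficient_quality")))),
    "not_detected")
  expect_error(participant_ai_output(make_eyes(10L, pid = "A")), "missing")
})

test_that("CSV round-trip is the identity on generated datasets", {
  for (seed in c(3, 17)) {
    ds <- random_trial(n = 30, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_trial_table(ds, path)
    back <- read_trial_table(path)
    expect_equal(strip_ds(back), strip_ds(ds))
  }
})

test_that("reader reports malformed input with position and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,laterality,etdrs_base,dme_level1,ai_output",
               "A,left,35,TRUE,detected",
               "B,right,35,TRUE,maybe"), path)
  expect_error(read_trial_table(path), "row 2.*ai_output.*maybe")
  writeLines(c("participant_id,laterality,etdrs_base,dme_level1",
               "A,left,ten,TRUE"), path)
  expect_error(read_trial_table(path), "line 2.*etdrs_base")
  writeLines("participant_id,laterality,etdrs_base,dme_level1", path)
  expect_equal(n_participants(read_trial_table(path)), 0)
})

test_that("waterfall summary counts stages and exclusions", {
  full <- random_trial(n = 20, seed = 5)
  ids <- participant_ids(full)
  completed <- subset_participants(full, ids[1:18])
  analyzable <- subset_participants(full, ids[1:15])
  w <- waterfall_summary(full, completed, analyzable)
  expect_equal(w$participants, c(20, 18, 15))
  expect_equal(w$excluded_participants, c(NA, 2, 3))
  expect_equal(w$eyes, c(40, 36, 30))

  same <- waterfall_summary(full, full, full)
  expect_equal(same$excluded_participants[2:3], c(0, 0))

  expect_error(waterfall_summary(completed, full, analyzable), "not a subset")
})
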
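test_that("cluster resampling keeps participants intact", {
  one <- make_eyes(c(35L, 10L), ai = "detected")
  set.seed(1)
  r <- cluster_resample(one)
  expect_equal(n_eyes(r), 2)
  expect_equal(sort(r$etdrs_base), c(10L, 35L))

  ds <- random_trial(n = 15, seed = 3)
  sizes <- table(ds$participant_id)
  set.seed(2)
  for (i in 1:100) {
    rep <- cluster_resample(ds)
    expect_equal(n_participants(rep), 15)
    # every resampled cluster has the size of its source participant
    src <- sub("\\.[0-9]+$", "", unique(rep$participant_id))
    expect_equal(unname(table(rep$participant_id)[unique(rep$participant_id)]),
                 unname(sizes[src]))
  }
  expect_error(cluster_resample(generate_trial(sim_config(n_participants = 0))),
               "empty")
})

test_that("spectrum expansion stops at first crossing of the target", {
  rich <- make_eyes(c(60L, 61L, 35L, 35L), ai = "detected")  # vt share 0.5
  expect_identical(as.data.frame(spectrum_expand(rich, 0.2)),
                   as.data.frame(rich))

  sparse <- make_eyes(c(60L, rep(35L, 19)), ai = "detected")  # 1/20 vt
  set.seed(4)
  ex <- spectrum_expand(sparse, 0.2)
  cn <- drdscreen:::vt_pos_counts(ex)
  frac <- sum(cn$vt) / sum(cn$pos)
  expect_gte(frac, 0.2)
  # removing the last appended carrier must drop the share below target
  appended <- grepl("\\.x[0-9]+$", ex$participant_id)
  expect_true(any(appended))
  last <- ex$participant_id == ex$participant_id[max(which(appended))]
  cn0 <- drdscreen:::vt_pos_counts(ex[!last, ])
  expect_lt(sum(cn0$vt) / sum(cn0$pos), 0.2)

  none <- make_eyes(rep(35L, 10), ai = "detected")
  expect_error(spectrum_expand(none, 0.2), "no vtDRD carrier")
})

test_that("degenerate perfect-accuracy bootstrap yields bound 1 and minimal p", {
  ds <- perfect_dataset(3)
  res <- bootstrap_metric(ds, "sensitivity",
                          settings = bootstrap_settings(n_replicates = 100,
                                                        seed = 5))
  expect_equal(res$point_estimate, 1)
  expect_equal(res$lower_bound, 1)
  expect_equal(res$ni_p_value, 1 / 101)
})

test_that("bootstrap is reproducible under the seed", {
  ds <- random_trial(n = 60, seed = 6)
  st <- bootstrap_settings(n_replicates = 200, seed = 7)
  a <- bootstrap_metric(ds, "sensitivity", settings = st)
  b <- bootstrap_metric(ds, "sensitivity", settings = st)
  expect_identical(a$replicate_values, b$replicate_values)
  expect_identical(a$lower_bound, b$lower_bound)
  c <- bootstrap_metric(ds, "sensitivity",
                        settings = bootstrap_settings(n_replicates = 200,
                                                      seed = 8))
  expect_false(identical(a$replicate_values, c$replicate_values))
})

test_that("lower bound sits below the point estimate on non-degenerate data", {
  ds <- generate_trial(sim_config(n_participants = 300, seed = 30))
  r <- bootstrap_metric(ds, "sensitivity",
                        settings = bootstrap_settings(n_replicates = 400,
                                                      seed = 31))
  expect_lt(r$lower_bound, r$point_estimate)

  # a comfortably non-inferior operating point is rejected decisively
  hi <- generate_trial(sim_config(n_participants = 400, seed = 32,
                                  ai_sensitivity = 0.9))
  rh <- bootstrap_metric(hi, "sensitivity",
                         settings = bootstrap_settings(n_replicates = 400,
                                                       seed = 33))
  expect_lt(rh$ni_p_value, 0.025)
})

test_that("NI p-value is non-increasing in the point estimate at fixed margins", {
  # fixed family: 20 two-eye positive participants (40 positive eyes),
  # k of which are detected; same seed throughout
  p_at <- function(k) {
    ai <- rep("not_detected", 40)
    ai[seq_len(k)] <- "detected"
    ds <- make_eyes(rep(35L, 40), ai = ai)
    bootstrap_metric(ds, "sensitivity",
                     settings = bootstrap_settings(n_replicates = 300,
                                                   seed = 9,
                                                   expand_spectrum = FALSE)
                     )$ni_p_value
  }
  ps <- vapply(c(24, 28, 32, 36, 40), p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("study success demands rejection of both endpoints", {
  ds <- perfect_dataset(4)
  st <- bootstrap_settings(n_replicates = 150, seed = 10)
  sens <- bootstrap_metric(ds, "sensitivity", settings = st)
  fake_spec <- sens
  fake_spec$metric <- "specificity"

  good <- fake_spec
  good$ni_p_value <- 0.001
  base <- sens
  base$ni_p_value <- 0.021
  expect_true(study_success(base, good))
  bad <- fake_spec
  bad$ni_p_value <- 0.5
  expect_false(study_success(base, bad))
  boundary <- base
  boundary$ni_p_value <- 0.026
  expect_false(study_success(boundary, good))

  other <- fake_spec
  other$settings <- bootstrap_settings(n_replicates = 300, seed = 1)
  expect_error(study_success(base, other), "mismatched")
  expect_error(study_success(good, base), "sensitivity and a specificity")
})

test_that("power simulation validates inputs and reports MC error", {
  expect_error(power_simulation(0), "positive")
  p <- power_simulation(4, settings = bootstrap_settings(n_replicates = 150,
                                                         seed = 12))
  expect_true(p$power_study >= 0 && p$power_study <= 1)
  expect_equal(p$n_trials, 4)
})
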
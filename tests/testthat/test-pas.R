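test_that("PAS evaluates the full formula and collapses when prevalences agree", {
  expect_equal(pas(pas_inputs(s_c = 0.815, d_c = 0.958, c = 1, p_c = 0.2)),
               0.815 * 0.958, tolerance = 1e-12)
  expect_equal(round(pas(pas_inputs(0.815, 0.958, 1, 0.2)), 3), 0.781)
  expect_equal(pas(pas_inputs(s_c = 0, d_c = 0.9, c = 0.5, p_c = 0.2)), 0)
  expect_equal(pas(pas_inputs(s_c = 0.8, d_c = 0.9, c = 0.5, p_c = 0.2,
                              p_nc_hat = 0.4)), 0.24, tolerance = 1e-12)
  expect_error(pas(pas_inputs(0.8, 1, 0, 0, 0)), "zero prevalence")
  expect_error(pas_inputs(1.2), "\\[0, 1\\]")
})

test_that("simplified PAS equals the full formula under equal prevalence", {
  expect_equal(pas_simplified(1, 1, 1), 1)
  expect_equal(pas_simplified(0.872, 1, 1), 0.872)
  set.seed(42)
  for (i in 1:1000) {
    s <- runif(1); d <- runif(1); cc <- runif(1); p <- runif(1, 0.01, 0.99)
    expect_equal(pas(pas_inputs(s, d, cc, p, p)), pas_simplified(s, cc, d),
                 tolerance = 1e-12)
  }
})

test_that("PAS is monotone in sensitivity, diagnosability and access", {
  set.seed(43)
  for (i in 1:200) {
    base <- runif(4)
    lo <- pas(pas_inputs(base[1], base[2], base[3], base[4], base[4]))
    for (j in 1:3) {
      bumped <- base
      bumped[j] <- min(1, base[j] + runif(1, 0, 1 - base[j]))
      hi <- pas(pas_inputs(bumped[1], bumped[2], bumped[3], bumped[4],
                           bumped[4]))
      expect_gte(hi, lo - 1e-12)
    }
  }
})

test_that("break-even ratio matches the two-system comparison", {
  ref <- pas_inputs(s_c = 0.872, d_c = 0.958, c = 1, p_c = 0.2)
  new <- pas_inputs(s_c = 0.815, d_c = 0.958, c = 1, p_c = 0.2)
  expect_equal(round(pas_break_even_ratio(ref, new), 2), 1.07)
  expect_equal(pas_break_even_ratio(ref, ref), 1)
  expect_equal(pas_break_even_ratio(pas_inputs(0.9, 0.9), pas_inputs(0.81, 1)),
               1, tolerance = 1e-12)
  expect_error(pas_break_even_ratio(pas_inputs(0.9, 1, c = 0.5),
                                    pas_inputs(0.8, 1, c = 0.7)), "equal")
  expect_error(pas_break_even_ratio(ref, pas_inputs(0)), "zero")
})

test_that("ratio antisymmetry holds to 1e-12", {
  set.seed(44)
  for (i in 1:100) {
    a <- pas_inputs(runif(1, 0.1, 1), runif(1, 0.1, 1), 1, 0.2)
    b <- pas_inputs(runif(1, 0.1, 1), runif(1, 0.1, 1), 1, 0.2)
    expect_equal(pas_break_even_ratio(a, b) * pas_break_even_ratio(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo ratio interval is seeded, bracketing and symmetric", {
  int <- pas_ratio_interval(0.872, c(0.818, 0.912), 0.815, c(0.769, NA),
                            n_draws = 20000, seed = 3)
  expect_lt(int[["lower"]], 1.07)
  expect_gt(int[["upper"]], 1.07)
  again <- pas_ratio_interval(0.872, c(0.818, 0.912), 0.815, c(0.769, NA),
                              n_draws = 20000, seed = 3)
  expect_identical(int, again)

  tight <- pas_ratio_interval(0.9, c(0.9, 0.9), 0.8, c(0.8, 0.8),
                              n_draws = 1000, seed = 4)
  expect_equal(unname(tight), rep(0.9 / 0.8, 2), tolerance = 1e-9)

  fwd <- pas_ratio_interval(0.872, c(0.818, 0.912), 0.815, c(0.769, 0.861),
                            n_draws = 50000, seed = 5)
  rev <- pas_ratio_interval(0.815, c(0.769, 0.861), 0.872, c(0.818, 0.912),
                            n_draws = 50000, seed = 6)
  expect_equal(fwd[["lower"]], 1 / rev[["upper"]], tolerance = 0.02)
  expect_equal(fwd[["upper"]], 1 / rev[["lower"]], tolerance = 0.02)

  expect_error(pas_ratio_interval(0.9, c(NA, NA), 0.8, c(0.7, 0.9)),
               "degenerate")
})

test_that("risk annotation encodes the published outcome lookup", {
  det <- risk_annotation("detected")
  expect_equal(det$risk_pdr_3y, 0.185)
  expect_equal(det$risk_modvl_1y, 0.11)
  expect_equal(det$risk_modvl_3y, 0.35)
  expect_equal(det$icd10_category, "E11.339x")
  nod <- risk_annotation("not_detected")
  expect_lte(nod$risk_pdr_3y, 0.018)
  expect_true(all(c(nod$risk_pdr_3y, nod$risk_modvl_1y, nod$risk_modvl_3y) <
                    c(det$risk_pdr_3y, det$risk_modvl_1y, det$risk_modvl_3y)))
})
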
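test_that("combination index arithmetic and guards", {
  expect_equal(ci_value(5, 10, 5, 10), 1.0)
  expect_equal(ci_value(2, 10, 1, 10), 0.3)
  expect_equal(ci_value(3, 10, 0, 7), 0.3)  # drug 2 absent
  expect_error(ci_value(1, 0, 1, 1), "> 0")
  expect_error(ci_value(-1, 1, 1, 1), ">= 0")
})

test_that("CI bands partition [0, Inf) with the documented closure", {
  expect_equal(classify_ci(0.42), "synergism")
  expect_equal(classify_ci(1.04), "nearly_additive")
  expect_equal(classify_ci(0.27), "strong_synergism")
  # boundary closure: left-closed at 0.3/0.7/0.9, right-closed at 1.1/1.45
  expect_equal(classify_ci(c(0.3, 0.7, 0.9, 1.1, 1.45)),
               c("synergism", "moderate_slight_synergism",
                 "nearly_additive", "nearly_additive",
                 "slight_moderate_antagonism"))
  expect_equal(classify_ci(2), "strong_antagonism")
  # total and single-valued on a dense grid
  grid <- seq(0, 3, by = 0.001)
  bands <- classify_ci(grid)
  expect_true(all(nzchar(bands)))
  expect_equal(length(bands), length(grid))
  expect_error(classify_ci(-0.1), "non-negative")
})

test_that("sham self-combination yields CI = 1 at all levels", {
  sim <- simulate_dose_response(noise_sd = 0, seed = 1)
  f <- fit_4pl(sim$data$dose_nM, sim$data$viability_percent)
  tab <- combination_ci(sim$data$dose_nM / 2, sim$data$viability_percent,
                        ratio = 1, fit1 = f, fit2 = f)
  expect_true(all(tab$reachable))
  expect_equal(tab$ci, rep(1, 3), tolerance = 0.02)
  expect_equal(tab$band, rep("nearly_additive", 3))
})

test_that("a 4-fold potency boost scores as synergy, zero drug2 as additive", {
  sim <- simulate_dose_response(noise_sd = 0, seed = 1)
  f <- fit_4pl(sim$data$dose_nM, sim$data$viability_percent)
  # combination acting like the single agent at 4x its total dose
  boosted <- predict_4pl(f, 4 * sim$data$dose_nM)
  tab <- combination_ci(sim$data$dose_nM / 2, boosted, ratio = 1,
                        fit1 = f, fit2 = f)
  expect_lt(tab$ci[tab$effect_level == 0.5], 0.7)
  # drug2 identically zero: CI = D1/Dx1 = 1 when the combo is drug1 itself
  tab0 <- combination_ci(sim$data$dose_nM, sim$data$viability_percent,
                         ratio = 0, fit1 = f, fit2 = f)
  expect_equal(tab0$ci, rep(1, 3), tolerance = 0.02)
  expect_equal(tab0$D2, rep(0, 3))
})

test_that("Loewe surface matches single agents on the axes and is monotone", {
  f1 <- make_reference_fit()
  f2 <- make_reference_fit(log_ic50 = -7, hill = 2)
  for (d in c(1, 10, 200)) {
    expect_equal(as.numeric(loewe_expected(d, 0, f1, f2)),
                 100 - predict_4pl(f1, d), tolerance = 1e-7)
    expect_equal(as.numeric(loewe_expected(0, d, f1, f2)),
                 100 - predict_4pl(f2, d), tolerance = 1e-7)
  }
  expect_equal(loewe_expected(0, 0, f1, f2), 0)
  # monotone non-decreasing in each dose
  doses <- 10^seq(0, 3, length.out = 6)
  surf <- outer(doses, doses, Vectorize(function(a, b)
    as.numeric(loewe_expected(a, b, f1, f2))))
  expect_true(all(apply(surf, 1, function(r) all(diff(r) >= -1e-6))))
  expect_true(all(apply(surf, 2, function(c) all(diff(c) >= -1e-6))))
})

test_that("identical-agent Loewe equals the single agent at the summed dose", {
  f <- make_reference_fit(hill = 1.7)
  for (d in c(0.5, 3, 12, 80)) {
    expect_equal(as.numeric(loewe_expected(d, d, f, f)),
                 100 - predict_4pl(f, 2 * d), tolerance = 1e-6)
  }
})

test_that("HSA is the max of single-agent effects and bounded by Loewe", {
  f1 <- make_reference_fit()
  f2 <- make_reference_fit(log_ic50 = -7)
  d1 <- 10; d2 <- 100
  e1 <- 100 - predict_4pl(f1, d1)
  e2 <- 100 - predict_4pl(f2, d2)
  expect_equal(hsa_expected(d1, d2, f1, f2), max(e1, e2))
  expect_equal(hsa_expected(0, 0, f1, f2), 0)
  doses <- 10^seq(0, 3, length.out = 5)
  for (a in doses) for (b in doses) {
    expect_lte(hsa_expected(a, b, f1, f1),
               as.numeric(loewe_expected(a, b, f1, f1)) + 1e-6)
  }
})

test_that("synergy matrices close under their generating model", {
  f1 <- make_reference_fit()
  f2 <- make_reference_fit(log_ic50 = -7.5, hill = 1.3)
  g1 <- 10^seq(0, 4, length.out = 5)
  g2 <- 10^seq(0, 4, length.out = 4)
  for (model in c("loewe", "hsa")) {
    m <- simulate_combination_matrix(model, f1, f2, g1, g2, noise_sd = 0,
                                     seed = 2)
    sm <- synergy_matrix(m$observed, g1, g2, f1, f2, model = model)
    expect_lt(max(abs(sm$delta)), 1e-6)
  }
})

test_that("a planted +15 point cell is recovered as the peak", {
  f <- make_reference_fit()
  g <- 10^seq(0, 4, length.out = 5)
  m <- simulate_combination_matrix("boosted_synergy", f, f, g, g,
                                   interaction_strength = 15,
                                   window = list(rows = 2, cols = 4),
                                   noise_sd = 0, seed = 3)
  sm <- synergy_matrix(m$observed, g, g, f, f, model = "loewe")
  expect_equal(sm$summary$peak_delta, 15, tolerance = 1e-6)
  expect_equal(unname(sm$summary$peak_cell), c(2, 4))
  expect_equal(sm$delta, sm$observed - sm$expected)
})

test_that("synergy summaries are invariant to swapping the two drugs", {
  f1 <- make_reference_fit()
  f2 <- make_reference_fit(log_ic50 = -7.5, hill = 1.3)
  g1 <- 10^seq(0, 3, length.out = 4)
  g2 <- 10^seq(1, 4, length.out = 5)
  m <- simulate_combination_matrix("boosted_synergy", f1, f2, g1, g2,
                                   interaction_strength = 10,
                                   window = list(rows = 3, cols = 2),
                                   noise_sd = 0, seed = 4)
  sm12 <- synergy_matrix(m$observed, g1, g2, f1, f2, model = "loewe")
  sm21 <- synergy_matrix(t(m$observed), g2, g1, f2, f1, model = "loewe")
  expect_equal(sm21$delta, t(sm12$delta), tolerance = 1e-6)
  expect_equal(sm21$summary$mean_delta, sm12$summary$mean_delta,
               tolerance = 1e-9)
  expect_equal(sm21$summary$peak_delta, sm12$summary$peak_delta,
               tolerance = 1e-9)
})
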
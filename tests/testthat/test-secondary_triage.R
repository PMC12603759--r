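make_profile <- function(supp, line = "Moffitt-ns", id = "X",
                         doses = c(50, 200, 650, 2000)) {
  dose_profile(id, line, "ctg", doses, supp)
}

test_that("viability suppression is vehicle-anchored with the right sign", {
  veh <- c(1000, 1100, 900)
  expect_equal(suppression_from_viability(stats::median(veh), veh), 0)
  expect_equal(suppression_from_viability(0, veh), 100)
  expect_equal(suppression_from_viability(1.2 * stats::median(veh), veh),
               -20)
  expect_error(suppression_from_viability(10, c(0, 0)), "> 0")
})

test_that("imaging suppression is the control-based normalized effect", {
  veh <- c(10, 10, 10)
  pos <- c(60, 60, 60)
  expect_equal(suppression_from_imaging(10, veh, pos), 0)
  expect_equal(suppression_from_imaging(60, veh, pos), 100)
  expect_equal(suppression_from_imaging(30, veh, pos), 40)
})

test_that("selectivity filter requires strict >delta at >= min_doses doses", {
  ctl <- make_profile(rep(0, 4), line = "Lf")
  expect_true(selectivity_filter(make_profile(c(45, 50, 10, 5)), ctl))
  expect_false(selectivity_filter(make_profile(c(40, 40, 40, 40)), ctl))
  expect_false(selectivity_filter(make_profile(c(41, 39, 39, 39)), ctl))
  # exceedance doses need not be adjacent
  expect_true(selectivity_filter(make_profile(c(45, 10, 10, 45)), ctl))
  expect_error(
    selectivity_filter(make_profile(c(45, 50, 10, 5)),
                       make_profile(rep(0, 4), line = "Lf",
                                    doses = c(125, 500, 1600, 5000))),
    "mismatch")
})

test_that("efficacy and safety filters are strict at 50% on the top dose", {
  expect_false(efficacy_filter(make_profile(c(90, 80, 20, 50.0))))
  expect_true(efficacy_filter(make_profile(c(0, 10, 20, 50.1))))
  # profile stores ascending doses; the top dose drives the decision
  expect_false(efficacy_filter(make_profile(c(90, 80, 20, 10))))
  expect_true(safety_filter(make_profile(c(0, 0, 0, 49.9), line = "Lf")))
  expect_false(safety_filter(make_profile(c(0, 0, 0, 50.0), line = "Lf")))
  expect_true(safety_filter(make_profile(c(0, 0, 0, -10), line = "Lf")))
})

test_that("dose profiles sort doses and cap suppression at 100", {
  p <- dose_profile("X", "Moffitt-ns", "ctg", c(650, 50, 2000, 200),
                    c(30, 10, 120, 20))
  expect_equal(p$doses_nM, c(50, 200, 650, 2000))
  expect_equal(p$suppression_percent, c(10, 20, 30, 100))
  expect_error(dose_profile("X", "a", "ctg", c(50, 50), c(1, 2)),
               "increasing")
})

test_that("filter decisions are unit-invariant after normalization to nM", {
  t_nm <- make_profile(c(45, 55, 60, 70))
  c_nm <- make_profile(c(0, 5, 5, 10), line = "Lf")
  t_um <- make_profile(c(45, 55, 60, 70),
                       doses = c(0.05, 0.2, 0.65, 2) * 1000)
  c_um <- make_profile(c(0, 5, 5, 10), line = "Lf",
                       doses = c(0.05, 0.2, 0.65, 2) * 1000)
  expect_equal(selectivity_filter(t_nm, c_nm),
               selectivity_filter(t_um, c_um))
  expect_equal(efficacy_filter(t_nm), efficacy_filter(t_um))
})

test_that("raising tumor suppression never flips a pass to a fail", {
  ctl <- make_profile(c(0, 5, 10, 15), line = "Lf")
  base <- c(45, 50, 55, 60)
  stopifnot(selectivity_filter(make_profile(base), ctl),
            efficacy_filter(make_profile(base)))
  set.seed(11)
  for (i in 1:25) {
    bumped <- pmin(base + runif(4, 0, 40), 100)
    expect_true(selectivity_filter(make_profile(bumped), ctl))
    expect_true(efficacy_filter(make_profile(bumped)))
  }
})

test_that("each filter depends only on its documented inputs", {
  tumor <- make_profile(c(45, 55, 60, 70))
  ctl <- make_profile(c(0, 5, 5, 10), line = "Lf")
  # perturbing the control's low doses cannot change efficacy or safety
  ctl2 <- make_profile(c(90, 90, 90, 10), line = "Lf")
  expect_equal(efficacy_filter(tumor), efficacy_filter(tumor))
  expect_equal(safety_filter(ctl), safety_filter(ctl2))
  # perturbing tumor values cannot change safety
  expect_true(safety_filter(ctl))
})

test_that("triage returns the conjunction with deterministic ordering", {
  profiles <- rbind(
    data.frame(compound_id = "B", cell_line = "Moffitt-ns",
               metric_kind = "ctg", dose_nM = c(50, 200, 650, 2000),
               suppression_percent = c(45, 55, 60, 70)),
    data.frame(compound_id = "B", cell_line = "Lf", metric_kind = "ctg",
               dose_nM = c(50, 200, 650, 2000),
               suppression_percent = c(0, 5, 5, 10)),
    # fails only safety
    data.frame(compound_id = "A", cell_line = "Moffitt-ns",
               metric_kind = "ctg", dose_nM = c(50, 200, 650, 2000),
               suppression_percent = c(45, 55, 60, 95)),
    data.frame(compound_id = "A", cell_line = "Lf", metric_kind = "ctg",
               dose_nM = c(50, 200, 650, 2000),
               suppression_percent = c(0, 5, 5, 52)))
  tr <- triage(profiles, "ctg", "Moffitt-ns", "Lf")
  expect_equal(tr$compound_id, c("A", "B"))
  expect_equal(tr$overall, c(FALSE, TRUE))
  expect_equal(tr$selectivity_pass, c(TRUE, TRUE))
  expect_equal(tr$safety_pass, c(FALSE, TRUE))
  expect_error(triage(profiles[1:4, ], "ctg", "Moffitt-ns", "Lf"),
               "missing tumor or control")
})

test_that("triage recovers exactly the planted pan-filter passers", {
  sec <- simulate_secondary_profiles(n_compounds = 104, n_planted = 3,
                                     seed = 21)
  tr <- triage(sec$profiles, "ctg", "Moffitt-ns", "Lf")
  expect_equal(sort(tr$compound_id[tr$overall]),
               sort(sec$truth$compound_id[sec$truth$planted]))
})
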
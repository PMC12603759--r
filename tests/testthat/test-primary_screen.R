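test_that("death fraction pools counts across fields before dividing", {
  expect_equal(well_death_fraction(rep(10, 4), rep(100, 4)), 0.10)
  # pooled sum, not mean of per-field ratios
  expect_equal(well_death_fraction(c(0, 20), c(100, 100)), 20 / 200)
  expect_error(well_death_fraction(5, 0), "QC")
  expect_error(well_death_fraction(numeric(0), numeric(0)), "non-empty")
})

test_that("death series requires the full schedule and orders timepoints", {
  ds <- make_tiny_dataset()
  w <- ds$annotations$well[ds$annotations$role == "library"][1]
  p <- ds$annotations$plate_id[1]
  sr <- death_series(ds, p, w)
  expect_equal(sr$timepoints, c(0, 24, 48, 72))
  expect_length(sr$fractions, 4)
  expect_true(all(sr$fractions >= 0))

  img <- ds$imaging
  keep <- !(img$well == w & img$timepoint_h == 72)
  ds2 <- screen_dataset(ds$annotations, img[keep, ])
  expect_error(death_series(ds2, p, w), "incomplete series")
})

test_that("trapezoid AUC matches closed forms and a brute-force oracle", {
  expect_equal(auc_trapezoid(c(0, 0.5, 0.5, 1.0), c(0, 24, 48, 72)), 36.0)
  # constant fraction c over 72 h integrates to 72 c
  expect_equal(auc_trapezoid(rep(0.3, 4), c(0, 24, 48, 72)), 72 * 0.3)
  # independent piecewise-linear integration oracle on random series
  set.seed(17)
  for (i in 1:20) {
    tp <- sort(sample(0:100, 5))
    while (any(diff(tp) == 0)) tp <- sort(sample(0:100, 5))
    fr <- runif(5)
    expect_equal(auc_trapezoid(fr, tp), pracma::trapz(tp, fr),
                 tolerance = 1e-12)
  }
  expect_error(auc_trapezoid(0.5, 10), ">= 2")
  expect_error(auc_trapezoid(c(0.1, 0.2), c(24, 24)), "increasing")
  # baseline subtraction removes a constant offset
  expect_equal(auc_trapezoid(c(0.1, 0.6, 0.6, 1.1), c(0, 24, 48, 72),
                             baseline_subtract = TRUE), 36.0)
})

test_that("vehicle-anchored effect uses the median and resists outliers", {
  expect_equal(effect_vs_vehicle(0.4, c(0.1, 0.1, 0.1)), 0.3)
  expect_equal(effect_vs_vehicle(stats::median(c(0.2, 0.3, 0.25)),
                                 c(0.2, 0.3, 0.25)), 0)
  clean <- c(0.1, 0.11, 0.09, 0.1, 0.12)
  dirty <- c(0.1, 0.11, 0.09, 0.1, 50)  # one gross outlier
  expect_equal(effect_vs_vehicle(0.5, clean), effect_vs_vehicle(0.5, dirty))
  expect_error(effect_vs_vehicle(1, 0.1), ">= 2")
})

test_that("control-based normalization anchors vehicle at 0 and positive at 100", {
  veh <- c(1.0, 1.1, 0.9)
  pos <- c(5.0, 5.2, 4.8)
  expect_equal(normalize_control_based(stats::median(veh), veh, pos), 0)
  expect_equal(normalize_control_based(stats::median(pos), veh, pos), 100)
  mid <- (stats::median(veh) + stats::median(pos)) / 2
  expect_equal(normalize_control_based(mid, veh, pos), 50)
  expect_error(normalize_control_based(1, c(2, 2), c(2, 2)), "zero control")
})

test_that("robust Z-scores match a brute-force median/MAD oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 100)
  z <- robust_zscores(x)
  oracle <- (x - median(x)) / (1.4826 * median(abs(x - median(x))))
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_equal(robust_zscores(c(1, 2, 3, 4, 5, 6, 7, 8, 9))[5], 0)
  expect_error(robust_zscores(rep(2, 10)), "degenerate")
  expect_error(robust_zscores(1:5), ">= 8")
  # affine invariance: z(a x + b) = z(x) for a > 0
  set.seed(3)
  y <- rnorm(50)
  expect_equal(robust_zscores(3.7 * y + 11), robust_zscores(y),
               tolerance = 1e-12)
})

test_that("hit calling is strict at the threshold and sorts by z", {
  z <- c(A = -3.0, B = -3.01, C = 0.5, D = -8)
  h <- call_hits(z, threshold = -3)
  expect_equal(h$compound_id, c("D", "B", "A", "C"))
  expect_equal(h$is_hit, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("stronger killing gives a more negative killing-oriented z", {
  sim <- simulate_primary_plate(n_compounds = 40, active_fraction = 0,
                                seed = 8)
  h1 <- primary_screen_hits(sim$dataset)
  # raise one compound's death counts and rescore
  ds <- sim$dataset
  cmp <- "CMPD0001"
  w <- ds$annotations$well[!is.na(ds$annotations$compound_id) &
                             ds$annotations$compound_id == cmp]
  sel <- ds$imaging$well == w & ds$imaging$timepoint_h > 0
  ds$imaging$draq7_count[sel] <- ds$imaging$tracker_count[sel]
  h2 <- primary_screen_hits(ds)
  for (mk in c("auc", "final_timepoint")) {
    z1 <- h1$robust_z[h1$metric_kind == mk & h1$compound_id == cmp]
    z2 <- h2$robust_z[h2$metric_kind == mk & h2$compound_id == cmp]
    expect_lt(z2, z1)
  }
  # raw orientation flips the sign of the effect
  h3 <- primary_screen_hits(ds, orientation = "raw")
  expect_equal(h3$effect[order(h3$compound_id, h3$metric_kind)],
               -h2$effect[order(h2$compound_id, h2$metric_kind)])
})

test_that("control-based scheme and pooled scope run end to end", {
  sim <- simulate_primary_plate(n_compounds = 40, active_fraction = 0.1,
                                seed = 9)
  h <- primary_screen_hits(sim$dataset, scheme = "control_based",
                           scope = "pooled")
  expect_true(all(c("auc", "final_timepoint") %in% h$metric_kind))
  expect_equal(nrow(h), 80)
  expect_true(all(is.finite(h$effect)))
})
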
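# Seeded synthetic-data generators with known ground truth, emulating the
# screening assay geometry: 384-well plates, 4 imaging fields per well,
# timepoints 0/24/48/72 h, dual-dye object counts, dose ladders and
# combination matrices.
#
# All generators are pure functions of their arguments including `seed`.

# saturating-exponential death kinetics: plateau f_max, rate k per hour
.death_kinetics <- function(t, f_max, k) f_max * (1 - exp(-k * t))

#' Simulate a primary dual-dye cytotoxicity screen
#'
#' Lays out library compounds with vehicle and positive-control wells on
#' 384-well plates and simulates per-field object counts over the imaging
#' schedule. Each compound's death time course follows a
#' saturating-exponential law `f(t) = f_max (1 - e^(-k t))`; planted
#' actives get `f_max` elevated by `effect_sigma` null standard deviations.
#' Live-stain counts are Poisson around exponential cell growth split over
#' fields; dead-stain counts are Binomial(tracker, f(t)).
#'
#' @param n_compounds number of library compounds (default 2600).
#' @param active_fraction proportion of planted killers (default 0).
#' @param effect_sigma planted effect size in null-SD units of the plateau
#'   death fraction (default 8).
#' @param cells_seeded cells per well at t = 0 (default 400; presets for
#'   other lines are 600 and 900).
#' @param timepoints imaging schedule in hours.
#' @param fields_per_well imaging fields per well (default 4).
#' @param n_vehicle,n_positive control wells per plate (default 16 each).
#' @param seed RNG seed, recorded in metadata.
#' @param cell_line cell-line label.
#' @param concentration_nM library compound dose (default 5000 nM).
#' @param null_fmax_mean,null_fmax_sd null distribution of the plateau
#'   death fraction across compounds.
#' @param vehicle_fmax,positive_fmax control plateaus (the positive-control
#'   concentration is not part of the model; its plateau is the parameter).
#' @param k death rate constant per hour.
#' @param doubling_h cell doubling time in hours.
#' @param with_luminescence also simulate an endpoint viability (CTG-like)
#'   reading proportional to live cells at the final timepoint.
#' @return list with `dataset` (a [screen_dataset()]) and `truth`
#'   (data.frame: compound_id, plate_id, well, is_active, f_max, k).
#' @export
simulate_primary_plate <- function(n_compounds = 2600,
                                   active_fraction = 0,
                                   effect_sigma = 8,
                                   cells_seeded = 400,
                                   timepoints = c(0, 24, 48, 72),
                                   fields_per_well = 4,
                                   n_vehicle = 16, n_positive = 16,
                                   seed = 1,
                                   cell_line = "NS-poly",
                                   concentration_nM = 5000,
                                   null_fmax_mean = 0.15,
                                   null_fmax_sd = 0.035,
                                   vehicle_fmax = 0.05,
                                   positive_fmax = 0.92,
                                   k = 0.05,
                                   doubling_h = 48,
                                   with_luminescence = FALSE) {
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0, 1]")
  }
  if (cells_seeded <= 0) stop("cells_seeded must be > 0")
  set.seed(seed)
  per_plate_lib <- 384 - n_vehicle - n_positive
  n_plates <- ceiling(n_compounds / per_plate_lib)
  all_wells <- paste0(rep(.WELL_ROWS, each = 24), rep(1:24, times = 16))

  n_active <- round(active_fraction * n_compounds)
  is_active <- rep(FALSE, n_compounds)
  if (n_active > 0) is_active[sample.int(n_compounds, n_active)] <- TRUE
  f_max <- pmin(pmax(stats::rnorm(n_compounds, null_fmax_mean,
                                  null_fmax_sd), 0.005), 0.95)
  f_max[is_active] <- pmin(null_fmax_mean + effect_sigma * null_fmax_sd +
                             stats::rnorm(sum(is_active), 0,
                                          null_fmax_sd / 2), 0.95)
  compound_ids <- sprintf("CMPD%04d", seq_len(n_compounds))

  ann <- list(); cmp_idx <- 0L
  for (p in seq_len(n_plates)) {
    plate_id <- sprintf("PLATE%02d", p)
    n_lib <- min(per_plate_lib, n_compounds - cmp_idx)
    roles <- c(rep("vehicle", n_vehicle), rep("positive_control", n_positive),
               rep("library", n_lib))
    wells <- all_wells[seq_along(roles)]
    cids <- c(rep(NA_character_, n_vehicle + n_positive),
              compound_ids[cmp_idx + seq_len(n_lib)])
    conc <- ifelse(roles == "library", concentration_nM, NA_real_)
    ann[[p]] <- data.frame(plate_id = plate_id, well = wells, role = roles,
                           compound_id = cids, concentration_nM = conc,
                           cell_line = cell_line, stringsAsFactors = FALSE)
    cmp_idx <- cmp_idx + n_lib
  }
  ann <- do.call(rbind, ann)

  # per-well kinetics
  fm <- numeric(nrow(ann))
  fm[ann$role == "vehicle"] <- vehicle_fmax
  fm[ann$role == "positive_control"] <- positive_fmax
  fm[ann$role == "library"] <- f_max[match(
    ann$compound_id[ann$role == "library"], compound_ids)]

  n_tp <- length(timepoints)
  n_wells <- nrow(ann)
  # expand to well x timepoint x field
  idx <- rep(seq_len(n_wells), each = n_tp * fields_per_well)
  tp <- rep(rep(timepoints, each = fields_per_well), times = n_wells)
  fld <- rep(seq_len(fields_per_well), times = n_wells * n_tp)
  frac <- .death_kinetics(tp, fm[idx], k)
  lambda_field <- cells_seeded * 2^(tp / doubling_h) / fields_per_well
  tracker <- stats::rpois(length(idx), lambda_field)
  draq7 <- stats::rbinom(length(idx), tracker, frac)
  imaging <- data.frame(plate_id = ann$plate_id[idx], well = ann$well[idx],
                        field = fld, timepoint_h = tp,
                        tracker_count = tracker, draq7_count = draq7,
                        stringsAsFactors = FALSE)

  lum <- NULL
  if (with_luminescence) {
    t_end <- max(timepoints)
    f_end <- .death_kinetics(t_end, fm, k)
    live <- cells_seeded * 2^(t_end / doubling_h) * (1 - f_end)
    rlu <- pmax(stats::rnorm(n_wells, live * 100, live * 2), 0)
    lum <- data.frame(plate_id = ann$plate_id, well = ann$well, rlu = rlu,
                      stringsAsFactors = FALSE)
  }

  truth <- data.frame(
    compound_id = compound_ids,
    plate_id = ann$plate_id[match(compound_ids, ann$compound_id)],
    well = ann$well[match(compound_ids, ann$compound_id)],
    is_active = is_active, f_max = fm[match(compound_ids, ann$compound_id)],
    k = k, stringsAsFactors = FALSE)

  ds <- screen_dataset(
    as_well_annotations(ann), imaging, lum,
    metadata = list(generator = "simulate_primary_plate", seed = seed,
                    n_compounds = n_compounds,
                    active_fraction = active_fraction,
                    effect_sigma = effect_sigma,
                    cells_seeded = cells_seeded,
                    null_fmax_mean = null_fmax_mean,
                    null_fmax_sd = null_fmax_sd))
  list(dataset = ds, truth = truth)
}

#' Simulate a secondary-screen suppression table
#'
#' Emulates the multi-dose secondary screen: each compound gets per-dose
#' suppression profiles in a tumor line and a fibroblast control line.
#' `n_planted` compounds are constructed to pass all three triage filters
#' with wide margins (selective, efficacious, safe); the remaining decoys
#' are drawn from archetypes that fail at least one filter by a wide
#' margin: inactive in both lines, pan-toxic in both lines, or selective
#' but sub-efficacious.
#'
#' @param n_compounds total compounds (default 104).
#' @param n_planted compounds passing all filters (default 3).
#' @param doses_nM ascending dose ladder (default 50/200/650/2000 nM; the
#'   alternate ladder is 125/500/1600/5000 nM).
#' @param metric_kind label for the profiles (default `"ctg"`).
#' @param tumor_line,control_line cell-line labels.
#' @param replicates replicate wells per (compound, line, dose).
#' @param noise_sd replicate noise in suppression points.
#' @param seed RNG seed.
#' @return list with `profiles` (long data.frame: compound_id, cell_line,
#'   metric_kind, dose_nM, replicate, suppression_percent) and `truth`
#'   (compound_id, planted, archetype).
#' @export
simulate_secondary_profiles <- function(n_compounds = 104, n_planted = 3,
                                        doses_nM = c(50, 200, 650, 2000),
                                        metric_kind = "ctg",
                                        tumor_line = "Moffitt-ns",
                                        control_line = "Lf",
                                        replicates = 3, noise_sd = 3,
                                        seed = 1) {
  if (n_planted > n_compounds) stop("n_planted must be <= n_compounds")
  set.seed(seed)
  nd <- length(doses_nM)
  ids <- sprintf("SCMPD%03d", seq_len(n_compounds))
  planted <- rep(FALSE, n_compounds)
  if (n_planted > 0) planted[sample.int(n_compounds, n_planted)] <- TRUE
  archetype <- character(n_compounds)
  archetype[planted] <- "planted_passer"
  archetype[!planted] <- sample(c("inactive", "pan_toxic",
                                  "selective_weak"),
                                sum(!planted), replace = TRUE)
  mean_profiles <- function(a) {
    # returns list(tumor, control) mean suppression per dose
    switch(a,
      planted_passer = list(
        tumor = seq(30, 90, length.out = nd),
        control = seq(0, 20, length.out = nd)),
      inactive = list(
        tumor = stats::runif(1, 0, 15) + seq(0, 10, length.out = nd),
        control = stats::runif(1, 0, 10) + seq(0, 10, length.out = nd)),
      pan_toxic = list(
        tumor = seq(60, 95, length.out = nd),
        control = seq(55, 90, length.out = nd)),
      selective_weak = list(
        tumor = seq(5, 30, length.out = nd),
        control = seq(-15, -5, length.out = nd)))
  }
  rows <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    mp <- mean_profiles(archetype[i])
    for (line in c(tumor_line, control_line)) {
      mu <- if (line == tumor_line) mp$tumor else mp$control
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = ids[i], cell_line = line,
          metric_kind = metric_kind, dose_nM = doses_nM, replicate = r,
          suppression_percent = mu + stats::rnorm(nd, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  profiles <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(profiles) <- NULL
  list(profiles = profiles,
       truth = data.frame(compound_id = ids, planted = planted,
                          archetype = archetype, stringsAsFactors = FALSE))
}

#' Simulate dose-response viability data from a 4PL curve
#'
#' @param bottom,top,log_ic50,hill generating 4PL parameters (`log_ic50` in
#'   log10 molar).
#' @param doses_nM dose ladder (> 0).
#' @param replicates replicates per dose.
#' @param noise_sd Gaussian noise in viability points; observations are
#'   truncated to the instrument-plausible range [-20, 150].
#' @param seed RNG seed.
#' @return list with `data` (dose_nM, replicate, viability_percent) and
#'   `truth` (the generating parameters).
#' @export
simulate_dose_response <- function(bottom = 0, top = 100, log_ic50 = -8,
                                   hill = 1,
                                   doses_nM = 10^seq(0, 4, length.out = 8),
                                   replicates = 4, noise_sd = 5,
                                   seed = 1) {
  if (any(doses_nM <= 0)) stop("doses must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  d <- rep(doses_nM, times = replicates)
  rep_idx <- rep(seq_len(replicates), each = length(doses_nM))
  mu <- .fourpl(.log10_molar(d), bottom, top, log_ic50, hill)
  y <- pmin(pmax(mu + stats::rnorm(length(d), 0, noise_sd), -20), 150)
  list(data = data.frame(dose_nM = d, replicate = rep_idx,
                         viability_percent = y, stringsAsFactors = FALSE),
       truth = list(bottom = bottom, top = top, log_ic50 = log_ic50,
                    hill = hill, noise_sd = noise_sd, seed = seed))
}

#' Simulate an observed combination-matrix effect surface
#'
#' Generates the expected effect surface (fraction affected, percent) over
#' a dose-by-dose grid under a chosen null model -- Loewe additivity, HSA,
#' or Bliss independence -- optionally boosts synergy by adding
#' `interaction_strength` effect points inside a window of cells
#' (`boosted_synergy`, on top of the Loewe surface), and adds Gaussian
#' noise.
#'
#' @param model `"loewe"`, `"hsa"`, `"bliss"`, or `"boosted_synergy"`.
#' @param fit1,fit2 converged single-agent `fit_4pl`s (ground truth).
#' @param doses1_nM,doses2_nM dose grids (may include 0).
#' @param interaction_strength effect-point offset for `boosted_synergy`.
#' @param window list with `rows` and `cols` (cell indices) receiving the
#'   boost; default the single central cell.
#' @param noise_sd Gaussian noise in effect points.
#' @param seed RNG seed.
#' @return list with `observed` matrix, `expected` truth matrix, dose
#'   grids, and the generator parameters.
#' @export
simulate_combination_matrix <- function(model = c("loewe", "hsa", "bliss",
                                                  "boosted_synergy"),
                                        fit1, fit2,
                                        doses1_nM, doses2_nM,
                                        interaction_strength = 0,
                                        window = NULL,
                                        noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  if (model == "boosted_synergy" && interaction_strength == 0) {
    stop("boosted_synergy requires a non-zero interaction_strength")
  }
  set.seed(seed)
  n1 <- length(doses1_nM); n2 <- length(doses2_nM)
  expected <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      d1 <- doses1_nM[i]; d2 <- doses2_nM[j]
      expected[i, j] <- switch(
        model,
        loewe = , boosted_synergy =
          as.numeric(loewe_expected(d1, d2, fit1, fit2)),
        hsa = hsa_expected(d1, d2, fit1, fit2),
        bliss = {
          e1 <- if (d1 == 0) 0 else .fa_percent(fit1, d1)
          e2 <- if (d2 == 0) 0 else .fa_percent(fit2, d2)
          e1 + e2 - e1 * e2 / 100
        })
    }
  }
  if (model == "boosted_synergy") {
    if (is.null(window)) {
      window <- list(rows = ceiling(n1 / 2), cols = ceiling(n2 / 2))
    }
    expected[window$rows, window$cols] <-
      expected[window$rows, window$cols] + interaction_strength
  }
  observed <- expected +
    matrix(stats::rnorm(n1 * n2, 0, noise_sd), n1, n2)
  list(observed = observed, expected = expected, doses1_nM = doses1_nM,
       doses2_nM = doses2_nM,
       params = list(model = model,
                   interaction_strength = interaction_strength,
                   noise_sd = noise_sd, seed = seed))
}
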
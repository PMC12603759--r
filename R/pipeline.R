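# End-to-end orchestration: simulate -> primary screen -> triage ->
# dose-response -> synergy, with plain-text outputs and a markdown report.

#' Default pipeline configuration
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @param ... overrides for any configuration entry.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("run"), ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    n_compounds = 260,           # scaled-down library for routine runs
    active_fraction = 0.05,
    effect_sigma = 8,
    z_threshold = -3,
    scheme = "test_population",
    orientation = "killing_negative",
    scope = "per_plate",
    n_secondary = 104,
    n_planted = 3,
    secondary_doses_nM = c(50, 200, 650, 2000),
    selectivity_delta = 40,
    selectivity_min_doses = 2,
    efficacy_cutoff = 50,
    safety_cutoff = 50,
    dr_doses_nM = 10^seq(0, 4, length.out = 8),
    dr_noise_sd = 5,
    ci_levels = c(0.5, 0.75, 0.9),
    synergy_model = "loewe")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full screening pipeline on seeded simulations
#'
#' Stages, in dependency order: primary-screen simulation and robust-Z hit
#' calling; secondary-screen simulation and three-filter triage;
#' dose-response simulation, 4PL fits and ICx table; sham-combination CI
#' and a boosted-synergy matrix. Each stage writes its table under
#' `out_dir`; a config echo with the seed accompanies every run.
#'
#' @param config list from [pipeline_config()].
#' @return list of stage results, class `pipeline_run`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  required <- names(pipeline_config())
  unknown <- setdiff(names(config), required)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- primary screen ---
  sim <- simulate_primary_plate(
    n_compounds = config$n_compounds,
    active_fraction = config$active_fraction,
    effect_sigma = config$effect_sigma, seed = config$seed)
  hits <- primary_screen_hits(
    sim$dataset, scheme = config$scheme,
    orientation = config$orientation, scope = config$scope,
    threshold = config$z_threshold)
  utils::write.table(hits, file.path(config$out_dir, "primary_hits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- secondary triage ---
  sec <- simulate_secondary_profiles(
    n_compounds = config$n_secondary, n_planted = config$n_planted,
    doses_nM = config$secondary_doses_nM, seed = config$seed + 1)
  tri <- triage(sec$profiles, metric_kind = "ctg",
                tumor_line = "Moffitt-ns", control_line = "Lf",
                delta = config$selectivity_delta,
                min_doses = config$selectivity_min_doses,
                efficacy_cutoff = config$efficacy_cutoff,
                safety_cutoff = config$safety_cutoff)
  utils::write.table(tri, file.path(config$out_dir, "triage.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- dose-response ---
  dr <- simulate_dose_response(doses_nM = config$dr_doses_nM,
                               noise_sd = config$dr_noise_sd,
                               seed = config$seed + 2)
  fit <- fit_4pl(dr$data$dose_nM, dr$data$viability_percent)
  ic_tab <- do.call(rbind, lapply(c(0.5, 0.75, 0.9), function(x) {
    r <- icx(fit, level = x)
    data.frame(level = x, dose_nM = r$dose_nM, reachable = r$reachable)
  }))
  utils::write.csv(ic_tab, file.path(config$out_dir, "ic_table.csv"),
                   row.names = FALSE)

  # --- synergy: sham self-combination CI + boosted Loewe matrix ---
  # sham self-combination: "drug 1 + drug 2" are the same agent, each
  # contributing half of the total dose -- additivity ground truth CI = 1
  ci_tab <- combination_ci(dr$data$dose_nM / 2, dr$data$viability_percent,
                           ratio = 1, fit1 = fit, fit2 = fit,
                           levels = config$ci_levels)
  utils::write.table(ci_tab, file.path(config$out_dir, "ci_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  grid <- 10^seq(0, 4, length.out = 5)
  mat <- simulate_combination_matrix("boosted_synergy", fit, fit,
                                     grid, grid,
                                     interaction_strength = 15,
                                     noise_sd = 0, seed = config$seed + 3)
  sm <- synergy_matrix(mat$observed, grid, grid, fit, fit,
                       model = config$synergy_model)
  utils::write.csv(as.data.frame(sm$delta),
                   file.path(config$out_dir, "synergy_delta.csv"),
                   row.names = FALSE)

  run <- structure(list(config = config, primary = hits,
                        primary_truth = sim$truth, triage = tri,
                        triage_truth = sec$truth, fit = fit,
                        ic_table = ic_tab, ci_table = ci_tab,
                        synergy = sm),
                   class = "pipeline_run")
  report <- render_report(run)
  writeLines(report, file.path(config$out_dir, "report.md"))
  run
}

#' Render a markdown report for a pipeline run
#'
#' @param run a `pipeline_run`.
#' @return character vector of markdown lines.
#' @export
render_report <- function(run) {
  cfg <- run$config
  lines <- c("# Screening pipeline report", "",
             sprintf("Seed: %d", cfg$seed), "")
  if (!is.null(run$primary)) {
    hit_counts <- tapply(run$primary$is_hit, run$primary$metric_kind, sum)
    lines <- c(lines, "## Primary screen", "",
               sprintf("- %s hits (robust Z < %g): %d", names(hit_counts),
                       cfg$z_threshold, as.integer(hit_counts)), "")
  }
  if (!is.null(run$triage)) {
    surv <- run$triage$compound_id[run$triage$overall]
    lines <- c(lines, "## Secondary triage", "",
               sprintf("- %d of %d compounds pass all three filters: %s",
                       length(surv), nrow(run$triage),
                       paste(surv, collapse = ", ")), "")
  }
  if (!is.null(run$ic_table)) {
    lines <- c(lines, "## Dose-response", "",
               "| level | dose_nM | reachable |", "|---|---|---|",
               sprintf("| IC%g | %.4g | %s |", 100 * run$ic_table$level,
                       run$ic_table$dose_nM, run$ic_table$reachable), "")
  }
  if (!is.null(run$ci_table) && nrow(run$ci_table) > 0) {
    lines <- c(lines, "## Combination index", "",
               "| level | CI | band |", "|---|---|---|",
               sprintf("| %g | %.3f | %s |", run$ci_table$effect_level,
                       run$ci_table$ci, run$ci_table$band), "")
  }
  if (!is.null(run$synergy)) {
    s <- run$synergy$summary
    lines <- c(lines, "## Synergy matrix", "",
               sprintf("- model: %s; mean delta %.3f; peak delta %.3f at cell (%d, %d)",
                       run$synergy$model, s$mean_delta, s$peak_delta,
                       s$peak_cell["row"], s$peak_cell["col"]), "")
  }
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
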
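# Shared fixtures, built in code at test time.

# a tiny complete two-plate dataset: 2 library + 2 vehicle + 1 positive
# wells per plate, 2 fields, full 0/24/48/72 h schedule
make_tiny_dataset <- function(seed = 1) {
  sim <- simulate_primary_plate(n_compounds = 4, active_fraction = 0,
                                n_vehicle = 2, n_positive = 1,
                                fields_per_well = 2, seed = seed)
  sim$dataset
}

# noiseless single-agent fit with known truth (IC50 = 10 nM, hill = 1)
make_reference_fit <- function(bottom = 0, top = 100, log_ic50 = -8,
                               hill = 1) {
  sim <- simulate_dose_response(bottom = bottom, top = top,
                                log_ic50 = log_ic50, hill = hill,
                                noise_sd = 0, seed = 99)
  fit_4pl(sim$data$dose_nM, sim$data$viability_percent)
}

# write a small CSV and return its path
write_fixture_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
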
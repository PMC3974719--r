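# Shared fixtures, all built in code.

# A small, fast stock used where the test exercises machinery rather than a
# packaged configuration: 6 ages, 15 years, quick growth.
tiny_lh <- function(sigma_R = 0.4) {
  life_history(
    name = "tiny", ages = 0:5, years = 2001:2015,
    M = 0.35, Linf = 40, k = 0.45, t0 = -0.3,
    w_alpha = 8e-6, w_beta = 3.0, mat_a50 = 1.5, mat_slope = 2,
    h = 0.65, R0 = 1e6, sigma_R = sigma_R, cv_length = 0.1,
    length_bins = seq(8, 44, by = 4),
    fleets = list(
      fleet_spec(1, "fishery", sel_a50 = 1.8, sel_slope = 2),
      fleet_spec(2, "survey", sel_a50 = 1.2, sel_slope = 2, q = 1)))
}

tiny_f <- function(lh, f_max = 0.3) {
  build_f_series(list(pattern = "ramp_constant", f_max = f_max,
                      ramp_years = 5), lh$years)
}

# Truth + sampled dataset for a stock under its default harvest pattern.
simulate_dataset <- function(lh, seed, f = NULL, sds_obs = 0.1, Nsamp = 100,
                             survey_every = 2, lencomp = TRUE) {
  if (is.null(f)) f <- tiny_f(lh)
  devs <- make_rec_devs(lh$sigma_R, lh$years, seed = seed)
  truth <- project(lh, f, devs)
  svy <- seq(min(lh$years), max(lh$years), by = survey_every)
  idx <- sample_index(truth, index_spec(2, svy, sds_obs), seed + 1L)
  ac <- sample_agecomp(truth, comp_spec(c(1, 2), list(lh$years, svy), Nsamp),
                       seed + 2L)
  lc <- if (lencomp) {
    sample_lcomp(truth, comp_spec(c(1, 2), list(lh$years, svy), Nsamp),
                 seed + 3L)
  } else NULL
  list(truth = truth,
       data = observed_dataset(idx, ac, lc, catch_series(truth)))
}

# Case files for the tiny stock, written into a temporary case folder.
write_tiny_cases <- function(dir, species = "tiny") {
  w <- function(name, lines) writeLines(lines, file.path(dir, name))
  w(paste0("index0-", species, ".txt"),
    c("fleets; 2", "years; list(seq(2001, 2015, by = 2))",
      "sds_obs; list(0.1)"))
  w(paste0("index1-", species, ".txt"),
    c("fleets; 2", "years; list(seq(2001, 2015, by = 2))",
      "sds_obs; list(0.4)"))
  for (k in 0:1) {
    w(paste0("agecomp", k, "-", species, ".txt"),
      c("fleets; c(1, 2)",
        "years; list(seq(2001, 2015, by = 1), seq(2001, 2015, by = 2))",
        "Nsamp; list(50, 50)"))
    w(paste0("lcomp", k, "-", species, ".txt"),
      c("fleets; c(1, 2)",
        "years; list(seq(2001, 2015, by = 1), seq(2001, 2015, by = 2))",
        "Nsamp; list(50, 50)"))
  }
  w(paste0("E0-", species, ".txt"), 'M; "fixed"')
  w(paste0("E1-", species, ".txt"), 'M; "estimated"')
  w(paste0("F0-", species, ".txt"),
    c('pattern; "ramp_constant"', "f_max; 0.3", "ramp_years; 5"))
  w(paste0("M0-", species, ".txt"),
    c('function_type; "change_tv"', 'param; "M"', "dev; 0"))
  w(paste0("R0-", species, ".txt"), "retro_yr; 0")
  invisible(dir)
}

# Noise-free observations taken directly from the truth's expected values.
exact_dataset <- function(truth, svy_years = NULL, se_log = 0.1,
                          Nsamp = 100) {
  lh <- truth$lh
  if (is.null(svy_years)) svy_years <- lh$years
  sid <- as.character(survey_id <- 2L)
  idx <- tibble::tibble(
    fleet = survey_id, year = as.integer(svy_years),
    value = as.numeric(truth$true_index[[sid]][as.character(svy_years)]),
    se_log = se_log)
  mk <- function(E, fleet, yrs) {
    dplyr::bind_rows(lapply(yrs, function(y) tibble::tibble(
      fleet = fleet, year = as.integer(y), Nsamp = Nsamp,
      bin = as.numeric(rownames(E)), prop = E[, as.character(y)])))
  }
  ac <- dplyr::bind_rows(mk(truth$expected_agecomp[["1"]], 1L, lh$years),
                         mk(truth$expected_agecomp[["2"]], 2L, svy_years))
  lc <- dplyr::bind_rows(mk(truth$expected_lencomp[["1"]], 1L, lh$years),
                         mk(truth$expected_lencomp[["2"]], 2L, svy_years))
  observed_dataset(idx, ac, lc, catch_series(truth))
}

# Natural-scale true parameter list for a two-fleet life history.
true_params <- function(lh, devs) {
  list(M = lh$M[1], h = lh$h, R0 = lh$R0, sigma_R = lh$sigma_R,
       sel_a50 = vapply(lh$fleets, function(f) f$sel_a50[1], numeric(1)),
       sel_slope = vapply(lh$fleets, function(f) f$sel_slope[1], numeric(1)),
       q = vapply(lh$fleets, function(f) ifelse(is.na(f$q[1]), 1, f$q[1]),
                  numeric(1)),
       rec_devs = as.numeric(devs))
}

eg_case_folder <- function() {
  system.file("extdata", "eg-cases", package = "scaloop")
}

expect_tibble_cols <- function(df, cols) {
  expect_true(all(cols %in% names(df)),
              info = paste("missing:", paste(setdiff(cols, names(df)),
                                             collapse = ", ")))
}
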
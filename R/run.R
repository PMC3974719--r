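# ---- case-bundle -> argument resolution --------------------------------

index_spec_from_case <- function(case) {
  index_spec(fleets = unlist(case$fleets), years = case$years,
             sds_obs = case$sds_obs)
}
comp_spec_from_case <- function(case) {
  comp_spec(fleets = unlist(case$fleets), years = case$years,
            Nsamp = case$Nsamp)
}
toggles_from_case <- function(case) {
  case <- case[setdiff(names(case), "comment")]
  bad <- setdiff(names(case), em_toggle_names)
  if (length(bad) > 0) {
    stop("E case contains unknown toggle(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  case
}
tv_from_case <- function(case) {
  if (is.null(case)) return(list())
  if (!identical(case$function_type, "change_tv")) {
    stop("M case file must declare 'function_type; \"change_tv\"'",
         call. = FALSE)
  }
  if (is.null(case$param) || is.null(case$dev)) {
    stop("change_tv case needs 'param' and 'dev' keys", call. = FALSE)
  }
  dev <- unlist(case$dev)
  if (length(dev) == 1 && dev == 0) return(list())
  stats::setNames(list(dev), case$param)
}
retro_from_case <- function(case) {
  if (is.null(case) || is.null(case$retro_yr)) 0L else as.integer(case$retro_yr)
}

# ---- plain-text serialization ------------------------------------------

fmt_val <- function(x) {
  if (is.logical(x)) return(as.character(x))
  if (is.character(x)) return(paste0('"', x, '"'))
  sprintf("%.17g", x)
}
write_kv <- function(x, path) {
  writeLines(paste0(names(x), "; ",
                    vapply(x, fmt_val, character(1))), path)
}
read_kv <- function(path) parse_case_file(path)

write_em_data <- function(data, path) {
  blocks <- list(
    dplyr::mutate(data$index, section = "index", bin = NA_real_,
                  Nsamp = NA_real_),
    dplyr::mutate(data$agecomp, section = "agecomp", se_log = NA_real_,
                  value = .data$prop),
    dplyr::mutate(data$lencomp, section = "lencomp", se_log = NA_real_,
                  value = .data$prop),
    dplyr::mutate(data$catch, section = "catch", bin = NA_real_,
                  se_log = NA_real_, Nsamp = NA_real_))
  out <- dplyr::bind_rows(blocks)[
    , c("section", "fleet", "year", "bin", "value", "se_log", "Nsamp")]
  readr::write_csv(out, path, progress = FALSE)
}

om_scalar_list <- function(truth, lh_om) {
  ff <- fishery_fleets(lh_om)[[1]]
  bio_sel <- logistic_age(lh_om$ages, base_val(ff$sel_a50),
                          base_val(ff$sel_slope))
  L <- mean_length_at_age(lh_om$ages, base_val(lh_om$Linf),
                          base_val(lh_om$k), lh_om$t0)
  msy <- msy_reference_points(lh_om$ages, base_val(lh_om$M), lh_om$h,
                              lh_om$R0,
                              weight_at_length(L, lh_om$w_alpha,
                                               lh_om$w_beta),
                              maturity_at_age(lh_om), bio_sel)
  ny <- length(truth$years)
  list(SSB_terminal = unname(truth$SSB[ny]),
       depletion = unname(truth$depletion[ny]),
       SSB_MSY = msy$SSB_MSY, F_MSY = msy$F_MSY, MSY = msy$MSY,
       F_terminal = unname(Reduce(`+`, truth$F)[ny]),
       M = base_val(lh_om$M), h = lh_om$h, R0 = lh_om$R0,
       SSB0 = truth$SSB0, sigma_R = lh_om$sigma_R)
}

em_scalar_list <- function(ft) {
  est <- function(term) {
    v <- ft$estimates$estimate[ft$estimates$term == term]
    if (length(v) == 0) NA_real_ else v[1]
  }
  ny <- nrow(ft$ssb)
  list(SSB_terminal = ft$ssb$est[ny], depletion = ft$depletion,
       SSB_MSY = ft$SSB_MSY, F_MSY = ft$F_MSY, MSY = ft$MSY,
       F_terminal = ft$F_terminal, M = est("M"), h = est("h"),
       R0 = est("R0"), SSB0 = ft$SSB0,
       nll = ft$nll, max_gradient = ft$max_gradient,
       covariance_ok = isTRUE(ft$covariance_ok),
       n_params_on_bounds = as.numeric(ft$n_params_on_bounds),
       runtime = ft$runtime, converged = isTRUE(ft$converged))
}

# ---- one scenario x iteration ------------------------------------------

run_iteration <- function(scn, iter, lh_om, lh_em, cases, base_seed,
                          bias_adjust, out_dir) {
  t_start <- proc.time()[["elapsed"]]
  iter_dir <- file.path(out_dir, iter)
  dir.create(iter_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  log_lines <- character(0)
  log_stage <- function(stage, t0) {
    sprintf("scenario=%s iteration=%d stage=%s elapsed=%.2fs",
            scn$id, iter, stage, proc.time()[["elapsed"]] - t0)
  }
  tryCatch({
    stage <- "operating_model"
    t0 <- proc.time()[["elapsed"]]
    lh_tv <- apply_tv(lh_om, tv_from_case(cases$M))
    f <- build_f_series(cases$F, lh_tv$years)
    devs <- make_rec_devs(lh_tv$sigma_R, lh_tv$years,
                          seed = process_seed(base_seed, iter))
    truth <- project(lh_tv, f, devs)
    readr::write_csv(om_truth_table(truth),
                     file.path(iter_dir, "om_truth.csv"), progress = FALSE)
    readr::write_csv(om_ts_table(truth),
                     file.path(iter_dir, "om_ts.csv"), progress = FALSE)
    write_kv(om_scalar_list(truth, lh_om),
             file.path(iter_dir, "om_scalars.txt"))
    log_lines <- c(log_lines, log_stage(stage, t0))

    stage <- "sampling"
    t0 <- proc.time()[["elapsed"]]
    oseed <- function(s) observation_seed(base_seed, iter, scn$id, s)
    data <- observed_dataset(
      index = sample_index(truth, index_spec_from_case(cases$D$index),
                           oseed("index")),
      agecomp = sample_agecomp(truth, comp_spec_from_case(cases$D$agecomp),
                               oseed("agecomp")),
      lencomp = sample_lcomp(truth, comp_spec_from_case(cases$D$lcomp),
                             oseed("lcomp")),
      catch = catch_series(truth))
    write_em_data(data, file.path(iter_dir, "em_data.csv"))
    log_lines <- c(log_lines, log_stage(stage, t0))

    stage <- "estimation"
    t0 <- proc.time()[["elapsed"]]
    cfg <- em_config(lh_em, toggles = toggles_from_case(cases$E))
    if (bias_adjust) cfg <- run_bias_adjust(cfg, data)
    ft <- fit(cfg, data)
    scal <- em_scalar_list(ft)
    log_lines <- c(log_lines, log_stage(stage, t0))

    retro_yr <- retro_from_case(cases$R)
    if (retro_yr > 0) {
      stage <- "retrospective"
      t0 <- proc.time()[["elapsed"]]
      retro <- run_retrospective(cfg, data, retro_yr)
      rho <- mohns_rho(retro)
      scal$mohns_rho_SSB <- rho
      readr::write_csv(tibble::tibble(
        peel = attr(retro, "peels"),
        terminal_year = vapply(retro, function(f) max(f$ssb$year),
                               numeric(1)),
        SSB_terminal = vapply(retro, function(f) f$ssb$est[nrow(f$ssb)],
                              numeric(1)),
        converged = vapply(retro, function(f) f$converged, logical(1))),
        file.path(iter_dir, "retro.csv"), progress = FALSE)
      log_lines <- c(log_lines, log_stage(stage, t0))
    }

    stage <- "output"
    write_kv(scal, file.path(iter_dir, "em_scalars.txt"))
    readr::write_csv(tibble::tibble(
      year = ft$ssb$year, SSB = ft$ssb$est, SSB_se = ft$ssb$se,
      R = ft$recruits$est, R_se = ft$recruits$se, F = ft$F_series$est),
      file.path(iter_dir, "em_ts.csv"), progress = FALSE)
    write_kv(list(scenario = scn$id, iteration = iter,
                  species = scn$species, base_seed = base_seed,
                  process_seed = process_seed(base_seed, iter),
                  bias_adjust = bias_adjust,
                  b_y_mean = mean(cfg$b_y)),
             file.path(iter_dir, "config.txt"))
    writeLines(log_lines, file.path(iter_dir, "log.txt"))
    tibble::tibble(scenario = scn$id, iteration = iter, status = "ok",
                   stage = NA_character_, message = NA_character_,
                   elapsed = proc.time()[["elapsed"]] - t_start)
  }, error = function(e) {
    tibble::tibble(scenario = scn$id, iteration = iter, status = "failed",
                   stage = stage, message = conditionMessage(e),
                   elapsed = proc.time()[["elapsed"]] - t_start)
  })
}

#' Run one scenario from directly supplied argument bundles
#'
#' The underlying base simulation: skips case files and takes the parsed
#' argument bundles directly. [run_simulation()] is a thin loop over
#' `base_run()` after reading the case files, so the two produce identical
#' outputs for equivalent inputs.
#'
#' @param om,em `life_history` objects (or built-in names / file paths) for
#'   the operating and estimation models.
#' @param cases Named list of argument bundles: `D` (list with `index`,
#'   `agecomp`, `lcomp` key-value lists), `F` (fishing pattern), and
#'   optionally `E` (estimation toggles), `M` (time-varying change), `R`
#'   (retrospective). `D` and `F` are required.
#' @param iterations Integer vector of iteration numbers.
#' @param scenario_id Folder/ID name for this run.
#' @param output_dir Root output directory.
#' @param base_seed Integer base seed.
#' @param bias_adjust Calibrate recruitment bias adjustment per iteration.
#' @param parallel_workers Forked workers (1 = serial; any count gives
#'   byte-identical output).
#' @return A tibble report, one row per iteration (`status`, failing
#'   `stage` and `message` if any, `elapsed` seconds).
#' @export
base_run <- function(om, em = om, cases, iterations,
                     scenario_id = "BASE-run", output_dir = ".",
                     base_seed = 1, bias_adjust = FALSE,
                     parallel_workers = 1) {
  required <- c("D", "F")
  missing_bundles <- setdiff(required, names(cases))
  if (length(missing_bundles) > 0) {
    stop("missing argument bundle(s): ",
         paste(missing_bundles, collapse = ", "), call. = FALSE)
  }
  for (part in c("index", "agecomp", "lcomp")) {
    if (is.null(cases$D[[part]])) {
      stop("data bundle D is missing its '", part, "' component",
           call. = FALSE)
    }
  }
  scn <- list(id = scenario_id, species = if (inherits(om, "life_history"))
    om$name else as.character(om))
  lh_om <- resolve_life_history(om, scn$species)
  lh_em <- resolve_life_history(em, scn$species)
  out_dir <- file.path(output_dir, scenario_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runner <- function(iter) {
    run_iteration(scn, iter, lh_om, lh_em, cases, base_seed, bias_adjust,
                  out_dir)
  }
  rows <- if (parallel_workers > 1) {
    parallel::mclapply(iterations, runner, mc.cores = parallel_workers)
  } else {
    lapply(iterations, runner)
  }
  dplyr::bind_rows(rows)
}

#' Run a full simulation over scenarios and iterations
#'
#' For every scenario x iteration: derive seeds, build the recruitment
#' deviations and F series, project the operating-model truth, sample
#' observations, optionally calibrate recruitment bias adjustment, fit the
#' estimation model (plus a retrospective analysis when the R case asks for
#' one), and write a `<scenario>/<iteration>/` folder containing the OM
#' truth, the sampled data and the EM results, all in plain text. A re-run
#' with an identical configuration reproduces byte-identical outputs; a
#' failed iteration is recorded in the report and never aborts the batch.
#'
#' @param rc A [run_config()].
#' @return A tibble report with one row per scenario x iteration.
#' @export
run_simulation <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  reports <- lapply(rc$scenarios, function(id) {
    scn <- parse_scenario_id(id)
    need <- c("D", "E", "F", "M", "R")
    missing_cases <- setdiff(need, names(scn$cases))
    if (length(missing_cases) > 0) {
      stop("scenario ", id, " is missing case letter(s): ",
           paste(missing_cases, collapse = ", "), call. = FALSE)
    }
    cases <- lapply(stats::setNames(nm = names(scn$cases)), function(L) {
      read_case(rc$case_folder, L, scn$cases[[L]], scn$species)
    })
    base_run(om = rc$om %||% scn$species, em = rc$em %||% scn$species,
             cases = cases, iterations = rc$iterations,
             scenario_id = id, output_dir = rc$output_dir,
             base_seed = rc$base_seed, bias_adjust = rc$bias_adjust,
             parallel_workers = rc$parallel_workers)
  })
  dplyr::bind_rows(reports)
}
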
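scalar_quantities <- c("SSB_terminal", "depletion", "SSB_MSY", "F_terminal",
                       "F_MSY", "M", "h", "R0", "SSB0")
# runtime stays in each iteration's em_scalars.txt but is excluded from the
# harvested csv so identical re-runs remain byte-identical
diag_cols <- c("nll", "max_gradient", "covariance_ok", "n_params_on_bounds",
               "converged")

#' Relative error of an estimate against the truth
#'
#' `(em - om) / om`; vectorized.
#'
#' @param em_value Estimation-model value(s).
#' @param om_value Operating-model (true) value(s); must be non-zero.
#' @return Dimensionless relative error(s).
#' @export
relative_error <- function(em_value, om_value) {
  if (any(om_value == 0, na.rm = TRUE)) {
    stop("relative error undefined: operating-model value is 0",
         call. = FALSE)
  }
  (em_value - om_value) / om_value
}

#' Add relative-error columns to a results table
#'
#' For every paired `<q>_om` / `<q>_em` column adds `<q>_re` computed
#' row-wise as `(em - om) / om`.
#'
#' @param df A scalar or time-series results tibble.
#' @return `df` with `_re` columns appended.
#' @export
add_relative_error <- function(df) {
  om_cols <- grep("_om$", names(df), value = TRUE)
  for (oc in om_cols) {
    q <- sub("_om$", "", oc)
    ec <- paste0(q, "_em")
    if (!ec %in% names(df)) next
    df[[paste0(q, "_re")]] <- ifelse(
      is.na(df[[oc]]) | df[[oc]] == 0, NA_real_,
      (df[[ec]] - df[[oc]]) / df[[oc]])
  }
  df
}

read_iteration_scalars <- function(iter_dir, scenario, iteration) {
  om <- read_kv(file.path(iter_dir, "om_scalars.txt"))
  row <- tibble::tibble(scenario = scenario, iteration = iteration)
  for (q in scalar_quantities) {
    row[[paste0(q, "_om")]] <- as.numeric(om[[q]] %||% NA_real_)
  }
  em_path <- file.path(iter_dir, "em_scalars.txt")
  em <- if (file.exists(em_path)) read_kv(em_path) else list()
  for (q in scalar_quantities) {
    row[[paste0(q, "_em")]] <- as.numeric(em[[q]] %||% NA_real_)
  }
  for (d in diag_cols) {
    v <- em[[d]]
    row[[d]] <- if (d %in% c("covariance_ok", "converged")) {
      isTRUE(as.logical(v %||% FALSE))
    } else as.numeric(v %||% NA_real_)
  }
  row$mohns_rho_SSB <- as.numeric(em[["mohns_rho_SSB"]] %||% NA_real_)
  row
}

read_iteration_ts <- function(iter_dir, scenario, iteration) {
  om <- readr::read_csv(file.path(iter_dir, "om_ts.csv"),
                        show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(scenario = scenario, iteration = iteration,
                        year = as.integer(om$year),
                        SSB_om = om$SSB, R_om = om$R, F_om = om$F)
  em_path <- file.path(iter_dir, "em_ts.csv")
  if (file.exists(em_path)) {
    em <- readr::read_csv(em_path, show_col_types = FALSE, progress = FALSE)
    i <- match(out$year, em$year)
    out$SSB_em <- em$SSB[i]
    out$R_em <- em$R[i]
    out$F_em <- em$F[i]
  } else {
    out$SSB_em <- out$R_em <- out$F_em <- NA_real_
  }
  out
}

#' Harvest results for one scenario folder
#'
#' Reads every iteration folder produced by [run_simulation()] /
#' [base_run()] under one scenario and returns one scalar row and one
#' time-series block per iteration, with paired `_om` / `_em` columns plus
#' `_re` relative errors and the convergence diagnostics. Iterations whose
#' estimation output is missing (failed fits) keep their row with EM
#' columns NA and `converged = FALSE`.
#'
#' @param scenario_folder Path to a `<scenario>` directory.
#' @return List with tibbles `scalars` and `ts`.
#' @export
get_results_scenario <- function(scenario_folder) {
  if (!dir.exists(scenario_folder)) {
    stop("scenario folder not found: ", scenario_folder, call. = FALSE)
  }
  scenario <- basename(normalizePath(scenario_folder, mustWork = FALSE))
  subdirs <- list.dirs(scenario_folder, recursive = FALSE)
  iters <- suppressWarnings(as.integer(basename(subdirs)))
  keep <- !is.na(iters) &
    file.exists(file.path(subdirs, "om_scalars.txt"))
  if (!any(keep)) {
    stop("no iteration folders (with om_scalars.txt) under ",
         scenario_folder, "; expected the <scenario>/<iteration>/ layout",
         call. = FALSE)
  }
  subdirs <- subdirs[keep][order(iters[keep])]
  iters <- sort(iters[keep])
  scalars <- purrr::map2(subdirs, iters, read_iteration_scalars,
                         scenario = scenario) |> dplyr::bind_rows()
  ts <- purrr::map2(subdirs, iters, read_iteration_ts,
                    scenario = scenario) |> dplyr::bind_rows()
  list(scalars = add_relative_error(scalars), ts = add_relative_error(ts))
}

#' Harvest all scenarios into the two long-format result files
#'
#' Concatenates [get_results_scenario()] over every scenario folder under
#' `root` (stable ordering: scenario, iteration, year) and writes
#' `ss3sim_scalars.csv` and `ss3sim_ts.csv` at `root`.
#'
#' @param root Directory containing scenario folders.
#' @return Invisibly, a list with the `scalars` and `ts` tibbles.
#' @export
get_results_all <- function(root = ".") {
  dirs <- list.dirs(root, recursive = FALSE)
  is_scenario <- vapply(dirs, function(d) {
    subs <- list.dirs(d, recursive = FALSE)
    any(!is.na(suppressWarnings(as.integer(basename(subs)))) &
          file.exists(file.path(subs, "om_scalars.txt")))
  }, logical(1))
  dirs <- dirs[is_scenario]
  if (length(dirs) == 0) {
    stop("no scenario folders found under ", root, call. = FALSE)
  }
  res <- lapply(sort(dirs), get_results_scenario)
  scalars <- dplyr::arrange(
    dplyr::bind_rows(lapply(res, `[[`, "scalars")),
    .data$scenario, .data$iteration)
  ts <- dplyr::arrange(dplyr::bind_rows(lapply(res, `[[`, "ts")),
                       .data$scenario, .data$iteration, .data$year)
  readr::write_csv(scalars, file.path(root, "ss3sim_scalars.csv"),
                   progress = FALSE)
  readr::write_csv(ts, file.path(root, "ss3sim_ts.csv"), progress = FALSE)
  invisible(list(scalars = scalars, ts = ts))
}
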
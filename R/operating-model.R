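#' Unfished (virgin) equilibrium of a life history
#'
#' Per-recruit survivorship at zero fishing: `N0_a = R0 * exp(-M * a)` for
#' ages below the plus group and `N0_A = R0 * exp(-M * A) / (1 - exp(-M))`
#' for the plus group `A`. Unfished spawning biomass is
#' `SSB0 = sum_a N0_a * w_a * mat_a`, with weight from the length-weight
#' curve at mean length-at-age and age-0 fish immature.
#'
#' When `M` has been made time-varying, the base (first-year) value is used:
#' the virgin state describes the population before any perturbation.
#'
#' @param lh A `life_history`.
#' @return A list with `N0` (numbers-at-age, named by age) and `SSB0` (kg).
#' @export
unfished_equilibrium <- function(lh) {
  M <- lh$M[1]
  if (!is.finite(M) || M <= 0) {
    stop("degenerate equilibrium: M must be > 0 for a plus-group model",
         call. = FALSE)
  }
  ages <- lh$ages
  A <- max(ages)
  N0 <- lh$R0 * exp(-M * ages)
  N0[ages == A] <- lh$R0 * exp(-M * A) / (1 - exp(-M))
  names(N0) <- ages
  L <- mean_length_at_age(ages, lh$Linf[1], lh$k[1], lh$t0)
  w <- weight_at_length(L, lh$w_alpha, lh$w_beta)
  SSB0 <- sum(N0 * w * maturity_at_age(lh))
  list(N0 = N0, SSB0 = SSB0)
}

#' Beverton-Holt expected recruitment
#'
#' Steepness parameterization:
#' `R = 4 h R0 S / (SSB0 (1 - h) + S (5 h - 1))`, so that `R = R0` at
#' `S = SSB0` and `R = h R0` at `S = 0.2 SSB0` (the definition of steepness).
#'
#' @param ssb Spawning stock biomass (kg), `>= 0`; vectorized.
#' @param lh A `life_history` supplying `h` and `R0`.
#' @param ssb0 Unfished spawning biomass; computed from `lh` if omitted.
#' @return Expected recruits (numbers).
#' @export
beverton_holt <- function(ssb, lh, ssb0 = NULL) {
  stopifnot(all(ssb >= 0))
  if (is.null(ssb0)) ssb0 <- unfished_equilibrium(lh)$SSB0
  4 * lh$h * lh$R0 * ssb / (ssb0 * (1 - lh$h) + ssb * (5 * lh$h - 1))
}

#' Baranov catch-at-age
#'
#' Catch as the fishing fraction of total deaths under continuous competing
#' mortality: `Z_a = M + sel_a F`, `C_a = (sel_a F / Z_a) N_a (1 - e^{-Z_a})`,
#' with `C_a = 0` where `Z_a = 0`.
#'
#' @param N_a Numbers-at-age at the start of the year.
#' @param M_y Natural mortality this year (scalar or per-age).
#' @param F_y Fully selected fishing mortality this year (scalar).
#' @param sel_a Selectivity-at-age in `[0, 1]`.
#' @return Catch-at-age in numbers.
#' @export
baranov_catch <- function(N_a, M_y, F_y, sel_a) {
  stopifnot(all(N_a >= 0), all(M_y >= 0), F_y >= 0, all(sel_a >= 0))
  Fa <- sel_a * F_y
  Z <- M_y + Fa
  C <- ifelse(Z > 0, Fa / Z * N_a * (1 - exp(-Z)), 0)
  unname(C)
}

# Valid targets for time-varying injection. Bare selectivity/catchability
# names apply to every fleet; the `_f<id>` forms target one fleet.
tv_targets <- function(lh) {
  ids <- vapply(lh$fleets, function(f) f$fleet_id, integer(1))
  c("M", "k", "Linf", "cv_length",
    "sel_a50", "sel_slope", "q",
    paste0(rep(c("sel_a50_f", "sel_slope_f", "q_f"), each = length(ids)), ids))
}

#' Inject time-varying parameters into a life history
#'
#' Each entry of `tv` maps a parameter name to additive per-year deviations;
#' the targeted scalar becomes a per-year vector `base + deviation`
#' (deviation 0 in unspecified years). The input object is not modified.
#'
#' Valid targets: `M`, `k`, `Linf`, `cv_length`, `sel_a50`, `sel_slope`, `q`
#' (the last three applied to every fleet carrying that parameter), and
#' fleet-specific forms like `sel_a50_f1`.
#'
#' @param lh A `life_history`.
#' @param tv Named list: parameter name -> deviations. Each element is either
#'   a full-length vector (one value per model year) or a named vector whose
#'   names are years.
#' @return A new `life_history` with per-year vectors for targeted
#'   parameters.
#' @examples
#' cod <- get_builtin("cod")$om
#' bump <- apply_tv(cod, list(M = c("1990" = 0.1)))
#' range(bump$M)
#' @export
apply_tv <- function(lh, tv) {
  if (length(tv) == 0) return(lh)
  valid <- tv_targets(lh)
  nyears <- length(lh$years)
  expand <- function(dev, what) {
    if (is.null(names(dev))) {
      if (length(dev) == 1) dev <- rep(dev, nyears)
      if (length(dev) != nyears) {
        stop("time-varying deviations for '", what, "' must have length 1, ",
             nyears, ", or be named by year", call. = FALSE)
      }
      return(as.numeric(dev))
    }
    yrs <- as.integer(names(dev))
    if (!all(yrs %in% lh$years)) {
      stop("time-varying deviations for '", what, "' name years outside ",
           min(lh$years), "-", max(lh$years), ": ",
           paste(setdiff(yrs, lh$years), collapse = ", "), call. = FALSE)
    }
    full <- rep(0, nyears)
    full[match(yrs, lh$years)] <- as.numeric(dev)
    full
  }
  out <- lh
  for (param in names(tv)) {
    if (!(param %in% valid)) {
      stop("unknown time-varying target '", param, "'; valid targets: ",
           paste(valid, collapse = ", "), call. = FALSE)
    }
    dev <- expand(tv[[param]], param)
    if (param %in% c("M", "k", "Linf", "cv_length")) {
      base <- out[[param]]
      if (length(base) == 1) base <- rep(base, nyears)
      out[[param]] <- base + dev
    } else {
      m <- regmatches(param, regexec("^(sel_a50|sel_slope|q)(_f(\\d+))?$",
                                     param))[[1]]
      field <- m[2]
      target_ids <- if (nzchar(m[4])) as.integer(m[4]) else
        vapply(out$fleets, function(f) f$fleet_id, integer(1))
      for (i in seq_along(out$fleets)) {
        fl <- out$fleets[[i]]
        if (!(fl$fleet_id %in% target_ids)) next
        if (field == "q" && fl$kind != "survey") next
        base <- fl[[field]]
        if (length(base) == 1) base <- rep(base, nyears)
        out$fleets[[i]][[field]] <- base + dev
      }
    }
  }
  validate_life_history(out)
  out
}

# Per-year matrix of a possibly time-varying scalar field.
per_year <- function(x, nyears) {
  if (length(x) == 1) rep(x, nyears) else x
}

#' Project the operating-model truth
#'
#' Age-structured projection generating the true population dynamics:
#' initialized at unfished equilibrium; each year, spawning biomass is
#' computed at the start of the year, recruitment follows Beverton-Holt with
#' a lognormal deviation and the `-sigma_R^2 / 2` mean-bias correction
#' (`R_y = BH(SSB_y) exp(dev_y - sigma_R^2/2)`, so recruitment is
#' mean-unbiased around the curve), total mortality is
#' `Z = M_y + sum_fleets sel F`, survivors move up an age with plus-group
#' accumulation, and catch-at-age follows the Baranov equation. Expected
#' (noise-free) survey indices, age compositions and length compositions are
#' stored for the sampling functions.
#'
#' @param lh A `life_history` (after [apply_tv()] if time-varying).
#' @param f Fishing mortality: a numeric vector over the model years (single
#'   fishery fleet), or a named list of such vectors keyed by fleet id.
#' @param devs Log-scale recruitment deviations: numeric vector over the
#'   model years (see [make_rec_devs()]).
#' @return A `population_truth` object; see Details.
#' @details The returned object contains: `N` (ages x years), `SSB`, `R`,
#'   `depletion`, `SSB0`, `Z` (ages x years), per-fishery-fleet `F`, `C`
#'   (catch-at-age) and `catch_biomass`; per-survey-fleet `true_index`
#'   (biomass scale, `q * sum_a sel_a N_a e^{-timing Z_a} w_a`); and
#'   per-fleet `expected_agecomp` / `expected_lencomp` proportion matrices
#'   (survey compositions from selected numbers at survey timing, fishery
#'   compositions from whole-year catch-at-age, lengths through the
#'   age-length transition matrix).
#' @export
project <- function(lh, f, devs) {
  years <- lh$years
  ages <- lh$ages
  ny <- length(years)
  na <- length(ages)
  A_idx <- na

  ffleets <- fishery_fleets(lh)
  sfleets <- survey_fleets(lh)
  if (length(ffleets) == 0) stop("life history has no fishery fleet",
                                 call. = FALSE)

  # --- normalize and check F coverage -----------------------------------
  if (is.numeric(f) && is.null(names(f)) && length(ffleets) == 1 &&
      length(f) == ny) {
    f <- stats::setNames(list(f), as.character(ffleets[[1]]$fleet_id))
  } else if (is.numeric(f)) {
    f <- stats::setNames(list(check_year_cover(f, years, "F series")),
                         as.character(ffleets[[1]]$fleet_id))
  } else {
    f <- lapply(f, check_year_cover, years = years, what = "F series")
  }
  for (fl in ffleets) {
    id <- as.character(fl$fleet_id)
    if (is.null(f[[id]])) stop("F series missing for fishery fleet ", id,
                               call. = FALSE)
    if (any(f[[id]] < 0)) stop("F must be >= 0", call. = FALSE)
  }
  devs <- check_year_cover(devs, years, "recruitment deviations")
  if (any(!is.finite(devs))) stop("recruitment deviations must be finite",
                                  call. = FALSE)

  # --- per-year biology --------------------------------------------------
  M_y <- per_year(lh$M, ny)
  k_y <- per_year(lh$k, ny)
  Linf_y <- per_year(lh$Linf, ny)
  cvl_y <- per_year(lh$cv_length, ny)
  growth_tv <- length(unique(k_y)) > 1 || length(unique(Linf_y)) > 1 ||
    length(unique(cvl_y)) > 1
  L_ay <- vapply(seq_len(ny), function(y)
    mean_length_at_age(ages, Linf_y[y], k_y[y], lh$t0), numeric(na))
  W_ay <- weight_at_length(L_ay, lh$w_alpha, lh$w_beta)
  mat_a <- maturity_at_age(lh)
  alk1 <- age_length_transition(lh, Linf = Linf_y[1], k = k_y[1],
                                cv_length = cvl_y[1])
  alk_y <- if (growth_tv) {
    lapply(seq_len(ny), function(y)
      age_length_transition(lh, Linf = Linf_y[y], k = k_y[y],
                            cv_length = cvl_y[y]))
  } else NULL
  sel <- lapply(lh$fleets, function(fl) {
    a50 <- per_year(fl$sel_a50, ny)
    slope <- per_year(fl$sel_slope, ny)
    vapply(seq_len(ny), function(y) logistic_age(ages, a50[y], slope[y]),
           numeric(na))
  })
  names(sel) <- vapply(lh$fleets, function(fl) as.character(fl$fleet_id),
                       character(1))

  eq <- unfished_equilibrium(lh)
  SSB0 <- eq$SSB0

  # --- annual recursion --------------------------------------------------
  N <- matrix(0, na, ny, dimnames = list(age = ages, year = years))
  Z <- matrix(0, na, ny, dimnames = dimnames(N))
  SSB <- R <- numeric(ny)
  C <- lapply(ffleets, function(fl) matrix(0, na, ny, dimnames = dimnames(N)))
  names(C) <- vapply(ffleets, function(fl) as.character(fl$fleet_id),
                     character(1))
  N[, 1] <- eq$N0
  for (y in seq_len(ny)) {
    SSB[y] <- sum(N[, y] * W_ay[, y] * mat_a)
    R[y] <- beverton_holt(SSB[y], lh, ssb0 = SSB0) *
      exp(devs[y] - lh$sigma_R^2 / 2)
    N[1, y] <- R[y]
    Ztot <- M_y[y]
    for (fl in ffleets) {
      id <- as.character(fl$fleet_id)
      Ztot <- Ztot + sel[[id]][, y] * f[[id]][y]
    }
    Z[, y] <- Ztot
    for (fl in ffleets) {
      id <- as.character(fl$fleet_id)
      Fa <- sel[[id]][, y] * f[[id]][y]
      C[[id]][, y] <- ifelse(Z[, y] > 0,
                             Fa / Z[, y] * N[, y] * (1 - exp(-Z[, y])), 0)
    }
    if (y < ny) {
      N[2:na, y + 1] <- N[1:(na - 1), y] * exp(-Z[1:(na - 1), y])
      N[A_idx, y + 1] <- N[A_idx, y + 1] + N[A_idx, y] * exp(-Z[A_idx, y])
    }
  }

  # --- expected observations --------------------------------------------
  true_index <- list()
  expected_agecomp <- list()
  expected_lencomp <- list()
  for (fl in lh$fleets) {
    id <- as.character(fl$fleet_id)
    if (fl$kind == "survey") {
      q_y <- per_year(fl$q, ny)
      avail <- sel[[id]] * N * exp(-fl$timing * Z)    # numbers at timing
      true_index[[id]] <- stats::setNames(
        q_y * colSums(avail * W_ay), years)
      comp_n <- avail
    } else {
      comp_n <- C[[id]]
    }
    expected_agecomp[[id]] <- sweep(comp_n, 2, colSums(comp_n), "/")
    len_n <- if (growth_tv) {
      vapply(seq_len(ny), function(y) alk_y[[y]] %*% comp_n[, y],
             numeric(nrow(alk1)))
    } else {
      alk1 %*% comp_n
    }
    dimnames(len_n) <- list(bin = rownames(alk1), year = years)
    expected_lencomp[[id]] <- sweep(len_n, 2, colSums(len_n), "/")
  }
  catch_biomass <- lapply(C, function(Cm) stats::setNames(
    colSums(Cm * W_ay), years))

  structure(list(
    lh = lh, years = years, ages = ages,
    N = N, SSB = stats::setNames(SSB, years), R = stats::setNames(R, years),
    Z = Z, F = lapply(f, function(v) stats::setNames(v, years)),
    C = C, catch_biomass = catch_biomass,
    true_index = true_index,
    expected_agecomp = expected_agecomp,
    expected_lencomp = expected_lencomp,
    SSB0 = SSB0, depletion = stats::setNames(SSB / SSB0, years),
    weight_at_age = W_ay, maturity = mat_a, selectivity = sel,
    M_y = M_y, devs = stats::setNames(devs, years)),
    class = "population_truth")
}

# Accept a plain vector over all years or a year-named vector; return the
# full-length vector, erroring with the missing years named.
check_year_cover <- function(x, years, what) {
  if (is.null(names(x))) {
    if (length(x) != length(years)) {
      stop(what, " must cover all ", length(years), " projection years (",
           min(years), "-", max(years), "); got length ", length(x),
           call. = FALSE)
    }
    return(as.numeric(x))
  }
  got <- as.integer(names(x))
  missing <- setdiff(years, got)
  if (length(missing) > 0) {
    stop(what, " missing years: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x[as.character(years)])
}

#' @export
print.population_truth <- function(x, ...) {
  cat("<population_truth> ", x$lh$name, ", years ", min(x$years), "-",
      max(x$years), ", ages 0:", max(x$ages), "\n",
      "  SSB0 = ", format(x$SSB0, digits = 4), " kg, terminal depletion = ",
      round(x$depletion[length(x$depletion)], 3), "\n", sep = "")
  invisible(x)
}

#' Tabulate an operating-model truth by age and year
#'
#' One row per age-year with numbers-at-age, total mortality, and
#' catch-at-age per fishery fleet (columns `C_<fleet>`); this is the table
#' written as `om_truth.csv` inside each iteration folder.
#'
#' @param truth A `population_truth`.
#' @return A tibble.
#' @export
om_truth_table <- function(truth) {
  grid <- tidyr::expand_grid(year = truth$years, age = truth$ages)
  out <- dplyr::mutate(grid,
    N = as.numeric(truth$N[cbind(match(.data$age, truth$ages),
                                 match(.data$year, truth$years))]),
    Z = as.numeric(truth$Z[cbind(match(.data$age, truth$ages),
                                 match(.data$year, truth$years))]))
  for (id in names(truth$C)) {
    out[[paste0("C_", id)]] <- as.numeric(
      truth$C[[id]][cbind(match(out$age, truth$ages),
                          match(out$year, truth$years))])
  }
  out
}

#' Per-year operating-model time series
#'
#' @param truth A `population_truth`.
#' @return A tibble with columns `year`, `SSB`, `R`, `F` (summed over
#'   fishery fleets), `depletion`.
#' @export
om_ts_table <- function(truth) {
  Ftot <- Reduce(`+`, truth$F)
  tibble::tibble(year = truth$years,
                 SSB = as.numeric(truth$SSB),
                 R = as.numeric(truth$R),
                 F = as.numeric(Ftot),
                 depletion = as.numeric(truth$depletion))
}
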
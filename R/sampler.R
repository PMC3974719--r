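# Run expr with a private RNG stream: seeds deterministically, restores the
# caller's RNG state afterwards so samplers are pure given (truth, spec, seed).
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify index observations
#'
#' @param fleets Fleet ids to observe (survey fleets).
#' @param years List of observation-year vectors, one per fleet (a single
#'   vector is recycled to all fleets).
#' @param sds_obs Log-scale observation SD per fleet (scalar recycled).
#' @return An `index_spec`.
#' @export
index_spec <- function(fleets, years, sds_obs) {
  fleets <- as.integer(unlist(fleets))
  if (!is.list(years)) years <- list(years)
  if (length(years) == 1) years <- rep(years, length(fleets))
  sds_obs <- as.numeric(unlist(sds_obs))
  if (length(sds_obs) == 1) sds_obs <- rep(sds_obs, length(fleets))
  if (length(years) != length(fleets) || length(sds_obs) != length(fleets)) {
    stop("index_spec: years and sds_obs must have one entry per fleet",
         call. = FALSE)
  }
  if (any(sds_obs < 0)) stop("sds_obs must be >= 0", call. = FALSE)
  structure(list(fleets = fleets, years = years, sds_obs = sds_obs),
            class = "index_spec")
}

#' Specify composition sampling
#'
#' @param fleets Fleet ids to sample.
#' @param years List of observation-year vectors, one per fleet (a single
#'   vector is recycled).
#' @param Nsamp Multinomial effective sample size per fleet (scalar
#'   recycled); positive integers.
#' @return A `comp_spec`.
#' @export
comp_spec <- function(fleets, years, Nsamp) {
  fleets <- as.integer(unlist(fleets))
  if (!is.list(years)) years <- list(years)
  if (length(years) == 1) years <- rep(years, length(fleets))
  Nsamp <- as.numeric(unlist(Nsamp))
  if (length(Nsamp) == 1) Nsamp <- rep(Nsamp, length(fleets))
  if (any(Nsamp < 1) || any(Nsamp != round(Nsamp))) {
    stop("Nsamp must be positive integers", call. = FALSE)
  }
  if (length(years) != length(fleets) || length(Nsamp) != length(fleets)) {
    stop("comp_spec: years and Nsamp must have one entry per fleet",
         call. = FALSE)
  }
  structure(list(fleets = fleets, years = years, Nsamp = Nsamp),
            class = "comp_spec")
}

check_obs_years <- function(truth, fleet, yrs, what) {
  bad <- setdiff(yrs, truth$years)
  if (length(bad) > 0) {
    stop("no ", what, " truth for fleet ", fleet, " in year(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Sample a noisy abundance index from the truth
#'
#' Each requested fleet-year draws `obs = true_index * exp(eps)` with
#' `eps ~ Normal(0, sds_obs^2)`: lognormal, median-unbiased noise (no
#' `-sigma^2/2` shift), matching the lognormal index likelihood of the
#' estimation model. The log-scale SD is recorded with each observation.
#'
#' @param truth A `population_truth`.
#' @param spec An [index_spec()].
#' @param seed Integer seed; calls are bit-reproducible given it.
#' @return A tibble with columns `fleet`, `year`, `value`, `se_log`.
#' @export
sample_index <- function(truth, spec, seed) {
  stopifnot(inherits(spec, "index_spec"))
  with_rng_seed(seed, {
    rows <- lapply(seq_along(spec$fleets), function(i) {
      fl <- spec$fleets[[i]]
      yrs <- spec$years[[i]]
      check_obs_years(truth, fl, yrs, "index")
      ti <- truth$true_index[[as.character(fl)]]
      if (is.null(ti)) {
        stop("fleet ", fl, " has no expected survey index ",
             "(only survey fleets are indexed)", call. = FALSE)
      }
      eps <- stats::rnorm(length(yrs), 0, spec$sds_obs[[i]])
      tibble::tibble(fleet = fl, year = as.integer(yrs),
                     value = as.numeric(ti[as.character(yrs)]) * exp(eps),
                     se_log = spec$sds_obs[[i]])
    })
    dplyr::bind_rows(rows)
  })
}

sample_comp <- function(truth, spec, seed, expected, what) {
  with_rng_seed(seed, {
    rows <- lapply(seq_along(spec$fleets), function(i) {
      fl <- spec$fleets[[i]]
      yrs <- spec$years[[i]]
      check_obs_years(truth, fl, yrs, what)
      E <- expected[[as.character(fl)]]
      if (is.null(E)) stop("no expected ", what, " for fleet ", fl,
                           call. = FALSE)
      bins <- rownames(E)
      dplyr::bind_rows(lapply(yrs, function(yr) {
        p <- E[, as.character(yr)]
        counts <- as.numeric(stats::rmultinom(1, spec$Nsamp[[i]], p)[, 1])
        tibble::tibble(fleet = fl, year = as.integer(yr),
                       Nsamp = spec$Nsamp[[i]], bin = as.numeric(bins),
                       prop = counts / spec$Nsamp[[i]])
      }))
    })
    dplyr::bind_rows(rows)
  })
}

#' Sample multinomial age compositions
#'
#' Counts are drawn as `Multinomial(Nsamp, expected_agecomp[fleet, year])`
#' and returned as exact proportions `counts / Nsamp` alongside `Nsamp`
#' (both are needed by the multinomial likelihood). Survey compositions come
#' from selected numbers at survey timing; fishery compositions from
#' whole-year catch-at-age.
#'
#' @inheritParams sample_index
#' @param spec A [comp_spec()] over age bins.
#' @return A tibble with columns `fleet`, `year`, `Nsamp`, `bin` (age),
#'   `prop`; each fleet-year's proportions sum to 1.
#' @export
sample_agecomp <- function(truth, spec, seed) {
  stopifnot(inherits(spec, "comp_spec"))
  sample_comp(truth, spec, seed, truth$expected_agecomp, "age composition")
}

#' Sample multinomial length compositions
#'
#' As [sample_agecomp()], over length bins: the expected composition is the
#' age composition pushed through the age-length transition matrix. `bin`
#' is the lower edge of each length bin (`-Inf` for the open first bin).
#'
#' @inheritParams sample_agecomp
#' @return A tibble with columns `fleet`, `year`, `Nsamp`, `bin`, `prop`.
#' @export
sample_lcomp <- function(truth, spec, seed) {
  stopifnot(inherits(spec, "comp_spec"))
  sample_comp(truth, spec, seed, truth$expected_lencomp, "length composition")
}

#' Generate or pass through recruitment deviations
#'
#' Exactly one of `seed` (generate `dev_y ~ iid Normal(0, sigma_R^2)`) or
#' `user_vector` (used verbatim, e.g. autocorrelated deviations built by the
#' user) must be supplied.
#'
#' @param sigma_R SD of log recruitment deviations.
#' @param years Recruitment years.
#' @param seed Integer seed for generated deviations.
#' @param user_vector Optional explicit deviation vector, one per year.
#' @return A named numeric vector (names = years) with attribute `sigma_R`.
#' @export
make_rec_devs <- function(sigma_R, years, seed = NULL, user_vector = NULL) {
  if (is.null(seed) == is.null(user_vector)) {
    stop("supply exactly one of seed or user_vector", call. = FALSE)
  }
  if (!is.null(user_vector)) {
    if (length(user_vector) != length(years)) {
      stop("user_vector has length ", length(user_vector), " but ",
           length(years), " years were requested", call. = FALSE)
    }
    devs <- as.numeric(user_vector)
  } else {
    devs <- with_rng_seed(seed, stats::rnorm(length(years), 0, sigma_R))
  }
  structure(stats::setNames(devs, years), sigma_R = sigma_R)
}

#' Build a fishing-mortality series from case arguments
#'
#' Two patterns are supported: `"vector"` (key `f`: an explicit per-year
#' vector) and `"ramp_constant"` (keys `f_max`, `ramp_years`: F increases
#' linearly from 0 to `f_max` over the first `ramp_years` years — so year
#' `j` of the ramp has `F = f_max * j / ramp_years` — then stays at
#' `f_max`).
#'
#' @param case_args Named list with at least `pattern`.
#' @param years Projection years to cover.
#' @return A named numeric vector of F (1/yr), one per year.
#' @export
build_f_series <- function(case_args, years) {
  pattern <- case_args$pattern
  if (is.null(pattern)) stop("F case must name a 'pattern'", call. = FALSE)
  ny <- length(years)
  f <- switch(pattern,
    vector = {
      v <- as.numeric(unlist(case_args$f))
      if (length(v) != ny) {
        stop("F vector has length ", length(v), " but ", ny,
             " years are required", call. = FALSE)
      }
      v
    },
    ramp_constant = {
      f_max <- case_args$f_max
      ramp <- case_args$ramp_years
      if (is.null(f_max) || is.null(ramp)) {
        stop("ramp_constant pattern needs f_max and ramp_years",
             call. = FALSE)
      }
      c(f_max * seq_len(min(ramp, ny)) / ramp,
        rep(f_max, max(0, ny - ramp)))
    },
    stop("unknown F pattern '", pattern,
         "'; valid patterns: vector, ramp_constant", call. = FALSE)
  )
  if (any(f < 0)) stop("F must be >= 0", call. = FALSE)
  stats::setNames(f, years)
}

#' Bundle sampled observations into a dataset for the estimation model
#'
#' @param index Tibble from [sample_index()].
#' @param agecomp Tibble from [sample_agecomp()] (or NULL).
#' @param lencomp Tibble from [sample_lcomp()] (or NULL).
#' @param catch Tibble with `fleet`, `year`, `value` — whole-year fishery
#'   catch in biomass (kg), passed to the estimation model as observed
#'   without error.
#' @return An `observed_dataset`.
#' @export
observed_dataset <- function(index, agecomp = NULL, lencomp = NULL, catch) {
  if (any(index$value <= 0)) stop("index values must be > 0", call. = FALSE)
  for (comp in list(agecomp, lencomp)) {
    if (is.null(comp) || nrow(comp) == 0) next
    sums <- dplyr::summarise(
      dplyr::group_by(comp, .data$fleet, .data$year),
      s = sum(.data$prop), .groups = "drop")
    if (any(abs(sums$s - 1) > 1e-10)) {
      stop("composition proportions must sum to 1 per fleet-year",
           call. = FALSE)
    }
  }
  empty_comp <- tibble::tibble(fleet = integer(), year = integer(),
                               Nsamp = numeric(), bin = numeric(),
                               prop = numeric())
  structure(list(index = index,
                 agecomp = if (is.null(agecomp)) empty_comp else agecomp,
                 lencomp = if (is.null(lencomp)) empty_comp else lencomp,
                 catch = catch),
            class = "observed_dataset")
}

#' Extract the error-free catch series from a truth
#'
#' @param truth A `population_truth`.
#' @return Tibble with `fleet`, `year`, `value` (catch biomass, kg).
#' @export
catch_series <- function(truth) {
  purrr::imap(truth$catch_biomass, function(cb, id) {
    tibble::tibble(fleet = as.integer(id), year = truth$years,
                   value = as.numeric(cb))
  }) |> dplyr::bind_rows()
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat("<observed_dataset>\n",
      "  index:   ", nrow(x$index), " obs\n",
      "  agecomp: ", nrow(x$agecomp), " rows (",
      dplyr::n_distinct(x$agecomp[c("fleet", "year")]), " fleet-years)\n",
      "  lencomp: ", nrow(x$lencomp), " rows (",
      dplyr::n_distinct(x$lencomp[c("fleet", "year")]), " fleet-years)\n",
      "  catch:   ", nrow(x$catch), " fleet-years\n", sep = "")
  invisible(x)
}
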
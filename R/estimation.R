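em_toggle_names <- c("M", "h", "R0", "q", "sel_fishery", "sel_survey",
                     "sigma_R")

#' Configure the estimation model
#'
#' Builds an estimation-model configuration from a structural life-history
#' template plus per-parameter toggles. Each toggle is `"estimated"`,
#' `"fixed"` (fix at the template value — for a matched self-test this is
#' the truth), or a number (fix at that value). Defaults: `R0`, `q` and
#' both selectivity blocks estimated; `M`, `h` and `sigma_R` fixed.
#' Recruitment deviations are always estimated (penalized by
#' `sigma_R`).
#'
#' @param lh The estimation-model `life_history` template.
#' @param toggles Named list over `M`, `h`, `R0`, `q`, `sel_fishery`,
#'   `sel_survey`, `sigma_R` overriding the defaults.
#' @param b_y Recruitment bias-adjustment factors in `[0, 1]`: scalar or one
#'   per model year. Default 1 (full lognormal correction); calibrate with
#'   [run_bias_adjust()].
#' @param grad_tol Convergence threshold on the maximum absolute gradient.
#' @return An `em_config`.
#' @export
em_config <- function(lh, toggles = list(), b_y = 1, grad_tol = 1e-3) {
  stopifnot(inherits(lh, "life_history"))
  tg <- list(M = "fixed", h = "fixed", R0 = "estimated", q = "estimated",
             sel_fishery = "estimated", sel_survey = "estimated",
             sigma_R = "fixed")
  for (nm in names(toggles)) {
    if (!(nm %in% em_toggle_names)) {
      stop("unknown estimation toggle '", nm, "'; valid: ",
           paste(em_toggle_names, collapse = ", "), call. = FALSE)
    }
    v <- toggles[[nm]]
    if (!(identical(v, "estimated") || identical(v, "fixed") ||
          (is.numeric(v) && length(v) == 1))) {
      stop("toggle '", nm, "' must be \"estimated\", \"fixed\", or a number",
           call. = FALSE)
    }
    tg[[nm]] <- v
  }
  ny <- length(lh$years)
  b_y <- if (length(b_y) == 1) rep(b_y, ny) else as.numeric(b_y)
  if (length(b_y) != ny || any(b_y < 0 | b_y > 1)) {
    stop("b_y must lie in [0, 1], one value per model year", call. = FALSE)
  }
  structure(list(lh = lh, toggles = tg, b_y = b_y, grad_tol = grad_tol),
            class = "em_config")
}

# Base (first-year) value of a possibly time-varying field.
base_val <- function(x) x[1]

# Template-side biology shared by the TMB data block and the MSY machinery.
em_biology <- function(lh) {
  ages <- lh$ages
  L <- mean_length_at_age(ages, base_val(lh$Linf), base_val(lh$k), lh$t0)
  list(ages = ages,
       w_a = weight_at_length(L, lh$w_alpha, lh$w_beta),
       mat_a = maturity_at_age(lh),
       alk = age_length_transition(lh, Linf = base_val(lh$Linf),
                                   k = base_val(lh$k),
                                   cv_length = base_val(lh$cv_length)))
}

# Per-recruit spawning biomass and yield at fishing mortality F.
per_recruit <- function(ages, M, F, sel, w, mat) {
  na <- length(ages)
  Z <- M + sel * F
  n <- numeric(na)
  n[1] <- 1
  for (a in seq_len(na - 1)) n[a + 1] <- n[a] * exp(-Z[a])
  n[na] <- n[na] / (1 - exp(-Z[na]))   # plus-group accumulation
  list(spr = sum(n * w * mat),
       ypr = sum(ifelse(Z > 0, sel * F / Z * n * (1 - exp(-Z)) * w, 0)))
}

# Deterministic starting values (reproducible by construction): R0 at twice
# a naive estimate from mean catch and yield-per-recruit at F = M,
# selectivity at the maturity parameters, M at 0.2, deviations at zero.
em_start_values <- function(cfg, data) {
  lh <- cfg$lh
  bio <- em_biology(lh)
  tg <- cfg$toggles
  fixed_at <- function(nm, template) {
    v <- tg[[nm]]
    if (identical(v, "fixed")) template else if (is.numeric(v)) v else template
  }
  M0 <- if (identical(tg$M, "estimated")) 0.2 else fixed_at("M", base_val(lh$M))
  h0 <- fixed_at("h", lh$h)
  sigR0 <- fixed_at("sigma_R", lh$sigma_R)
  sel_mat <- logistic_age(bio$ages, lh$mat_a50, lh$mat_slope)
  ypr_M <- per_recruit(bio$ages, M0, M0, sel_mat, bio$w_a, bio$mat_a)$ypr
  cbar <- mean(data$catch$value)
  R0_init <- if (identical(tg$R0, "estimated")) {
    max(2 * cbar / max(ypr_M, 1e-12), 1)
  } else fixed_at("R0", lh$R0)

  nf <- length(lh$fleets)
  sel_a50 <- log_sel_slope <- log_q <- numeric(nf)
  N0 <- R0_init * exp(-M0 * bio$ages)
  N0[length(N0)] <- N0[length(N0)] / (1 - exp(-M0))
  for (i in seq_len(nf)) {
    fl <- lh$fleets[[i]]
    est_sel <- identical(tg[[paste0("sel_", fl$kind)]], "estimated")
    if (est_sel) {
      sel_a50[i] <- lh$mat_a50
      log_sel_slope[i] <- log(lh$mat_slope)
    } else {
      sel_a50[i] <- base_val(fl$sel_a50)
      log_sel_slope[i] <- log(base_val(fl$sel_slope))
    }
    if (fl$kind == "survey") {
      obs <- data$index$value[data$index$fleet == fl$fleet_id]
      if (identical(tg$q, "estimated") && length(obs) > 0) {
        sel0 <- logistic_age(bio$ages, sel_a50[i], exp(log_sel_slope[i]))
        B0 <- sum(sel0 * N0 * bio$w_a)
        log_q[i] <- mean(log(obs)) - log(max(B0, 1e-12))
      } else if (is.numeric(tg$q)) {
        log_q[i] <- log(tg$q)
      } else if (identical(tg$q, "fixed")) {
        log_q[i] <- log(base_val(fl$q))
      }
    }
  }
  h_safe <- min(max(h0, 0.2 + 1e-8), 1 - 1e-8)
  list(log_R0 = log(R0_init), log_M = log(M0),
       trans_h = stats::qlogis((h_safe - 0.2) / 0.8),
       sel_a50 = sel_a50, log_sel_slope = log_sel_slope, log_q = log_q,
       log_sigma_R = log(sigR0),
       rec_devs = rep(0, length(lh$years)))
}

# Assemble the TMB data list, parameter starts, map (fixed parameters) and
# box bounds for one configuration + dataset.
build_tmb_inputs <- function(cfg, data, start = NULL) {
  lh <- cfg$lh
  bio <- em_biology(lh)
  years <- lh$years
  ny <- length(years)
  fleet_ids <- vapply(lh$fleets, function(f) f$fleet_id, integer(1))
  kinds <- vapply(lh$fleets, function(f) f$kind, character(1))
  fid0 <- function(fleet) {
    i <- match(fleet, fleet_ids)
    if (anyNA(i)) stop("observations reference unknown fleet(s): ",
                       paste(unique(fleet[is.na(i)]), collapse = ", "),
                       call. = FALSE)
    i - 1L
  }
  yid0 <- function(year) {
    i <- match(year, years)
    if (anyNA(i)) stop("observations reference years outside the model: ",
                       paste(unique(year[is.na(i)]), collapse = ", "),
                       call. = FALSE)
    i - 1L
  }

  fishery_pos <- which(kinds == "fishery")
  catch_obs <- matrix(0, length(fishery_pos), ny)
  for (j in seq_along(fishery_pos)) {
    id <- fleet_ids[fishery_pos[j]]
    rows <- data$catch[data$catch$fleet == id, ]
    if (!all(years %in% rows$year)) {
      stop("catch series for fishery fleet ", id,
           " must cover every model year", call. = FALSE)
    }
    catch_obs[j, ] <- rows$value[match(years, rows$year)]
  }

  comp_matrix <- function(comp, bins, what) {
    if (nrow(comp) == 0) {
      return(list(fleet = integer(0), year = integer(0), N = numeric(0),
                  prop = matrix(0, 0, length(bins))))
    }
    key <- dplyr::distinct(comp[c("fleet", "year", "Nsamp")])
    prop <- matrix(0, nrow(key), length(bins))
    for (r in seq_len(nrow(key))) {
      rows <- comp[comp$fleet == key$fleet[r] & comp$year == key$year[r], ]
      i <- match(rows$bin, bins)
      if (anyNA(i) || nrow(rows) != length(bins)) {
        stop(what, " bins must match the model's bins exactly",
             call. = FALSE)
      }
      prop[r, i] <- rows$prop
    }
    list(fleet = fid0(key$fleet), year = yid0(key$year),
         N = as.numeric(key$Nsamp), prop = prop)
  }
  ac <- comp_matrix(data$agecomp, bio$ages, "age-composition")
  lbins <- as.numeric(rownames(bio$alk))
  lc <- comp_matrix(data$lencomp, lbins, "length-composition")

  tmb_data <- list(
    ages = as.numeric(bio$ages), w_a = bio$w_a, mat_a = bio$mat_a,
    alk = unname(bio$alk), b_y = cfg$b_y,
    fleet_kind = as.integer(kinds == "survey"),
    fleet_timing = vapply(lh$fleets, function(f) f$timing, numeric(1)),
    catch_obs = catch_obs, fishery_idx = as.integer(fishery_pos - 1L),
    iobs_fleet = fid0(data$index$fleet), iobs_year = yid0(data$index$year),
    iobs_val = as.numeric(data$index$value),
    iobs_sd = as.numeric(data$index$se_log),
    ac_fleet = ac$fleet, ac_year = ac$year, ac_N = ac$N, ac_prop = ac$prop,
    lc_fleet = lc$fleet, lc_year = lc$year, lc_N = lc$N, lc_prop = lc$prop)

  par <- em_start_values(cfg, data)

  tg <- cfg$toggles
  map <- list()
  if (!identical(tg$M, "estimated")) map$log_M <- factor(NA)
  if (!identical(tg$h, "estimated")) map$trans_h <- factor(NA)
  if (!identical(tg$R0, "estimated")) map$log_R0 <- factor(NA)
  if (!identical(tg$sigma_R, "estimated")) map$log_sigma_R <- factor(NA)
  sel_est <- ifelse(kinds == "fishery",
                    identical(tg$sel_fishery, "estimated"),
                    identical(tg$sel_survey, "estimated"))
  if (!all(sel_est)) {
    idx <- ifelse(sel_est, seq_along(kinds), NA)
    map$sel_a50 <- factor(idx)
    map$log_sel_slope <- factor(idx)
  }
  q_est <- kinds == "survey" & identical(tg$q, "estimated")
  if (!all(q_est)) {
    map$log_q <- factor(ifelse(q_est, seq_along(kinds), NA))
  }

  # Warm-restart values: full-length vectors replace directly; vectors the
  # length of the free (unmapped) entries fill those positions.
  if (!is.null(start)) {
    for (nm in names(start)) {
      full <- par[[nm]]
      s <- as.numeric(start[[nm]])
      if (length(s) == length(full)) {
        par[[nm]] <- s
      } else {
        lv <- if (!is.null(map[[nm]])) as.integer(as.character(map[[nm]])) else
          rep(NA_integer_, length(full))
        if (sum(!is.na(lv)) == length(s)) {
          full[!is.na(lv)] <- s
          par[[nm]] <- full
        } else {
          stop("start value for '", nm, "' has length ", length(s),
               "; expected ", length(full), call. = FALSE)
        }
      }
    }
  }

  bound <- list(log_R0 = c(par$log_R0 - log(1e3), par$log_R0 + log(1e3)),
                log_M = log(c(0.01, 2)), trans_h = c(-10, 10),
                sel_a50 = c(0.1, max(bio$ages)),
                log_sel_slope = log(c(0.05, 10)), log_q = c(-15, 15),
                log_sigma_R = log(c(0.01, 2)), rec_devs = c(-10, 10))
  list(data = tmb_data, par = par, map = map, bounds = bound,
       years = years, fleet_ids = fleet_ids, kinds = kinds, bio = bio)
}

make_em_obj <- function(cfg, data, start = NULL, hessian = TRUE) {
  inp <- build_tmb_inputs(cfg, data, start = start)
  obj <- TMB::MakeADFun(data = inp$data, parameters = inp$par,
                        map = inp$map, DLL = "scaloop", silent = TRUE,
                        hessian = hessian)
  nm <- names(obj$par)
  lower <- vapply(nm, function(n) inp$bounds[[n]][1], numeric(1))
  upper <- vapply(nm, function(n) inp$bounds[[n]][2], numeric(1))
  list(obj = obj, lower = lower, upper = upper, inp = inp)
}

#' Lognormal index likelihood component
#'
#' `sum((log(obs) - log(pred))^2 / (2 se_log^2))`, the kernel of the
#' lognormal index likelihood (constants dropped).
#'
#' @param obs,pred Observed and predicted index values (> 0).
#' @param se_log Log-scale SD per observation.
#' @return Scalar negative log-likelihood contribution.
#' @export
nll_index_component <- function(obs, pred, se_log) {
  sum((log(obs) - log(pred))^2 / (2 * se_log^2))
}

#' Multinomial composition likelihood component
#'
#' `-Nsamp * sum(p_obs * log(max(p_pred, 1e-10)))` for one composition row
#' (constants dropped).
#'
#' @param p_obs,p_pred Observed and predicted proportion vectors.
#' @param Nsamp Effective sample size.
#' @return Scalar negative log-likelihood contribution.
#' @export
nll_multinomial_component <- function(p_obs, p_pred, Nsamp) {
  -Nsamp * sum(p_obs * log(pmax(p_pred, 1e-10)))
}

# Map natural-scale parameter values to the internal parameter list.
natural_to_internal <- function(params, cfg, defaults) {
  out <- defaults
  if (!is.null(params$R0)) out$log_R0 <- log(params$R0)
  if (!is.null(params$M)) out$log_M <- log(params$M)
  if (!is.null(params$h)) {
    h <- min(max(params$h, 0.2 + 1e-8), 1 - 1e-8)
    out$trans_h <- stats::qlogis((h - 0.2) / 0.8)
  }
  if (!is.null(params$sigma_R)) out$log_sigma_R <- log(params$sigma_R)
  if (!is.null(params$sel_a50)) out$sel_a50 <- params$sel_a50
  if (!is.null(params$sel_slope)) out$log_sel_slope <- log(params$sel_slope)
  if (!is.null(params$q)) {
    kinds <- vapply(cfg$lh$fleets, function(f) f$kind, character(1))
    q <- params$q
    if (length(q) == 1) q <- ifelse(kinds == "survey", q, 1)
    out$log_q <- log(q)
  }
  if (!is.null(params$rec_devs)) out$rec_devs <- as.numeric(params$rec_devs)
  out
}

#' Evaluate the estimation-model negative log-likelihood
#'
#' Evaluates the total objective (index + age composition + length
#' composition + recruitment-deviation penalty) at user-supplied
#' natural-scale parameter values, with the component breakdown attached.
#'
#' @param params Named list on natural scales; any of `R0`, `M`, `h`,
#'   `sigma_R`, `q` (scalar or per fleet), `sel_a50` / `sel_slope` (per
#'   fleet), `rec_devs` (per year). Unsupplied values fall back to the
#'   configuration's starting values.
#' @param data An `observed_dataset`.
#' @param cfg An `em_config`.
#' @return The scalar negative log-likelihood, with attribute `components`
#'   (named: `index`, `agecomp`, `lencomp`, `rec_devs`).
#' @export
nll <- function(params, data, cfg) {
  defaults <- em_start_values(cfg, data)
  par <- natural_to_internal(params, cfg, defaults)
  free <- em_config(cfg$lh,
                    toggles = list(M = "estimated", h = "estimated",
                                   R0 = "estimated", q = "estimated",
                                   sel_fishery = "estimated",
                                   sel_survey = "estimated",
                                   sigma_R = "estimated"),
                    b_y = cfg$b_y, grad_tol = cfg$grad_tol)
  inp <- build_tmb_inputs(free, data, start = par)
  obj <- TMB::MakeADFun(data = inp$data, parameters = inp$par, map = list(),
                        DLL = "scaloop", silent = TRUE)
  val <- as.numeric(obj$fn(obj$par))
  rep <- obj$report(obj$par)
  attr(val, "components") <- c(index = rep$nll_index, agecomp = rep$nll_ac,
                               lencomp = rep$nll_lc, rec_devs = rep$nll_devs)
  val
}

#' Estimation-model predictions at given parameter values
#'
#' Runs the estimation model's population recursion (with its per-year
#' catch-conditioned F solve) at user-supplied natural-scale parameters and
#' returns the predicted quantities without fitting.
#'
#' @inheritParams nll
#' @return List with `SSB`, `R`, `N`, `Z`, `F` (per fishery fleet x year),
#'   `SSB0`, `pred_index` (fleet x year matrix) and the likelihood
#'   components.
#' @export
em_predictions <- function(params, data, cfg) {
  defaults <- em_start_values(cfg, data)
  par <- natural_to_internal(params, cfg, defaults)
  free <- em_config(cfg$lh,
                    toggles = list(M = "estimated", h = "estimated",
                                   R0 = "estimated", q = "estimated",
                                   sel_fishery = "estimated",
                                   sel_survey = "estimated",
                                   sigma_R = "estimated"),
                    b_y = cfg$b_y, grad_tol = cfg$grad_tol)
  inp <- build_tmb_inputs(free, data, start = par)
  obj <- TMB::MakeADFun(data = inp$data, parameters = inp$par, map = list(),
                        DLL = "scaloop", silent = TRUE)
  obj$fn(obj$par)
  rep <- obj$report(obj$par)
  list(SSB = stats::setNames(as.numeric(rep$SSB), inp$years),
       R = stats::setNames(as.numeric(rep$R), inp$years),
       N = rep$N, Z = rep$Z, F = rep$Fm, SSB0 = rep$SSB0,
       pred_index = rep$pred_index,
       nll_components = c(index = rep$nll_index, agecomp = rep$nll_ac,
                          lencomp = rep$nll_lc, rec_devs = rep$nll_devs))
}

#' Fit the estimation model by maximum likelihood
#'
#' Quasi-Newton minimization (`nlminb` with exact AD gradients from the TMB
#' template, plus one continuation restart from the first optimum),
#' standard errors from the inverse Hessian at the optimum
#' (`TMB::sdreport`, exact second-order AD). The fit is declared converged
#' when the maximum absolute gradient is below the configuration threshold
#' and the Hessian is positive definite. Optimizer failure never raises an
#' error: it returns a `fit_result` with `converged = FALSE` and whatever
#' diagnostics are available.
#'
#' @param cfg An `em_config`.
#' @param data An `observed_dataset` structurally compatible with `cfg`.
#' @param start Optional named list of internal-scale starting values
#'   (e.g. from a previous fit) overriding the deterministic defaults.
#' @return A `fit_result`; see [tidy.fit_result()] and
#'   [glance.fit_result()].
#' @export
fit <- function(cfg, data, start = NULL) {
  stopifnot(inherits(cfg, "em_config"), inherits(data, "observed_dataset"))
  t0 <- proc.time()[["elapsed"]]
  built <- make_em_obj(cfg, data, start = start)
  obj <- built$obj
  years <- built$inp$years

  # Full Newton with the exact AD Hessian (few, cheap iterations); fall
  # back to gradient-only quasi-Newton, and polish whenever the gradient
  # has not reached the convergence threshold.
  opt <- tryCatch(
    stats::nlminb(obj$par, obj$fn, obj$gr, obj$he,
                  lower = built$lower, upper = built$upper,
                  control = list(iter.max = 500, eval.max = 1000)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    opt <- tryCatch(
      stats::nlminb(obj$par, obj$fn, obj$gr,
                    lower = built$lower, upper = built$upper,
                    control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL)
  }
  if (!is.null(opt) && is.finite(opt$objective)) {
    g <- tryCatch(max(abs(obj$gr(opt$par))), error = function(e) Inf)
    if (!is.finite(g) || g >= cfg$grad_tol) {
      opt2 <- tryCatch(
        stats::nlminb(opt$par, obj$fn, obj$gr,
                      lower = built$lower, upper = built$upper,
                      control = list(iter.max = 1000, eval.max = 2000,
                                     rel.tol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt2) && is.finite(opt2$objective) &&
          opt2$objective <= opt$objective) opt <- opt2
    }
  }

  if (is.null(opt) || !is.finite(opt$objective)) {
    return(failed_fit(cfg, years, t0,
                      message = "optimizer failed to produce a finite optimum"))
  }
  grad <- tryCatch(as.numeric(obj$gr(opt$par)), error = function(e) NA_real_)
  max_gradient <- if (all(is.finite(grad))) max(abs(grad)) else Inf
  on_bounds <- sum(pmin(abs(opt$par - built$lower),
                        abs(built$upper - opt$par)) < 1e-6)
  sdr <- tryCatch(TMB::sdreport(obj, getReportCovariance = FALSE),
                  error = function(e) NULL)
  rep <- obj$report(opt$par)

  pdhess <- !is.null(sdr) && isTRUE(sdr$pdHess)
  adnames <- if (!is.null(sdr)) names(sdr$value) else character(0)
  ad_est <- function(nm) if (nm %in% adnames) unname(sdr$value[adnames == nm]) else NA_real_
  ad_se <- function(nm) if (nm %in% adnames) unname(sdr$sd[adnames == nm]) else NA_real_

  tg <- cfg$toggles
  est_flag <- function(nm) identical(tg[[nm]], "estimated")
  fixed_value <- function(nm, template) {
    if (is.numeric(tg[[nm]])) tg[[nm]] else template
  }
  lh <- cfg$lh
  M_hat <- if (est_flag("M")) ad_est("M") else fixed_value("M", base_val(lh$M))
  h_hat <- if (est_flag("h")) ad_est("h") else fixed_value("h", lh$h)
  R0_hat <- if (est_flag("R0")) ad_est("R0") else fixed_value("R0", lh$R0)
  sigR_hat <- if (est_flag("sigma_R")) exp(opt$par[names(opt$par) == "log_sigma_R"][1]) else
    fixed_value("sigma_R", lh$sigma_R)

  par_se <- function(nm) {
    if (is.null(sdr)) return(rep(NA_real_, sum(names(opt$par) == nm)))
    i <- names(sdr$par.fixed) == nm
    if (!any(i)) return(numeric(0))
    sqrt(pmax(diag(as.matrix(sdr$cov.fixed))[i], 0))
  }
  pick <- function(nm) unname(opt$par[names(opt$par) == nm])

  estimates <- tibble::tibble(
    term = c("M", "h", "R0", "sigma_R"),
    estimate = c(M_hat, h_hat, R0_hat, sigR_hat),
    se = c(if (est_flag("M")) ad_se("M") else NA_real_,
           if (est_flag("h")) ad_se("h") else NA_real_,
           if (est_flag("R0")) ad_se("R0") else NA_real_,
           if (est_flag("sigma_R")) sigR_hat * par_se("log_sigma_R")[1] else NA_real_),
    estimated = c(est_flag("M"), est_flag("h"), est_flag("R0"),
                  est_flag("sigma_R")))
  kinds <- built$inp$kinds
  ids <- built$inp$fleet_ids
  sel_rows <- purrr::map(seq_along(ids), function(i) {
    est_sel <- if (kinds[i] == "fishery") est_flag("sel_fishery") else est_flag("sel_survey")
    a50_all <- pick_full(opt, built, "sel_a50")
    slope_all <- exp(pick_full(opt, built, "log_sel_slope"))
    a50_se <- se_full(sdr, built, "sel_a50")
    slope_se <- slope_all * se_full(sdr, built, "log_sel_slope")
    rows <- tibble::tibble(
      term = paste0(c("sel_a50_f", "sel_slope_f"), ids[i]),
      estimate = c(a50_all[i], slope_all[i]),
      se = if (est_sel) c(a50_se[i], slope_se[i]) else c(NA_real_, NA_real_),
      estimated = est_sel)
    if (kinds[i] == "survey") {
      q_all <- exp(pick_full(opt, built, "log_q"))
      q_se <- q_all * se_full(sdr, built, "log_q")
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        term = paste0("q_f", ids[i]), estimate = q_all[i],
        se = if (est_flag("q")) q_se[i] else NA_real_,
        estimated = est_flag("q")))
    }
    rows
  }) |> dplyr::bind_rows()
  estimates <- dplyr::bind_rows(estimates, sel_rows)

  dev_hat <- pick("rec_devs")
  dev_se <- par_se("rec_devs")
  if (length(dev_se) != length(dev_hat)) dev_se <- rep(NA_real_, length(dev_hat))
  rec_devs <- tibble::tibble(year = years, dev = dev_hat, se = dev_se)

  ssb <- tibble::tibble(year = years,
                        est = as.numeric(rep$SSB),
                        se = if ("SSB" %in% adnames) unname(sdr$sd[adnames == "SSB"]) else NA_real_)
  recruits <- tibble::tibble(year = years,
                             est = as.numeric(rep$R),
                             se = if ("R" %in% adnames) unname(sdr$sd[adnames == "R"]) else NA_real_)
  F_total <- colSums(matrix(rep$Fm, ncol = length(years)))

  sel_fishery_pos <- which(kinds == "fishery")[1]
  msy <- msy_reference_points(
    ages = built$inp$bio$ages, M = M_hat, h = h_hat, R0 = R0_hat,
    w = built$inp$bio$w_a, mat = built$inp$bio$mat_a,
    sel = logistic_age(built$inp$bio$ages,
                       pick_full(opt, built, "sel_a50")[sel_fishery_pos],
                       exp(pick_full(opt, built, "log_sel_slope")[sel_fishery_pos])))

  covariance_ok <- pdhess && all(is.finite(sdr$sd)) && all(sdr$sd >= 0)
  converged <- is.finite(max_gradient) && max_gradient < cfg$grad_tol && pdhess

  structure(list(
    estimates = estimates, rec_devs = rec_devs, ssb = ssb,
    recruits = recruits,
    F_series = tibble::tibble(year = years, est = as.numeric(F_total)),
    SSB0 = as.numeric(rep$SSB0),
    depletion = as.numeric(rep$SSB[length(years)] / rep$SSB0),
    depletion_se = ad_se("depletion"),
    F_terminal = as.numeric(F_total[length(years)]),
    F_terminal_se = ad_se("F_terminal"),
    SSB_MSY = msy$SSB_MSY, F_MSY = msy$F_MSY, MSY = msy$MSY,
    nll = as.numeric(opt$objective), max_gradient = max_gradient,
    covariance_ok = covariance_ok, n_params_on_bounds = as.integer(on_bounds),
    runtime = proc.time()[["elapsed"]] - t0, converged = converged,
    b_y = cfg$b_y, opt_par = opt$par, cfg = cfg,
    message = opt$message %||% ""),
    class = "fit_result")
}

# Parameter vector including mapped (fixed) entries, in fleet order.
pick_full <- function(opt, built, nm) {
  full <- built$inp$par[[nm]]
  est <- unname(opt$par[names(opt$par) == nm])
  map <- built$inp$map[[nm]]
  if (is.null(map)) {
    if (length(est) == length(full)) est else full
  } else {
    out <- full
    lv <- as.integer(as.character(map))
    out[!is.na(lv)] <- est
    out
  }
}
se_full <- function(sdr, built, nm) {
  full <- rep(NA_real_, length(built$inp$par[[nm]]))
  if (is.null(sdr)) return(full)
  i <- names(sdr$par.fixed) == nm
  if (!any(i)) return(full)
  ses <- sqrt(pmax(diag(as.matrix(sdr$cov.fixed))[i], 0))
  map <- built$inp$map[[nm]]
  if (is.null(map)) full[] <- ses else {
    lv <- as.integer(as.character(map))
    full[!is.na(lv)] <- ses
  }
  full
}

failed_fit <- function(cfg, years, t0, message) {
  structure(list(
    estimates = tibble::tibble(term = character(), estimate = numeric(),
                               se = numeric(), estimated = logical()),
    rec_devs = tibble::tibble(year = years, dev = NA_real_, se = NA_real_),
    ssb = tibble::tibble(year = years, est = NA_real_, se = NA_real_),
    recruits = tibble::tibble(year = years, est = NA_real_, se = NA_real_),
    F_series = tibble::tibble(year = years, est = NA_real_),
    SSB0 = NA_real_, depletion = NA_real_, depletion_se = NA_real_,
    F_terminal = NA_real_, F_terminal_se = NA_real_,
    SSB_MSY = NA_real_, F_MSY = NA_real_, MSY = NA_real_,
    nll = NA_real_, max_gradient = Inf, covariance_ok = FALSE,
    n_params_on_bounds = NA_integer_,
    runtime = proc.time()[["elapsed"]] - t0, converged = FALSE,
    b_y = cfg$b_y, opt_par = NULL, cfg = cfg, message = message),
    class = "fit_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", if (x$converged) "converged" else "NOT converged",
      " (max|grad| = ", format(x$max_gradient, digits = 3),
      ", nll = ", format(x$nll, digits = 6), ")\n", sep = "")
  est <- x$estimates[x$estimates$estimated, ]
  if (nrow(est) > 0) {
    cat("  estimated: ",
        paste(est$term, "=", signif(est$estimate, 4), collapse = ", "),
        "\n", sep = "")
  }
  cat("  depletion = ", round(x$depletion, 3), ", F_terminal = ",
      round(x$F_terminal, 3), ", SSB_MSY = ", format(x$SSB_MSY, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted estimation model
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, `se`,
#'   `estimated` (FALSE for parameters fixed by the configuration, whose
#'   `se` is NA and whose estimate equals the fixing value).
#' @export
tidy.fit_result <- function(x, ...) x$estimates

#' One-row summary of a fitted estimation model
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return A one-row tibble of derived quantities and convergence
#'   diagnostics.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(nll = x$nll, max_gradient = x$max_gradient,
                 converged = x$converged, covariance_ok = x$covariance_ok,
                 n_params_on_bounds = x$n_params_on_bounds,
                 SSB0 = x$SSB0, depletion = x$depletion,
                 F_terminal = x$F_terminal, SSB_MSY = x$SSB_MSY,
                 F_MSY = x$F_MSY, runtime = x$runtime)
}
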
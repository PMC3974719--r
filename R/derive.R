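#' Equilibrium MSY reference points
#'
#' For fully selected fishing mortality `F` on a grid, equilibrium
#' recruitment follows from the Beverton-Holt curve and spawning-per-recruit:
#' `R_eq(F) = (4 h R0 SPR(F) - SSB0 (1 - h)) / ((5 h - 1) SPR(F))` (floored
#' at 0), equilibrium yield is `Y(F) = YPR(F) * R_eq(F)`, and `F_MSY`
#' maximizes `Y`. The grid optimum is refined by golden-section search to a
#' tolerance of 1e-4 on `F`. With `h = 1`, `R_eq = R0` wherever `SPR > 0`.
#'
#' @param ages Model ages (plus group last).
#' @param M Natural mortality (1/yr).
#' @param h Beverton-Holt steepness.
#' @param R0 Unfished recruitment.
#' @param w,mat Weight- and maturity-at-age.
#' @param sel Fishery selectivity-at-age.
#' @param f_max Upper end of the F grid (1/yr).
#' @return List with `F_MSY`, `MSY`, `SSB_MSY`, `SSB0`, `SPR0`, and
#'   `yield_curve` (a tibble of F vs equilibrium yield). If the yield curve
#'   is zero everywhere (steepness at its lower limit), `F_MSY`, `MSY` and
#'   `SSB_MSY` are NA and the result carries `attr(, "flag") =
#'   "zero_yield_curve"`.
#' @export
msy_reference_points <- function(ages, M, h, R0, w, mat, sel, f_max = 4) {
  spr0 <- per_recruit(ages, M, 0, sel, w, mat)$spr
  ssb0 <- spr0 * R0
  r_eq <- function(F) {
    spr <- per_recruit(ages, M, F, sel, w, mat)$spr
    if (h >= 1 - 1e-12) return(if (spr > 0) R0 else 0)
    max(0, (4 * h * R0 * spr - ssb0 * (1 - h)) / ((5 * h - 1) * spr))
  }
  yield <- function(F) per_recruit(ages, M, F, sel, w, mat)$ypr * r_eq(F)
  grid <- seq(0, f_max, length.out = 81)
  y <- vapply(grid, yield, numeric(1))
  curve <- tibble::tibble(F = grid, yield = y)
  if (all(y <= 0)) {
    out <- list(F_MSY = NA_real_, MSY = NA_real_, SSB_MSY = NA_real_,
                SSB0 = ssb0, SPR0 = spr0, yield_curve = curve)
    attr(out, "flag") <- "zero_yield_curve"
    return(out)
  }
  i <- which.max(y)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  gr <- (sqrt(5) - 1) / 2          # golden-section refinement
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- yield(c1); fd <- yield(d1)
  while (b - a > 1e-4) {
    if (fc > fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- yield(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- yield(d1)
    }
  }
  f_msy <- (a + b) / 2
  spr_msy <- per_recruit(ages, M, f_msy, sel, w, mat)$spr
  list(F_MSY = f_msy, MSY = yield(f_msy), SSB_MSY = spr_msy * r_eq(f_msy),
       SSB0 = ssb0, SPR0 = spr0, yield_curve = curve)
}

#' Derived quantities from estimated parameters
#'
#' Computes the depletion (terminal SSB over unfished SSB), MSY reference
#' points and terminal fishing mortality implied by a parameter set under a
#' given estimation-model structure.
#'
#' @param params Either a `fit_result` or a named list with `M`, `h`, `R0`,
#'   fishery `sel_a50` / `sel_slope`, and optionally `SSB` (per-year series)
#'   and `F_terminal`.
#' @param cfg The `em_config` supplying the structural template (ages,
#'   weights, maturity).
#' @return List with `SSB` (series, if available), `SSB0`, `depletion`,
#'   `SSB_MSY`, `F_MSY`, `MSY`, `F_terminal`.
#' @export
derive_quantities <- function(params, cfg) {
  bio <- em_biology(cfg$lh)
  if (inherits(params, "fit_result")) {
    ft <- params
    est <- function(term) {
      ft$estimates$estimate[ft$estimates$term == term][1]
    }
    ff <- fishery_fleets(cfg$lh)[[1]]
    params <- list(M = est("M"), h = est("h"), R0 = est("R0"),
                   sel_a50 = est(paste0("sel_a50_f", ff$fleet_id)),
                   sel_slope = est(paste0("sel_slope_f", ff$fleet_id)),
                   SSB = stats::setNames(ft$ssb$est, ft$ssb$year),
                   F_terminal = ft$F_terminal)
  }
  sel <- logistic_age(bio$ages, params$sel_a50, params$sel_slope)
  msy <- msy_reference_points(bio$ages, params$M, params$h, params$R0,
                              bio$w_a, bio$mat_a, sel)
  ssb <- params$SSB
  depletion <- if (!is.null(ssb)) unname(ssb[length(ssb)] / msy$SSB0) else NA_real_
  list(SSB = ssb, SSB0 = msy$SSB0, depletion = depletion,
       SSB_MSY = msy$SSB_MSY, F_MSY = msy$F_MSY, MSY = msy$MSY,
       F_terminal = params$F_terminal %||% NA_real_)
}
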
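#' Retrospective analysis
#'
#' For each peel `p = 0, ..., n_peel` the model is truncated at terminal
#' year `T - p`: every observation (index, compositions, catch) in later
#' years is dropped, the model years and bias-adjustment factors are cut to
#' match, and the model is refitted. Peel 0 is the full fit.
#'
#' @param cfg An `em_config`.
#' @param data An `observed_dataset`.
#' @param n_peel Number of retrospective peels (>= 0); at least 10 model
#'   years must remain at the deepest peel.
#' @return A `retro_result`: a list of `fit_result`, one per peel, with the
#'   peel depth in `attr(, "peels")`. Summarize with [mohns_rho()].
#' @export
run_retrospective <- function(cfg, data, n_peel) {
  stopifnot(n_peel >= 0)
  years <- cfg$lh$years
  ny <- length(years)
  if (ny - n_peel < 10) {
    stop("retrospective needs >= 10 model years at the deepest peel; ",
         ny, " years - ", n_peel, " peels leaves ", ny - n_peel,
         call. = FALSE)
  }
  fits <- lapply(0:n_peel, function(p) {
    Tcut <- years[ny - p]
    cfg_p <- cfg
    keep <- years <= Tcut
    cfg_p$lh$years <- years[keep]
    for (fld in c("M", "k", "Linf", "cv_length")) {
      if (length(cfg_p$lh[[fld]]) == ny) cfg_p$lh[[fld]] <- cfg_p$lh[[fld]][keep]
    }
    cfg_p$lh$fleets <- lapply(cfg_p$lh$fleets, function(fl) {
      for (fld in c("sel_a50", "sel_slope", "q")) {
        if (length(fl[[fld]]) == ny) fl[[fld]] <- fl[[fld]][keep]
      }
      fl
    })
    cfg_p$b_y <- cfg$b_y[keep]
    data_p <- data
    for (tb in c("index", "agecomp", "lencomp", "catch")) {
      data_p[[tb]] <- data_p[[tb]][data_p[[tb]]$year <= Tcut, ]
    }
    fit(cfg_p, data_p)
  })
  structure(fits, peels = 0:n_peel, class = "retro_result")
}

#' Mohn's rho retrospective statistic
#'
#' Mean over peels of the relative difference between the peeled and full
#' estimates at each peel's terminal year:
#' `rho = mean_p (X_p(T - p) - X_0(T - p)) / X_0(T - p)`, `p = 1..P`.
#' Near-zero rho is expected when the estimation model matches the operating
#' model; systematic departures indicate a retrospective pattern.
#'
#' @param retro A `retro_result` from [run_retrospective()].
#' @param quantity `"SSB"` (default) or `"R"`.
#' @return Scalar Mohn's rho.
#' @export
mohns_rho <- function(retro, quantity = c("SSB", "R")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(retro, "retro_result"))
  full <- retro[[1]]
  series <- function(ft) {
    tb <- if (quantity == "SSB") ft$ssb else ft$recruits
    stats::setNames(tb$est, tb$year)
  }
  s0 <- series(full)
  peels <- attr(retro, "peels")
  terms <- vapply(seq_along(retro)[-1], function(i) {
    sp <- series(retro[[i]])
    yr <- names(sp)[length(sp)]
    (sp[[yr]] - s0[[yr]]) / s0[[yr]]
  }, numeric(1))
  mean(terms)
}
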
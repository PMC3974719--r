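#' Mean length-at-age under von Bertalanffy growth
#'
#' `L_a = Linf * (1 - exp(-k * (a - t0)))`, floored at a small positive
#' fraction of `Linf` so age-0 fish never get a non-positive length.
#'
#' @param ages Ages (yr).
#' @param Linf,k,t0 von Bertalanffy parameters.
#' @return Lengths (cm), one per age.
#' @export
mean_length_at_age <- function(ages, Linf, k, t0) {
  pmax(Linf * (1 - exp(-k * (ages - t0))), 1e-4 * Linf)
}

#' Weight-at-age from the length-weight relationship
#'
#' @param lengths Lengths (cm).
#' @param w_alpha,w_beta Length-weight coefficients (kg, cm).
#' @return Weights (kg).
#' @export
weight_at_length <- function(lengths, w_alpha, w_beta) {
  w_alpha * lengths^w_beta
}

#' Logistic curve over age
#'
#' Shared parameterization for maturity and selectivity:
#' `1 / (1 + exp(-slope * (age - a50)))`.
#'
#' @param ages Ages (yr).
#' @param a50 Age at 50%.
#' @param slope Logistic slope (1/yr).
#' @return Values in (0, 1).
#' @export
logistic_age <- function(ages, a50, slope) {
  1 / (1 + exp(-slope * (ages - a50)))
}

# Maturity-at-age; recruits (age 0) are immature by convention so the
# within-year SSB -> recruitment recursion is well defined.
maturity_at_age <- function(lh, ages = lh$ages) {
  m <- logistic_age(ages, lh$mat_a50, lh$mat_slope)
  m[ages == 0] <- 0
  m
}

selectivity_at_age <- function(fleet, ages) {
  logistic_age(ages, fleet$sel_a50, fleet$sel_slope)
}

#' Age-length transition matrix
#'
#' Probability that a fish of age `a` falls in length bin `l`: the Normal
#' mass with mean `L_a` (von Bertalanffy) and SD `cv_length * L_a` between
#' the bin edges, with open-ended first and last bins, renormalized per age.
#' With `m` interior edges there are `m + 1` bins; rows are bins, columns
#' ages, and every column sums to 1.
#'
#' @param lh A `life_history`; or supply `Linf`, `k`, `t0`, `cv_length`
#'   explicitly to override (used for time-varying growth).
#' @param Linf,k,t0,cv_length Optional overrides of the growth parameters.
#' @return A `(length(length_bins) + 1) x length(ages)` matrix; row names are
#'   the lower bin edges (`-Inf` for the first bin).
#' @export
age_length_transition <- function(lh, Linf = lh$Linf, k = lh$k, t0 = lh$t0,
                                  cv_length = lh$cv_length) {
  edges <- lh$length_bins
  L <- mean_length_at_age(lh$ages, Linf, k, t0)
  sd <- cv_length * L
  full_edges <- c(-Inf, edges, Inf)
  nb <- length(edges) + 1L
  P <- matrix(0, nrow = nb, ncol = length(lh$ages),
              dimnames = list(bin = c(-Inf, edges), age = lh$ages))
  for (j in seq_along(lh$ages)) {
    cdf <- stats::pnorm(full_edges, mean = L[j], sd = sd[j])
    p <- diff(cdf)
    P[, j] <- p / sum(p)
  }
  P
}
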
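#' Construct a life-history configuration
#'
#' A `life_history` object holds every biological and fleet parameter that
#' defines an operating-model (OM) or estimation-model (EM) structure: ages,
#' model years, natural mortality, von Bertalanffy growth, length-weight,
#' logistic maturity, Beverton-Holt steepness and unfished recruitment,
#' recruitment variability, length bins, and one `fleet_spec` per fleet.
#'
#' @param name Identifier for the stock (e.g. `"cod"`).
#' @param ages Integer vector `0:A`; the last age `A` is a plus group.
#' @param years Calendar years of the projection (contiguous).
#' @param M Natural mortality (1/yr); scalar, or per-year vector after
#'   time-varying injection with [apply_tv()].
#' @param Linf,k,t0 von Bertalanffy parameters: asymptotic length (cm),
#'   growth rate (1/yr), theoretical age at length zero (yr).
#' @param w_alpha,w_beta Length-weight coefficients, `W = w_alpha * L^w_beta`
#'   with weight in kg and length in cm.
#' @param mat_a50,mat_slope Logistic maturity-at-age: age at 50% maturity and
#'   slope (1/yr). Age-0 fish are treated as immature regardless.
#' @param h Beverton-Holt steepness, in (0.2, 1].
#' @param R0 Unfished recruitment (numbers of age-0 fish).
#' @param sigma_R SD of log-scale recruitment deviations.
#' @param cv_length CV of length-at-age (constant across ages).
#' @param length_bins Strictly increasing interior bin edges (cm); the first
#'   and last bins are open-ended.
#' @param fleets List of [fleet_spec()] objects with unique ids.
#' @return An object of class `life_history`.
#' @seealso [get_builtin()], [read_life_history()]
#' @export
life_history <- function(name, ages, years, M, Linf, k, t0, w_alpha, w_beta,
                         mat_a50, mat_slope, h, R0, sigma_R, cv_length,
                         length_bins, fleets) {
  lh <- structure(
    list(name = name, ages = as.integer(ages), years = as.integer(years),
         M = M, Linf = Linf, k = k, t0 = t0, w_alpha = w_alpha,
         w_beta = w_beta, mat_a50 = mat_a50, mat_slope = mat_slope, h = h,
         R0 = R0, sigma_R = sigma_R, cv_length = cv_length,
         length_bins = length_bins, fleets = fleets),
    class = "life_history")
  validate_life_history(lh)
  lh
}

#' Construct a fleet specification
#'
#' @param fleet_id Positive integer, unique within a life history.
#' @param kind `"fishery"` or `"survey"`.
#' @param sel_a50,sel_slope Logistic selectivity-at-age parameters.
#' @param q Catchability scaler linking selected biomass to the survey index
#'   (surveys only).
#' @param timing Fraction of the year elapsed at observation, in `[0, 1]`.
#'   Fishery catches always accumulate over the whole year; `timing` affects
#'   survey observations only.
#' @return An object of class `fleet_spec`.
#' @export
fleet_spec <- function(fleet_id, kind, sel_a50, sel_slope, q = NA_real_,
                       timing = 0.5) {
  kind <- match.arg(kind, c("fishery", "survey"))
  if (timing < 0 || timing > 1) stop("timing must be in [0, 1]", call. = FALSE)
  if (kind == "survey" && (!is.finite(q) || q <= 0)) {
    stop("survey fleets require q > 0", call. = FALSE)
  }
  structure(list(fleet_id = as.integer(fleet_id), kind = kind,
                 sel_a50 = sel_a50, sel_slope = sel_slope, q = q,
                 timing = timing),
            class = "fleet_spec")
}

#' Validate a life-history object
#'
#' Checks every structural invariant (steepness range, positive growth and
#' mortality, strictly increasing ages and length bins, unique fleet ids) and
#' raises an informative error on the first violation.
#'
#' @param lh A `life_history`.
#' @return `lh`, invisibly.
#' @export
validate_life_history <- function(lh) {
  chk <- function(ok, msg) if (!ok) stop("invalid life history '", lh$name,
                                         "': ", msg, call. = FALSE)
  chk(is.numeric(lh$ages) && length(lh$ages) >= 3 &&
        all(diff(lh$ages) == 1) && lh$ages[1] == 0,
      "ages must be 0:A with A >= 2")
  chk(all(diff(lh$years) == 1) && length(lh$years) >= 2,
      "years must be contiguous")
  chk(all(lh$M > 0), "M must be > 0 in every year")
  chk(length(lh$M) %in% c(1L, length(lh$years)),
      "M must be a scalar or one value per year")
  chk(lh$Linf > 0 && lh$k > 0, "Linf and k must be > 0")
  chk(lh$h > 0.2 && lh$h <= 1, "steepness h must satisfy 0.2 < h <= 1")
  chk(lh$sigma_R > 0, "sigma_R must be > 0")
  chk(lh$R0 > 0, "R0 must be > 0")
  chk(lh$cv_length > 0, "cv_length must be > 0")
  chk(all(diff(lh$length_bins) > 0) && length(lh$length_bins) >= 2,
      "length_bins must be strictly increasing")
  chk(length(lh$fleets) >= 1, "at least one fleet required")
  ids <- vapply(lh$fleets, function(f) f$fleet_id, integer(1))
  chk(!anyDuplicated(ids), "fleet ids must be unique")
  invisible(lh)
}

#' @export
print.life_history <- function(x, ...) {
  kinds <- vapply(x$fleets, function(f) f$kind, character(1))
  cat("<life_history> ", x$name, "\n",
      "  ages 0:", max(x$ages), " (plus group), years ", min(x$years), "-",
      max(x$years), "\n",
      "  M = ", paste(unique(x$M), collapse = "/"), ", Linf = ", x$Linf,
      ", k = ", x$k, ", h = ", x$h, ", R0 = ", format(x$R0),
      ", sigma_R = ", x$sigma_R, "\n",
      "  fleets: ", paste(paste0(vapply(x$fleets, function(f) f$fleet_id,
                                        integer(1)), " (", kinds, ")"),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

builtin_names <- c("cod", "flatfish", "sardine")

#' Load a built-in life-history configuration
#'
#' The package ships three generic life histories: `cod` (slow-growing,
#' long-lived), `flatfish` (fast-growing, long-lived) and `sardine`
#' (fast-growing, short-lived). Each is stored as a plain-text key-value file
#' under `inst/extdata/models/` that users can copy and modify; the schema is
#' documented in `inst/extdata/models/SCHEMA.md`.
#'
#' @param name One of `"cod"`, `"flatfish"`, `"sardine"`.
#' @return A list with elements `om` (the operating-model configuration) and
#'   `em_template` (a structurally matching estimation-model template sharing
#'   identical ages, years, bins and fleets; which parameters are estimated
#'   vs fixed is set later via [em_config()]).
#' @examples
#' cod <- get_builtin("cod")
#' cod$om$M
#' @export
get_builtin <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% builtin_names)) {
    stop("unknown life history '", name, "'; valid names: ",
         paste(builtin_names, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", "models", paste0(name, ".txt"),
                      package = "scaloop", mustWork = TRUE)
  om <- read_life_history(path)
  list(om = om, em_template = om)
}

#' Read a life-history configuration file
#'
#' The file uses the same `key; value` dialect as the case files
#' (see [parse_case_file()]); fleet blocks use `fleet<id>_` prefixed keys.
#'
#' @param path Path to a stock configuration file.
#' @return A validated `life_history`.
#' @export
read_life_history <- function(path) {
  kv <- parse_case_file(path)
  need <- function(key) {
    if (is.null(kv[[key]])) stop("life-history file ", basename(path),
                                 " missing key '", key, "'", call. = FALSE)
    kv[[key]]
  }
  ids <- need("fleets")
  fleets <- lapply(ids, function(id) {
    fk <- function(suffix, default = NULL) {
      v <- kv[[paste0("fleet", id, "_", suffix)]]
      if (is.null(v)) default else v
    }
    fleet_spec(fleet_id = id,
               kind = fk("kind"),
               sel_a50 = fk("sel_a50"), sel_slope = fk("sel_slope"),
               q = fk("q", NA_real_), timing = fk("timing", 0.5))
  })
  life_history(name = need("name"), ages = need("ages"), years = need("years"),
               M = need("M"), Linf = need("Linf"), k = need("k"),
               t0 = need("t0"), w_alpha = need("w_alpha"),
               w_beta = need("w_beta"), mat_a50 = need("mat_a50"),
               mat_slope = need("mat_slope"), h = need("h"), R0 = need("R0"),
               sigma_R = need("sigma_R"), cv_length = need("cv_length"),
               length_bins = need("length_bins"), fleets = fleets)
}

# Fleet accessors used throughout the package.
fishery_fleets <- function(lh) {
  Filter(function(f) f$kind == "fishery", lh$fleets)
}
survey_fleets <- function(lh) {
  Filter(function(f) f$kind == "survey", lh$fleets)
}
get_fleet <- function(lh, fleet_id) {
  for (f in lh$fleets) if (f$fleet_id == fleet_id) return(f)
  stop("no fleet with id ", fleet_id, " in life history '", lh$name, "'",
       call. = FALSE)
}
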
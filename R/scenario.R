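#' Parse a scenario ID
#'
#' A scenario ID is a hyphen-separated string of case tokens followed by the
#' species tag, e.g. `"D1-E0-F0-M0-R0-cod"`: each token is a case letter and
#' case number. The data case `D` expands to the three case files
#' `index<k>`, `lcomp<k>`, `agecomp<k>`; every other letter maps to the
#' single file `<letter><k>-<species>.txt`.
#'
#' @param id Scenario ID string.
#' @return A `scenario_id`: list with `id`, `cases` (named integer vector,
#'   letter -> number, in token order) and `species`. Round-trips through
#'   [format_scenario_id()].
#' @examples
#' parse_scenario_id("D1-E0-F0-M0-R0-cod")
#' @export
parse_scenario_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1)
  tokens <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 2) {
    stop("scenario ID must be case tokens followed by a species tag: ", id,
         call. = FALSE)
  }
  species <- tokens[length(tokens)]
  if (!grepl("^[a-z][a-z0-9]*$", species)) {
    stop("scenario ID must end in a lowercase species tag: ", id,
         call. = FALSE)
  }
  toks <- tokens[-length(tokens)]
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)$", toks))
  bad <- toks[vapply(m, length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop("malformed case token(s) in scenario ID '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  letters_ <- vapply(m, `[`, character(1), 2)
  numbers <- as.integer(vapply(m, `[`, character(1), 3))
  dup <- unique(letters_[duplicated(letters_)])
  if (length(dup) > 0) {
    stop("duplicate case letter(s) in scenario ID '", id, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, cases = stats::setNames(numbers, letters_),
                 species = species),
            class = "scenario_id")
}

#' Format a parsed scenario back into its ID string
#'
#' @param x A `scenario_id`.
#' @return The ID string; `format_scenario_id(parse_scenario_id(s))`
#'   equals `s`.
#' @export
format_scenario_id <- function(x) {
  stopifnot(inherits(x, "scenario_id"))
  paste(c(paste0(names(x$cases), x$cases), x$species), collapse = "-")
}

#' Derive a reproducible seed from labels
#'
#' Stable polynomial rolling hash (base 31 over the UTF-8 bytes of the
#' `|`-joined arguments, modulo the prime 2147483629), so seeds are portable
#' across platforms and R versions. Process-error seeds are derived from
#' (base seed, iteration) only — never from the scenario — so iteration `i`
#' reuses the same recruitment draws in every scenario and cross-scenario
#' contrasts at fixed `i` are paired. Observation seeds additionally hash
#' the scenario ID and sampler name, giving independent observation streams.
#'
#' @param ... Labels (coerced with `as.character`).
#' @return An integer seed in `[0, 2147483628]`.
#' @export
hash_seed <- function(...) {
  parts <- paste(vapply(list(...), function(x) paste(as.character(x),
                                                     collapse = ","),
                        character(1)), collapse = "|")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

process_seed <- function(base_seed, iteration) {
  hash_seed(base_seed, iteration, "proc")
}
observation_seed <- function(base_seed, iteration, scenario_id, sampler) {
  hash_seed(base_seed, iteration, scenario_id, "obs", sampler)
}

#' Assemble a run configuration
#'
#' @param iterations Integer vector of iteration numbers (e.g. `1:100`).
#' @param scenarios Character vector of scenario IDs.
#' @param case_folder Directory with the case files.
#' @param om,em Operating/estimation life histories: a built-in name, a path
#'   to a stock configuration file, a `life_history`, or NULL to use the
#'   built-in named by each scenario's species tag.
#' @param bias_adjust Calibrate recruitment bias adjustment before the final
#'   fit ([run_bias_adjust()]).
#' @param parallel_workers Number of worker processes (forked; results are
#'   byte-identical to a serial run).
#' @param base_seed Integer base seed for all derived seeds.
#' @param output_dir Root directory for scenario folders.
#' @return A `run_config`.
#' @export
run_config <- function(iterations, scenarios, case_folder, om = NULL,
                       em = NULL, bias_adjust = FALSE, parallel_workers = 1,
                       base_seed = 1, output_dir = ".") {
  stopifnot(length(iterations) >= 1, length(scenarios) >= 1,
            parallel_workers >= 1)
  structure(list(iterations = as.integer(iterations), scenarios = scenarios,
                 case_folder = case_folder, om = om, em = em,
                 bias_adjust = isTRUE(bias_adjust),
                 parallel_workers = as.integer(parallel_workers),
                 base_seed = as.integer(base_seed), output_dir = output_dir),
            class = "run_config")
}

resolve_life_history <- function(x, species) {
  if (is.null(x)) return(get_builtin(species)$om)
  if (inherits(x, "life_history")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (x %in% builtin_names) return(get_builtin(x)$om)
    return(read_life_history(x))
  }
  stop("cannot resolve a life history from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
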
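#' Parse a semicolon-delimited case file
#'
#' Case files supply the argument values for one aspect of a scenario (data
#' sampling, estimation toggles, fishing mortality, natural mortality,
#' retrospective peels). Each non-blank line has the form `key; value`, split
#' on the *first* semicolon. Values are parsed by a small, closed grammar:
#'
#' * integer / real literals (`2`, `0.1`, `-0.2`, `6.8e-6`),
#' * `TRUE` / `FALSE`,
#' * quoted text (`"estimated"`),
#' * `c(x1, x2, ...)` — a numeric vector,
#' * `seq(a, b, by = s)` — the arithmetic sequence `a, a + s, ..., <= b`,
#' * `list(e1, e2, ...)` — a list whose elements are any of the above
#'   (used for per-fleet arguments, e.g. one vector of years per fleet).
#'
#' No other expression form is evaluated; the grammar is deliberately closed
#' rather than a general-purpose evaluator.
#'
#' @param path Path to a case file, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A named list of parsed values, in file order.
#' @examples
#' parse_case_file(text = c("fleets; 2",
#'                          "years; list(seq(1974, 2012, by = 2))",
#'                          "sds_obs; list(0.1)"))
#' @export
parse_case_file <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(path), length(path) == 1)
    if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
    text <- readLines(path, warn = FALSE)
  }
  lines <- text[!grepl("^\\s*(#|$)", text)]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    pos <- regexpr(";", ln, fixed = TRUE)
    if (pos < 0) {
      stop("case-file parse error at line ", which(text == ln)[1],
           ": missing ';' in \"", trimws(ln), "\"", call. = FALSE)
    }
    key <- trimws(substr(ln, 1, pos - 1))
    val <- trimws(substr(ln, pos + 1, nchar(ln)))
    if (!nzchar(key)) {
      stop("case-file parse error at line ", which(text == ln)[1],
           ": empty key", call. = FALSE)
    }
    if (key %in% names(out)) {
      stop("duplicate key '", key, "' in case file", call. = FALSE)
    }
    out[[key]] <- parse_case_value(val)
  }
  out
}

#' Parse a single case-file value
#'
#' @param s A value string in the case-file grammar (see [parse_case_file()]).
#' @return A number, logical, string, numeric vector, or list of those.
#' @export
parse_case_value <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty case-file value", call. = FALSE)
  num_re <- "^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$"
  if (grepl(num_re, s)) return(as.numeric(s))
  if (s %in% c("TRUE", "FALSE")) return(as.logical(s))
  if (grepl('^"[^"]*"$', s)) return(substr(s, 2, nchar(s) - 1))
  if (grepl("^list\\(.*\\)$", s)) {
    inner <- substr(s, 6, nchar(s) - 1)
    return(lapply(split_top_level(inner), parse_case_value))
  }
  if (grepl("^c\\(.*\\)$", s)) {
    inner <- substr(s, 3, nchar(s) - 1)
    parts <- split_top_level(inner)
    vals <- vapply(parts, function(p) {
      v <- parse_case_value(p)
      if (!is.numeric(v) || length(v) != 1) {
        stop("c(...) accepts numeric scalars only, got: ", p, call. = FALSE)
      }
      v
    }, numeric(1))
    return(unname(vals))
  }
  m <- regmatches(s, regexec(
    "^seq\\(\\s*([^,]+)\\s*,\\s*([^,]+)\\s*,\\s*by\\s*=\\s*([^,)]+)\\s*\\)$", s))[[1]]
  if (length(m) == 4) {
    a <- parse_case_value(m[2]); b <- parse_case_value(m[3]); by <- parse_case_value(m[4])
    if (!all(vapply(list(a, b, by), is.numeric, logical(1)))) {
      stop("seq(a, b, by = s) requires numeric arguments: ", s, call. = FALSE)
    }
    if (by <= 0) stop("seq(..., by = ", by, "): step must be > 0", call. = FALSE)
    if (b < a) stop("seq(", a, ", ", b, "): upper limit below lower", call. = FALSE)
    return(seq(a, b, by = by))
  }
  stop("cannot parse case-file value: \"", s, "\"", call. = FALSE)
}

# Split "a, b, c" on commas at parenthesis depth zero.
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  out <- vapply(seq_along(starts), function(j) {
    trimws(paste(chars[starts[j]:ends[j]], collapse = ""))
  }, character(1))
  out[nzchar(out)]
}

#' Locate and read the case files for one case letter
#'
#' Files are named `<casetype><number>-<species>.txt`; the data case letter
#' `D` expands to the three files `index<k>`, `lcomp<k>`, `agecomp<k>`.
#'
#' @param case_folder Directory holding the case files.
#' @param letter Case letter (e.g. `"D"`, `"E"`).
#' @param number Case number.
#' @param species Species/stock tag (e.g. `"cod"`).
#' @return A named list: for `D`, elements `index`, `lcomp`, `agecomp`;
#'   otherwise the parsed key-value list of the single file.
#' @export
read_case <- function(case_folder, letter, number, species) {
  one <- function(stem) {
    p <- file.path(case_folder, paste0(stem, number, "-", species, ".txt"))
    if (!file.exists(p)) {
      stop("missing case file: ", basename(p), " (for case ", letter, number,
           "-", species, ")", call. = FALSE)
    }
    parse_case_file(p)
  }
  switch(letter,
    D = list(index = one("index"), lcomp = one("lcomp"), agecomp = one("agecomp")),
    E = one("E"),
    F = one("F"),
    M = one("M"),
    R = one("R"),
    stop("unknown case letter: ", letter, call. = FALSE)
  )
}
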
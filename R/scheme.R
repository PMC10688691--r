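#' Progressive first-failure censoring schemes
#'
#' A progressive first-failure censoring (PFFC) experiment places `n`
#' independent groups of `k` items on test. At the i-th observed first
#' failure, `removals[i]` surviving whole groups are withdrawn (together
#' with the group that failed); the test stops at the m-th failure. The
#' removal vector must satisfy `n = m + sum(removals)`.
#'
#' @param removals non-negative integer vector of group removals, one entry
#'   per observed failure (length `m`).
#' @param k number of items per group (>= 1). `k = 1` reduces the design to
#'   ordinary progressive type-II censoring; `k = 1` with all removals zero
#'   is the complete-sample case.
#' @param n number of groups; defaults to `m + sum(removals)` and is
#'   validated against it when supplied.
#'
#' @return an object of class `"censoring_scheme"`: a list with elements
#'   `n`, `k`, `m` and `removals`.
#' @examples
#' censoring_scheme(c(5, rep(0, 9)), k = 2)
#' parse_scheme("(5 * 1, 0 * 19)", k = 2)
#' @seealso [parse_scheme()] for the compact `(v * r, ...)` notation,
#'   [rpffc()] to draw samples under a scheme.
#' @export
censoring_scheme <- function(removals, k = 1, n = NULL) {
  if (!is.numeric(removals) || length(removals) < 1L ||
      any(!is.finite(removals)) || any(removals < 0) ||
      any(removals != round(removals)))
    stop("'removals' must be non-negative integers", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  removals <- as.integer(round(removals))
  m <- length(removals)
  n_implied <- m + sum(removals)
  if (is.null(n)) n <- n_implied
  if (n != n_implied)
    stop(sprintf("inconsistent scheme: n = %d but m + sum(removals) = %d",
                 n, n_implied), call. = FALSE)
  structure(list(n = as.integer(n), k = as.integer(k), m = m,
                 removals = removals),
            class = "censoring_scheme")
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("PFFC scheme: n = %d groups of k = %d, m = %d failures\n",
              x$n, x$k, x$m))
  cat("removals:", format_scheme(x$removals), "\n")
  invisible(x)
}

# compact run-length notation, e.g. (5*1, 0*19)
format_scheme <- function(g) {
  r <- rle(g)
  tok <- ifelse(r$lengths > 1L,
                paste0(r$values, "*", r$lengths),
                as.character(r$values))
  paste0("(", paste(tok, collapse = ", "), ")")
}

#' Parse compact censoring-scheme notation
#'
#' Expands strings such as `"(5 * 1, 0 * 19)"` — meaning the value 5
#' repeated once followed by 0 repeated nineteen times — into a removal
#' vector and returns the corresponding [censoring_scheme()]. Bare values
#' (`"(0, 0)"`) and repeat tokens may be mixed; whitespace and the outer
#' parentheses are optional.
#'
#' @param text scheme string.
#' @param k items per group of the resulting scheme.
#' @return a `"censoring_scheme"` object.
#' @examples
#' parse_scheme("(1 * 2, 0 * 8, 1 * 1, 0 * 7, 1 * 2)", k = 2)
#' @export
parse_scheme <- function(text, k = 1) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string", call. = FALSE)
  body <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(text))
  toks <- strsplit(body, ",", fixed = TRUE)[[1]]
  if (length(toks) == 0L) stop("empty scheme string", call. = FALSE)
  removals <- unlist(lapply(toks, function(tk) {
    tk <- gsub("\\s+", "", tk)
    if (grepl("^\\d+\\*\\d+$", tk)) {
      vr <- as.integer(strsplit(tk, "*", fixed = TRUE)[[1]])
      rep(vr[1], vr[2])
    } else if (grepl("^\\d+$", tk)) {
      as.integer(tk)
    } else {
      stop(sprintf("malformed scheme token '%s'", tk), call. = FALSE)
    }
  }))
  censoring_scheme(removals, k = k)
}

#' Read a censoring scheme from a YAML or JSON file
#'
#' The file must contain the keys `k` and either `removals` (a vector) or
#' `scheme_string` (compact notation understood by [parse_scheme()]);
#' an optional `n` is validated.
#'
#' @param path file path; format chosen by extension (`.json` via jsonlite,
#'   anything else via the yaml package).
#' @return a `"censoring_scheme"` object.
#' @export
read_scheme_file <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML scheme files requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  }
  k <- spec$k %||% 1
  sch <- if (!is.null(spec$removals)) {
    censoring_scheme(spec$removals, k = k, n = spec$n)
  } else if (!is.null(spec$scheme_string)) {
    parse_scheme(spec$scheme_string, k = k)
  } else {
    stop("scheme file must provide 'removals' or 'scheme_string'", call. = FALSE)
  }
  if (!is.null(spec$n) && sch$n != spec$n)
    stop("scheme file 'n' inconsistent with removals", call. = FALSE)
  sch
}

`%||%` <- function(a, b) if (is.null(a)) b else a
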
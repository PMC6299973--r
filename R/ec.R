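#' Parse Enzyme Commission (EC) numbers
#'
#' Parses EC identifiers into their four positions and a canonical string
#' form. Complete EC numbers look like `"2.7.1.2"`; partial ("three-digit")
#' numbers omit the serial, e.g. `"1.2.3.-"`, and two-digit partials such as
#' `"1.2.-.-"` are accepted and flagged partial as well. A leading `"EC"`
#' label (with optional colon) and surrounding whitespace are tolerated.
#'
#' Equality of EC numbers throughout the package is exact canonical-string
#' equality of all four positions; there is no hierarchy-aware matching and
#' deprecated or transferred numbers are not remapped.
#'
#' @param x Character vector of EC strings.
#' @param strict_classes If `TRUE`, restrict the top-level class to 1..6
#'   (pre-translocase nomenclature); default accepts 1..7.
#' @return A tibble with one row per element of `x`: `input`, `ec_class`,
#'   `subclass`, `subsubclass`, `serial` (integers, `NA` at and after the
#'   first omitted position), `is_partial`, and `canonical` (the normalized
#'   string, `"c.s.ss.n"` or with `"-"` in omitted trailing positions).
#' @examples
#' ec_parse(c("EC 1.1.1.1", "1.2.3.-"))
#' @export
ec_parse <- function(x, strict_classes = FALSE) {
  stopifnot(is.character(x))
  raw <- trimws(x)
  fail <- function(i, why) {
    stop(sprintf("EC parse error: %s in '%s'", why, x[i]), call. = FALSE)
  }
  empty <- is.na(raw) | !nzchar(raw)
  if (any(empty)) fail(which(empty)[1], "empty or missing EC string")
  body <- trimws(sub("^[Ee][Cc][ :]+", "", raw))
  pat <- "^([0-9]+)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"
  ok <- grepl(pat, body)
  if (any(!ok)) fail(which(!ok)[1], "malformed EC string")
  f1 <- sub(pat, "\\1", body)
  f2 <- sub(pat, "\\2", body)
  f3 <- sub(pat, "\\3", body)
  f4 <- sub(pat, "\\4", body)
  # omitted positions must form a trailing run ("1.2.-.4" is malformed)
  bad_run <- (f2 == "-" & f3 != "-") | (f3 == "-" & f4 != "-")
  if (any(bad_run)) fail(which(bad_run)[1], "non-trailing '-'")
  to_int <- function(f) ifelse(f == "-", NA_integer_, suppressWarnings(as.integer(f)))
  v1 <- to_int(f1); v2 <- to_int(f2); v3 <- to_int(f3); v4 <- to_int(f4)
  max_class <- if (strict_classes) 6L else 7L
  bad_class <- is.na(v1) | v1 < 1L | v1 > max_class
  if (any(bad_class)) {
    fail(which(bad_class)[1], sprintf("class outside 1..%d", max_class))
  }
  bad_zero <- (!is.na(v2) & v2 < 1L) | (!is.na(v3) & v3 < 1L) |
    (!is.na(v4) & v4 < 1L)
  if (any(bad_zero)) fail(which(bad_zero)[1], "non-positive field")
  dash_if_na <- function(v) ifelse(is.na(v), "-", as.character(v))
  tibble::tibble(
    input = x,
    ec_class = v1, subclass = v2, subsubclass = v3, serial = v4,
    is_partial = is.na(v4),
    canonical = paste(dash_if_na(v1), dash_if_na(v2), dash_if_na(v3),
                      dash_if_na(v4), sep = ".")
  )
}

#' Canonicalize EC strings
#'
#' Shortcut for [ec_parse()] returning only the canonical string form.
#' Malformed input raises a parse error naming the offending text.
#'
#' @inheritParams ec_parse
#' @return Character vector of canonical EC strings.
#' @export
ec_canonical <- function(x, strict_classes = FALSE) {
  if (length(x) == 0) return(character())
  ec_parse(x, strict_classes = strict_classes)$canonical
}

# canonical forms or NA for unparseable input, no error
ec_try_canonical <- function(x, strict_classes = FALSE) {
  vapply(x, function(s) {
    tryCatch(ec_parse(s, strict_classes = strict_classes)$canonical,
             error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether canonical EC strings are partial
#'
#' A partial EC omits at least the serial position (`"1.2.3.-"`).
#'
#' @param x Character vector of canonical EC strings.
#' @return Logical vector.
#' @export
ec_is_partial <- function(x) {
  grepl("-", x, fixed = TRUE)
}

#' Extract embedded EC tokens from a functional annotation string
#'
#' Scans free-text functional descriptions (RAST-style) for embedded
#' `"(EC c.s.ss.n)"` or `"(EC c.s.ss.-)"` tokens and returns the canonical EC
#' strings in order of first appearance, deduplicated. Strings without a
#' valid token yield an empty result.
#'
#' @param text Character vector of function descriptions.
#' @return A list (one element per input string) of character vectors of
#'   canonical EC strings.
#' @examples
#' ec_extract("Glucokinase (EC 2.7.1.2)")
#' @export
ec_extract <- function(text) {
  stopifnot(is.character(text))
  pat <- "\\(\\s*EC[ :]\\s*([0-9]+(?:\\.(?:[0-9]+|-)){3})\\s*\\)"
  m <- regmatches(text, gregexpr(pat, text, perl = TRUE))
  lapply(m, function(tokens) {
    if (length(tokens) == 0) return(character())
    body <- sub(pat, "\\1", tokens, perl = TRUE)
    parsed <- ec_try_canonical(body)
    unique(parsed[!is.na(parsed)])
  })
}

#' Drop partial-EC annotation records
#'
#' Incomplete ("three-digit") EC annotations such as `1.2.3.-` can be useful
#' for pathway hole filling but are excluded from all comparison statistics;
#' this filter removes them while leaving complete-EC records untouched.
#' Non-EC records (KO, TRANSPORT) pass through unchanged. Idempotent.
#'
#' @param x A normalized annotation tibble (see [read_annotation_table()]).
#' @return The tibble with partial-EC rows removed.
#' @export
filter_complete <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("feature_type", "value") %in% names(x))) {
    stop("filter_complete() expects a normalized annotation table", call. = FALSE)
  }
  dplyr::filter(x, .data$feature_type != "EC" | !ec_is_partial(.data$value))
}
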
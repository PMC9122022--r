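#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.05 -> 0.1), matching the convention of the statistical software
#' that produced the published tables. Base R's `round()` rounds half to
#' even and would disagree at ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1).
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse a character column of ISO-8601 dates, with an error that names the
# file, row and column of the first offending value.
parse_date_column <- function(x, file, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(trimws(as.character(x))))
  na_in <- which(is.na(x) | !nzchar(trimws(as.character(x))))
  if (length(na_in)) {
    stop(sprintf("unparseable date in '%s', row %d, column '%s': missing value",
                 file, na_in[1], column), call. = FALSE)
  }
  if (length(bad)) {
    stop(sprintf("unparseable date in '%s', row %d, column '%s': '%s'",
                 file, bad[1], column, x[bad[1]]), call. = FALSE)
  }
  d
}

# Coerce a 0/1/true/false column to logical, NA allowed when allow_na.
parse_flag_column <- function(x, file, column, allow_na = FALSE) {
  xx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(xx))
  out[xx %in% c("1", "true", "t", "yes")] <- TRUE
  out[xx %in% c("0", "false", "f", "no")] <- FALSE
  miss <- is.na(x) | xx %in% c("", "na")
  if (!allow_na && any(is.na(out) & !miss)) {
    i <- which(is.na(out) & !miss)[1]
    stop(sprintf("invalid boolean in '%s', row %d, column '%s': '%s'",
                 file, i, column, x[i]), call. = FALSE)
  }
  if (!allow_na && any(miss)) {
    stop(sprintf("missing boolean in '%s', row %d, column '%s'",
                 file, which(miss)[1], column), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

days_between <- function(a, b) as.integer(as.Date(b) - as.Date(a))
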
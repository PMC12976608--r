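# Exact time arithmetic.
#
# Every duration, wait, buffer, interval and clock position in the scheduling
# logic is an integer count of milliminutes (1/1000 min). Integer arithmetic
# keeps boundary cases exact: two windows that merely touch never register as
# overlapping, regardless of how many operations were summed to reach the
# boundary. Doubles appear only at the display/serialization boundary.

#' Convert minutes to milliminutes
#'
#' Accepts numeric minutes or decimal-minute strings (up to 3 decimal places)
#' and converts to exact integer milliminutes. Values that are not
#' representable at milliminute resolution are rejected rather than rounded.
#'
#' @param x numeric vector of minutes, or character vector of decimal minute
#'   strings such as `"0.25"` or `"85.5"`.
#' @param what label used in error messages.
#' @return integer vector of milliminutes.
#' @keywords internal
as_mmin <- function(x, what = "time") {
  if (is.character(x)) {
    return(vapply(x, parse_mmin, integer(1), what = what, USE.NAMES = FALSE))
  }
  if (!is.numeric(x)) {
    stop(what, " must be numeric minutes or a decimal minute string", call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contains NA", call. = FALSE)
  mm <- round(x * 1000)
  off <- abs(x * 1000 - mm) > 1e-6
  if (any(off)) {
    stop(what, " value ", x[which(off)[1]],
         " is not representable at milliminute (0.001 min) resolution",
         call. = FALSE)
  }
  as.integer(mm)
}

parse_mmin <- function(s, what = "time") {
  s <- trimws(s)
  if (!grepl("^-?[0-9]+(\\.[0-9]{1,3})?$", s)) {
    stop(what, " string '", s, "' is not a decimal minute value with at most 3 decimals",
         call. = FALSE)
  }
  neg <- startsWith(s, "-")
  if (neg) s <- substring(s, 2)
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  whole <- as.integer(parts[1]) * 1000L
  frac <- if (length(parts) == 2) {
    as.integer(paste0(parts[2], strrep("0", 3L - nchar(parts[2]))))
  } else 0L
  mm <- whole + frac
  if (neg) -mm else mm
}

#' Format milliminutes as a canonical decimal-minute string
#'
#' The canonical form has no trailing zeros and no trailing decimal point
#' (`26000 -> "26"`, `250 -> "0.25"`). Serialization uses this form so that
#' save/load round trips are byte-exact.
#'
#' @param mm integer milliminutes.
#' @return character vector.
#' @keywords internal
mmin_format <- function(mm) {
  mm <- as.integer(mm)
  sign <- ifelse(mm < 0, "-", "")
  a <- abs(mm)
  whole <- a %/% 1000L
  frac <- a %% 1000L
  out <- ifelse(frac == 0L, sprintf("%s%d", sign, whole),
                sprintf("%s%d.%s", sign, whole,
                        sub("0+$", "", sprintf("%03d", frac))))
  out
}

# display-only conversion; never used in comparisons
mmin_to_min <- function(mm) as.numeric(mm) / 1000
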
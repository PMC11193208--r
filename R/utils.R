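#' Round half away from zero
#'
#' Publication-style rounding: exact halves move away from zero, the
#' convention trial reports (and the tables this package mirrors) use.
#' Base `round()` rounds half to even, which disagrees on values such as
#' 0.0925 at 3 decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(0.0925, 3) # 0.093, where round() gives 0.092
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by one ulp so that values stored as ...49999 due to binary
  # representation of a printed half still round up
  z <- abs(x) * m
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / m
}

# count decimals in the literal string form of a number ("12.30" -> 2)
count_decimals <- function(x) {
  x <- trimws(as.character(x))
  out <- integer(length(x))
  has_dec <- grepl(".", x, fixed = TRUE)
  out[has_dec] <- nchar(sub("^-?[0-9]*\\.", "", x[has_dec]))
  out[is.na(x) | x == ""] <- NA_integer_
  out
}

# format one numeric cell back to its recorded number of decimals
format_decimals <- function(x, decimals) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) {
      out[i] <- ""
    } else if (is.na(decimals[i])) {
      out[i] <- format(x[i], trim = TRUE, scientific = FALSE, digits = 15)
    } else {
      out[i] <- formatC(x[i], format = "f", digits = decimals[i])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable non-cryptographic hash of a config list, for run metadata
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
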
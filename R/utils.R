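# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-point rounding as used in printed validation tables (so 91.85 -> 91.9,
#' never banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_away(c(0.5, 1.25, -0.5), 1)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Parse ISO-8601 dates strictly; returns Date with NA for unparseable entries.
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    out[ok] <- parsed
  }
  out
}

# The same calendar day `n` years earlier; Feb 29 maps to Feb 28 in
# non-leap years.
years_before <- function(date, n) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L - as.integer(n)
  mday <- lt$mday
  mon <- lt$mon + 1L
  cand <- as.Date(sprintf("%04d-%02d-%02d", y, mon, mday), format = "%Y-%m-%d")
  feb29 <- is.na(cand)
  if (any(feb29)) {
    cand[feb29] <- as.Date(sprintf("%04d-02-28", y[feb29]))
  }
  cand
}

# Collapse whitespace runs to single spaces, trim, lowercase.
normalize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(pedasthma_error(sprintf(...), class = "pedasthma_input_error"))
}

pedasthma_error <- function(message, class) {
  structure(
    class = c(class, "pedasthma_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}
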
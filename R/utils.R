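#' Parse ISO 8601 timestamps with an explicit UTC offset
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS+HH:MM`, `...+HHMM`, or a trailing `Z`.
#' The offset must be explicit: flow logs are recorded device-side and the
#' offset is the only timezone information carried per record.
#'
#' @param x character vector of timestamps.
#' @return data.frame with columns `utc` (POSIXct, UTC) and `offset_min`
#'   (integer minutes east of UTC).
#' @keywords internal
parse_iso8601 <- function(x) {
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(?:\\.\\d+)?(Z|[+-]\\d{2}:?\\d{2})$",
    x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("unparseable timestamp (ISO 8601 with explicit offset required): ",
         x[which(bad)[1]], call. = FALSE)
  }
  date <- vapply(m, `[`, character(1), 2L)
  time <- vapply(m, `[`, character(1), 3L)
  off  <- vapply(m, `[`, character(1), 4L)
  local <- as.POSIXct(paste(date, time), tz = "UTC",
                      format = "%Y-%m-%d %H:%M:%S")
  offset_min <- ifelse(off == "Z", 0L, {
    sgn <- ifelse(substr(off, 1, 1) == "-", -1L, 1L)
    hh <- as.integer(substr(off, 2, 3))
    mm <- as.integer(sub("^.*?(\\d{2})$", "\\1", substring(off, 4)))
    mm[substring(off, 4) == ""] <- 0L
    sgn * (hh * 60L + mm)
  })
  data.frame(utc = local - offset_min * 60, offset_min = as.integer(offset_min))
}

#' Format a POSIXct as ISO 8601 with an explicit offset
#' @keywords internal
format_iso8601 <- function(utc, offset_min) {
  local <- utc + offset_min * 60
  sgn <- ifelse(offset_min < 0, "-", "+")
  a <- abs(offset_min)
  sprintf("%s%s%02d:%02d",
          format(local, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          sgn, a %/% 60, a %% 60)
}

#' Round half away from zero
#'
#' Reporting convention for printed percentages: 49.89 -> 50, 92.5 -> 93.
#' Base `round()` rounds half to even, which does not match how proportions
#' are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream-specific 32-bit seed from a master seed; keeps every
# stochastic stage independently reproducible from one --seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483647)
}
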
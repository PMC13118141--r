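#' Flow-metadata log input/output and time binning
#'
#' A flow log holds one record per 10-second traffic window per destination
#' hostname: who (opaque participant id), when (window start with explicit
#' UTC offset), where-to (hostname), and how much (bytes/packets up and
#' down). These are the only fields the privacy model retains; no payloads,
#' no IPs beyond what the hostname string itself carries.
#'
#' @name flow_io
NULL

FLOW_COLUMNS <- c("participant_id", "window_start", "duration_s", "hostname",
                  "bytes_up", "bytes_down", "packets_up", "packets_down")

#' Read a flow-metadata log
#'
#' Parses a JSONL (one object per line) or CSV (RFC 4180, header row) flow
#' log into a validated flow-record table. Records are returned in
#' timestamp order within each participant. Malformed lines produce a hard
#' error naming the offending line: silent loss of traffic records would
#' bias every downstream coverage estimate.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return A `flow_log` data.frame with columns `participant_id`,
#'   `window_start` (POSIXct, UTC), `utc_offset_min`, `duration_s`,
#'   `hostname`, `bytes_up`, `bytes_down`, `packets_up`, `packets_down`.
#' @export
read_flow_log <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("flow log not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty flow log: ", path, call. = FALSE)
    df <- tryCatch(
      jsonlite::stream_in(textConnection(lines), verbose = FALSE),
      error = function(e) stop("invalid JSONL in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    missing <- setdiff(FLOW_COLUMNS, names(df))
    if (length(missing) > 0) {
      stop("flow log missing required field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (col in FLOW_COLUMNS) {
      if (anyNA(df[[col]])) {
        stop("line ", which(is.na(df[[col]]))[1], ": missing required field ",
             col, call. = FALSE)
      }
    }
    df <- df[FLOW_COLUMNS]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    missing <- setdiff(FLOW_COLUMNS, names(df))
    if (length(missing) > 0) {
      stop("flow CSV missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    df <- df[FLOW_COLUMNS]
    for (col in c("duration_s", "bytes_up", "bytes_down", "packets_up", "packets_down")) {
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  validate_flow_records(df)
}

# Validate parsed records and normalize column types; errors name the
# first offending line (1-based, in file order).
validate_flow_records <- function(df) {
  num_cols <- c("duration_s", "bytes_up", "bytes_down", "packets_up", "packets_down")
  for (col in num_cols) {
    v <- as.numeric(df[[col]])
    if (anyNA(v)) {
      stop("line ", which(is.na(v))[1], ": non-numeric ", col, call. = FALSE)
    }
    if (any(v < 0)) {
      stop("line ", which(v < 0)[1], ": negative ", col, " (",
           v[which(v < 0)[1]], ")", call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$duration_s != 10)) {
    stop("line ", which(df$duration_s != 10)[1],
         ": duration_s must be 10 (fixed aggregation window)", call. = FALSE)
  }
  if (any(!nzchar(df$hostname) | is.na(df$hostname))) {
    stop("line ", which(!nzchar(df$hostname) | is.na(df$hostname))[1],
         ": empty hostname", call. = FALSE)
  }
  ts <- parse_iso8601(as.character(df$window_start))
  out <- data.frame(
    participant_id = as.character(df$participant_id),
    window_start = ts$utc,
    utc_offset_min = ts$offset_min,
    duration_s = df$duration_s,
    hostname = as.character(df$hostname),
    bytes_up = df$bytes_up,
    bytes_down = df$bytes_down,
    packets_up = df$packets_up,
    packets_down = df$packets_down,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flow_log", "data.frame")
  out
}

#' Write a flow log
#'
#' Inverse of [read_flow_log()]; a write/read round trip reproduces the
#' record table exactly (up to row order, which both ends sort).
#'
#' @param flows a `flow_log` data.frame.
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_flow_log <- function(flows, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  out <- data.frame(
    participant_id = flows$participant_id,
    window_start = format_iso8601(flows$window_start, flows$utc_offset_min),
    duration_s = flows$duration_s,
    hostname = flows$hostname,
    bytes_up = flows$bytes_up,
    bytes_down = flows$bytes_down,
    packets_up = flows$packets_up,
    packets_down = flows$packets_down,
    stringsAsFactors = FALSE
  )
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(out, con, verbose = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Aggregate flow records into contiguous time bins
#'
#' Raw 10-second windows are summed into contiguous, non-overlapping bins
#' of `bin_width` minutes in the participant's local time (fixed UTC
#' offset; no DST modeling, matching a cohort restricted to a consistent
#' time zone). Each record is assigned by its `window_start` only -- a
#' 10-second window never meaningfully straddles a 10-minute bin, so the
#' assignment error is at most 10 s. Bins with no traffic inside the
#' covered span are present with zero bytes; byte totals are conserved.
#'
#' @param flows `flow_log` rows for a single participant.
#' @param bin_width bin width in minutes; must divide 1440 (default 10).
#' @param tz_offset_min local-time offset in minutes east of UTC; default
#'   taken from the records (must then be constant).
#' @return A `binned_series` data.frame with columns `day` (local calendar
#'   day index, 0 = first covered day), `local_date`, `bin` (0-based
#'   within-day index), `bytes_up`, `bytes_down`, `n_records`, plus
#'   attributes `participant_id`, `bin_width`, `tz_offset_min`.
#' @export
bin_traffic <- function(flows, bin_width = 10, tz_offset_min = NULL) {
  if (nrow(flows) == 0) stop("no flow records", call. = FALSE)
  if (length(unique(flows$participant_id)) > 1) {
    stop("bin_traffic expects records from a single participant; got ",
         length(unique(flows$participant_id)), call. = FALSE)
  }
  if (1440 %% bin_width != 0) {
    stop("bin_width must divide 1440 minutes", call. = FALSE)
  }
  if (is.null(tz_offset_min)) {
    tz_offset_min <- unique(flows$utc_offset_min)
    if (length(tz_offset_min) > 1) {
      stop("records carry multiple UTC offsets; pass tz_offset_min explicitly",
           call. = FALSE)
    }
  }
  local <- flows$window_start + tz_offset_min * 60
  local_day <- as.Date(local, tz = "UTC")
  day0 <- min(local_day)
  dayn <- max(local_day)
  T_bins <- 1440L %/% as.integer(bin_width)
  secs_into_day <- as.numeric(local) - as.numeric(as.POSIXct(paste(local_day, "00:00:00"), tz = "UTC"))
  bin_idx <- as.integer(secs_into_day %/% (bin_width * 60))

  days <- seq(day0, dayn, by = "day")
  grid <- data.frame(
    day = rep(seq_along(days) - 1L, each = T_bins),
    local_date = rep(days, each = T_bins),
    bin = rep.int(seq_len(T_bins) - 1L, length(days))
  )
  key <- (as.integer(local_day - day0)) * T_bins + bin_idx
  gkey <- grid$day * T_bins + grid$bin
  grid$bytes_up   <- as.numeric(rowsum(flows$bytes_up, key, reorder = TRUE)[
    match(gkey, sort(unique(key)))])
  grid$bytes_down <- as.numeric(rowsum(flows$bytes_down, key, reorder = TRUE)[
    match(gkey, sort(unique(key)))])
  grid$n_records  <- as.integer(rowsum(rep(1L, nrow(flows)), key, reorder = TRUE)[
    match(gkey, sort(unique(key)))])
  grid$bytes_up[is.na(grid$bytes_up)] <- 0
  grid$bytes_down[is.na(grid$bytes_down)] <- 0
  grid$n_records[is.na(grid$n_records)] <- 0L

  structure(grid,
            participant_id = flows$participant_id[1],
            bin_width = as.integer(bin_width),
            tz_offset_min = as.integer(tz_offset_min),
            class = c("binned_series", "data.frame"))
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> participant %s, %d-min bins, %d days, %d bins\n",
              attr(x, "participant_id"), attr(x, "bin_width"),
              length(unique(x$day)), nrow(x)))
  invisible(x)
}

#' Re-bin a series to a coarser width
#'
#' Sums constituent bins; 60-minute bins equal the sum of their six
#' 10-minute constituents.
#'
#' @param series a `binned_series`.
#' @param bin_width target width in minutes (multiple of the current width).
#' @return a `binned_series` at the coarser width.
#' @export
rebin_series <- function(series, bin_width) {
  w0 <- attr(series, "bin_width")
  if (bin_width %% w0 != 0) stop("target width must be a multiple of ", w0, call. = FALSE)
  k <- bin_width %/% w0
  newbin <- series$bin %/% k
  key <- series$day * (1440L %/% as.integer(bin_width)) + newbin
  agg <- rowsum(cbind(series$bytes_up, series$bytes_down, series$n_records), key)
  o <- !duplicated(key)
  out <- data.frame(
    day = series$day[o], local_date = series$local_date[o], bin = newbin[o],
    bytes_up = agg[, 1], bytes_down = agg[, 2], n_records = as.integer(agg[, 3])
  )
  rownames(out) <- NULL
  structure(out,
            participant_id = attr(series, "participant_id"),
            bin_width = as.integer(bin_width),
            tz_offset_min = attr(series, "tz_offset_min"),
            class = c("binned_series", "data.frame"))
}
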
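# Shared fixtures, built in code.

# Hand-built flow_log rows at given local clock times (one participant).
make_flows <- function(times_local, bytes_up = 100, bytes_down = 200,
                       hostname = "push.cdn-edge.net", id = "PX01",
                       offset_min = -300L) {
  utc <- as.POSIXct(times_local, tz = "UTC") - offset_min * 60
  n <- length(utc)
  df <- data.frame(
    participant_id = id, window_start = utc,
    utc_offset_min = offset_min, duration_s = 10,
    hostname = rep_len(hostname, n),
    bytes_up = rep_len(bytes_up, n), bytes_down = rep_len(bytes_down, n),
    packets_up = 1, packets_down = 1, stringsAsFactors = FALSE)
  class(df) <- c("flow_log", "data.frame")
  df
}

# Hourly on/off fixture as a binned_series: one active hour carries bytes.
series_from_hours <- function(active, start_date = as.Date("2025-03-03"),
                              id = "PX01") {
  n <- length(active)
  days <- seq(start_date, by = "day", length.out = ceiling(n / 24))
  grid <- data.frame(
    day = rep(seq_along(days) - 1L, each = 24)[1:n],
    local_date = rep(days, each = 24)[1:n],
    bin = rep(0:23, length.out = n),
    bytes_up = ifelse(active, 1000, 0),
    bytes_down = ifelse(active, 2000, 0),
    n_records = as.integer(active))
  structure(grid, participant_id = id, bin_width = 60L,
            tz_offset_min = -300L,
            class = c("binned_series", "data.frame"))
}

# Independent brute-force percentile oracle: explicit sort + tie groups.
oracle_percentiles <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(v < v[i])
    ties <- sum(v == v[i])
    avg_rank <- below + (1 + ties) / 2
    out[i] <- (avg_rank - 0.5) / n * 100
  }
  out
}

# Small app universe for fast attribution tests.
tiny_apps <- function() {
  list(
    app_spec("com.t.alpha", "AlphaChat", "Social", "alphachat.com",
             c("cdn-edge.net", "app-measurement.com"), 4, 2000),
    app_spec("com.t.beta", "BetaGames", "Games", "betagames.io",
             c("cdn-edge.net", "adservice.net"), 2, 3000),
    app_spec("com.t.gamma", "GammaTV", "Entertainment", "gammatv.net",
             c("app-measurement.com", "adservice.net"), 3, 1500)
  )
}

# One modest simulated cohort shared across test files (built lazily once).
.test_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    .test_cache$cohort <- simulate_cohort(
      cohort_config(n_participants = 4, days = 6, reboot_prob = 0.2, seed = 77))
  }
  .test_cache$cohort
}

# Full-size study-condition cohort: 12 routine + 12 fragmented, 14 days.
study_cohort <- function() {
  if (is.null(.test_cache$study)) {
    .test_cache$study <- simulate_cohort(
      cohort_config(n_participants = 24, days = 14, seed = 20))
  }
  .test_cache$study
}
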
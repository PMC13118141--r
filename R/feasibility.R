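#' Feasibility metrics: coverage, gaps, retention
#'
#' Monitoring feasibility is quantified per participant over their
#' monitoring window (first to last active hour): hour-level coverage
#' (an hour is "active" if at least one byte was observed), valid days
#' (calendar days with at least one active hour), off-gap durations,
#' time-of-day and weekday/weekend stratified coverage, and cohort-level
#' retention proportions with Wilson score intervals plus a percentile
#' bootstrap CI for mean coverage.
#'
#' @name feasibility
NULL

# Hour-level activity vector over the monitoring window (first to last
# active hour inclusive). Returns hour indices relative to the series
# origin and a logical active flag.
hourly_activity <- function(series) {
  if (attr(series, "bin_width") != 60) series <- rebin_series(series, 60)
  total <- series$bytes_up + series$bytes_down
  active <- total > 0
  if (!any(active)) stop("no monitoring window: series has no active hour",
                         call. = FALSE)
  first <- min(which(active)); last <- max(which(active))
  idx <- first:last
  list(series = series[idx, , drop = FALSE], active = active[idx],
       tz_offset_min = attr(series, "tz_offset_min"))
}

#' Hour-level coverage over the monitoring window
#'
#' @param series a `binned_series` (any width; re-binned to 60 min).
#' @return list: `window_start`/`window_end` (local date + hour of first
#'   and last active hour), `window_hours`, `active_hours`,
#'   `coverage_fraction`.
#' @export
hour_coverage <- function(series) {
  h <- hourly_activity(series)
  s <- h$series
  list(
    window_start = sprintf("%s %02d:00", s$local_date[1], s$bin[1]),
    window_end = sprintf("%s %02d:00", s$local_date[nrow(s)], s$bin[nrow(s)]),
    window_hours = nrow(s),
    active_hours = sum(h$active),
    coverage_fraction = sum(h$active) / nrow(s)
  )
}

#' Count valid days
#'
#' A valid day is a local calendar day with at least one active hour.
#'
#' @param series a `binned_series`.
#' @return integer count of valid days.
#' @export
valid_days <- function(series) {
  if (attr(series, "bin_width") != 60) series <- rebin_series(series, 60)
  active <- (series$bytes_up + series$bytes_down) > 0
  length(unique(series$local_date[active]))
}

#' Gap durations inside the monitoring window
#'
#' Maximal runs of consecutive inactive hours strictly inside the window
#' (the window by construction starts and ends on active hours), each in
#' hours. Gaps plus active runs tile the window exactly.
#'
#' @param series a `binned_series`.
#' @return numeric vector of gap lengths (hours); empty if fully active.
#' @export
gap_lengths <- function(series) {
  h <- hourly_activity(series)
  r <- rle(h$active)
  as.numeric(r$lengths[!r$values])
}

#' Default time-of-day and weekly strata
#'
#' Six-hour blocks (half-open, local time): night 00-06, morning 06-12,
#' afternoon 12-18, evening 18-24; plus weekday (Mon-Fri) and weekend
#' (Sat-Sun).
#'
#' @return list with `tod` (data.frame: stratum, start_h, end_h) and
#'   `weekend_days` (weekday names).
#' @export
default_strata <- function() {
  list(
    tod = data.frame(
      stratum = c("night", "morning", "afternoon", "evening"),
      start_h = c(0, 6, 12, 18), end_h = c(6, 12, 18, 24),
      stringsAsFactors = FALSE),
    weekend_days = c("Saturday", "Sunday")
  )
}

#' Stratified coverage
#'
#' Coverage (active / eligible hours) restricted to each time-of-day
#' stratum and to weekday vs weekend hours within the monitoring window.
#' The time-of-day strata must partition the 24-hour day.
#'
#' @param series a `binned_series`.
#' @param strata a strata definition as from [default_strata()].
#' @return named numeric vector of per-stratum coverage fractions (NA for
#'   strata with no eligible hours).
#' @export
stratify_coverage <- function(series, strata = default_strata()) {
  tod <- strata$tod
  hrs <- unlist(Map(seq, tod$start_h, tod$end_h - 1))
  if (length(hrs) != 24 || anyDuplicated(hrs) || !setequal(hrs, 0:23)) {
    stop("time-of-day strata must partition the 24-hour day", call. = FALSE)
  }
  h <- hourly_activity(series)
  s <- h$series
  wd <- weekdays(s$local_date)
  out <- numeric(0)
  for (i in seq_len(nrow(tod))) {
    el <- s$bin >= tod$start_h[i] & s$bin < tod$end_h[i]
    out[tod$stratum[i]] <- if (any(el)) mean(h$active[el]) else NA_real_
  }
  wk <- wd %in% strata$weekend_days
  out["weekday"] <- if (any(!wk)) mean(h$active[!wk]) else NA_real_
  out["weekend"] <- if (any(wk)) mean(h$active[wk]) else NA_real_
  out
}

#' Per-participant coverage summary
#'
#' Convenience wrapper combining window/coverage, valid days, gaps, and
#' strata for one participant's series.
#'
#' @param series a `binned_series`.
#' @param strata strata definition.
#' @return list of class `coverage_summary`.
#' @export
coverage_summary <- function(series, strata = default_strata()) {
  cov <- hour_coverage(series)
  structure(c(list(participant_id = attr(series, "participant_id")),
              cov,
              list(valid_days = valid_days(series),
                   gaps = gap_lengths(series),
                   strata = stratify_coverage(series, strata))),
            class = "coverage_summary")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param trials number of trials (>= 1).
#' @param level confidence level (default 0.95, z = 1.959964).
#' @return named numeric `c(lower, upper)`, both in `[0, 1]`.
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials) {
    stop("successes must lie in [0, trials]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Percentile bootstrap CI for a mean
#'
#' @param values numeric sample (>= 2 values).
#' @param level confidence level.
#' @param reps bootstrap replicates (default 10000).
#' @param seed RNG seed; fixed seed gives a fixed interval.
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_mean_ci <- function(values, level = 0.95, reps = 10000, seed = 1) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (reps < 1000) stop("reps must be >= 1000", call. = FALSE)
  set.seed(seed)
  n <- length(values)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
  means <- rowMeans(matrix(values[idx], nrow = reps))
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Cohort retention summary
#'
#' Retention proportions along the study pipeline with Wilson CIs:
#' participants with at least `threshold_days` valid days among (a) those
#' who contributed any traffic and (b) all consented participants, plus
#' completion (exit interview) among consented.
#'
#' @param valid_day_counts named numeric vector: valid days per
#'   contributing participant.
#' @param pipeline_counts named list/vector of pipeline stage counts;
#'   must include `consented`; optionally `outreach`, `onboarded`,
#'   `exit_survey`, `exit_interview`.
#' @param threshold_days retention threshold (default 5 days).
#' @param level confidence level for Wilson CIs.
#' @return data.frame of class `retention_table`: measure, numerator,
#'   denominator, proportion, Wilson bounds, printed percent
#'   (half-up-rounded).
#' @export
retention_summary <- function(valid_day_counts, pipeline_counts,
                              threshold_days = 5, level = 0.95) {
  contributors <- length(valid_day_counts)
  if (contributors == 0) stop("no contributing participants", call. = FALSE)
  consented <- pipeline_counts[["consented"]]
  if (is.null(consented) || consented < contributors) {
    stop("pipeline_counts$consented missing or fewer than contributors",
         call. = FALSE)
  }
  retained <- sum(valid_day_counts >= threshold_days)
  rows <- list(
    c(measure = sprintf("retention_ge%dd_of_contributors", threshold_days),
      num = retained, den = contributors),
    c(measure = sprintf("retention_ge%dd_of_consented", threshold_days),
      num = retained, den = consented)
  )
  if (!is.null(pipeline_counts[["exit_interview"]])) {
    rows <- c(rows, list(c(measure = "completion_of_consented",
                           num = pipeline_counts[["exit_interview"]],
                           den = consented)))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    num <- as.numeric(r["num"]); den <- as.numeric(r["den"])
    ci <- wilson_interval(num, den, level)
    data.frame(measure = r["measure"], numerator = num, denominator = den,
               proportion = num / den,
               wilson_lower = ci["lower"], wilson_upper = ci["upper"],
               percent = round_half_up(100 * num / den),
               percent_ci_lower = round_half_up(100 * ci["lower"]),
               percent_ci_upper = round_half_up(100 * ci["upper"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("retention_table", "data.frame")
  out
}
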
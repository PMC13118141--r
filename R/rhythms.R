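#' Behavioral rhythm analysis of binned upload traffic
#'
#' Upload volume is treated as a proxy for user-initiated activity. Each
#' local calendar day's 10-minute bins are rank-transformed to empirical
#' percentiles within that day, which removes between-person scale
#' differences (device, habits, throughput) while preserving intraday
#' temporal structure: the transform is invariant to any strictly
#' monotone rescaling of a day's raw volumes. From the resulting
#' days-by-bins profile matrix the package derives day-to-day stability
#' (mean Pearson correlation of consecutive daily profiles), the
#' circadian power ratio (share of non-DC periodogram power at exactly
#' 1 cycle per 24 h), activity onset/offset estimates, sleep-wake
#' contrasts against annotations, and a k-means (k = 2) partition of the
#' cohort in z-scored metric space.
#'
#' @name rhythms
NULL

#' Within-day percentile normalization
#'
#' Each observed bin's value is replaced by `(average rank - 0.5) /
#' n_observed * 100`, ranking with ties averaged over that day's observed
#' bins only. A fully observed constant day maps to all 50s; masked bins
#' stay `NA`.
#'
#' @param day_values numeric vector of raw bin volumes for one day.
#' @param mask logical vector, `TRUE` where the bin is observed (inside
#'   VPN-on coverage). Default: all observed.
#' @return numeric vector of percentiles in `[0, 100]`, `NA` where masked.
#' @export
percentile_normalize_day <- function(day_values, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(day_values))
  stopifnot(length(mask) == length(day_values))
  out <- rep(NA_real_, length(day_values))
  obs <- which(mask & !is.na(day_values))
  if (length(obs) == 0) return(out)
  r <- rank(day_values[obs], ties.method = "average")
  out[obs] <- (r - 0.5) / length(obs) * 100
  out
}

#' Build a daily profile matrix
#'
#' One row per local calendar day, `T = 1440 / bin_width` columns,
#' percentile-normalized within each day independently. The coverage
#' mask marks bins whose containing hour was active (>= 1 byte in the
#' masking series): inactive hours are VPN-off time, not true zeros, and
#' must not enter the rank transform.
#'
#' @param series a `binned_series` at 10-minute width (upload direction
#'   is taken from `bytes_up`; use `direction` to change).
#' @param direction `"up"`, `"down"`, or `"total"`.
#' @param mask_series optional `binned_series` whose hour-level activity
#'   defines coverage (defaults to `series` itself; pass the unfiltered
#'   series when `series` is category-filtered).
#' @return a `daily_profile_matrix`: list with `values` (D x T matrix of
#'   percentiles), `mask` (logical D x T), `raw` (D x T raw volumes),
#'   `dates` (local dates), `participant_id`, `bin_width`,
#'   `usable_days` (logical: any observed bin).
#' @export
build_profile_matrix <- function(series, direction = c("up", "down", "total"),
                                 mask_series = NULL) {
  direction <- match.arg(direction)
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  if (is.null(mask_series)) mask_series <- series
  bw <- attr(series, "bin_width")
  T_bins <- 1440L %/% bw
  vol <- switch(direction, up = series$bytes_up, down = series$bytes_down,
                total = series$bytes_up + series$bytes_down)
  dates <- sort(unique(series$local_date))
  D <- length(dates)
  raw <- matrix(0, D, T_bins)
  raw[cbind(match(series$local_date, dates), series$bin + 1L)] <- vol

  # hour-level activity of the masking series -> bin-level mask
  h <- rebin_series(mask_series, 60)
  h_active <- (h$bytes_up + h$bytes_down) > 0
  mask <- matrix(FALSE, D, T_bins)
  hr_of_bin <- (series$bin * bw) %/% 60
  hkey <- paste(h$local_date, h$bin)
  skey <- paste(series$local_date, hr_of_bin)
  mask[cbind(match(series$local_date, dates), series$bin + 1L)] <-
    h_active[match(skey, hkey)]

  values <- t(vapply(seq_len(D), function(d)
    percentile_normalize_day(raw[d, ], mask[d, ]), numeric(T_bins)))
  structure(list(values = values, mask = mask, raw = raw, dates = dates,
                 participant_id = attr(series, "participant_id"),
                 bin_width = bw,
                 usable_days = rowSums(mask) > 0),
            class = "daily_profile_matrix")
}

#' Construct a daily profile matrix from values
#'
#' Programmatic constructor for analyses that already hold a
#' days-by-bins matrix (e.g. closed-form signals in sensitivity checks).
#'
#' @param values D x T numeric matrix, values in `[0, 100]`.
#' @param mask logical D x T observation mask (default: all observed).
#' @param dates local dates, one per row.
#' @param participant_id id string.
#' @param bin_width bin width in minutes implied by T.
#' @return a `daily_profile_matrix`.
#' @export
daily_profile_matrix <- function(values, mask = NULL, dates = NULL,
                                 participant_id = "synthetic",
                                 bin_width = 1440 / ncol(values)) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  if (is.null(dates)) dates <- as.Date("2025-01-06") + seq_len(nrow(values)) - 1
  stopifnot(all(dim(mask) == dim(values)),
            min(values, na.rm = TRUE) >= 0, max(values, na.rm = TRUE) <= 100)
  structure(list(values = values, mask = mask, raw = values, dates = dates,
                 participant_id = participant_id, bin_width = bin_width,
                 usable_days = rowSums(mask) > 0),
            class = "daily_profile_matrix")
}

#' @export
print.daily_profile_matrix <- function(x, ...) {
  cat(sprintf("<daily_profile_matrix> participant %s: %d days x %d bins, %d usable days\n",
              x$participant_id, nrow(x$values), ncol(x$values),
              sum(x$usable_days)))
  invisible(x)
}

#' Day-to-day stability
#'
#' Mean Pearson correlation between consecutive daily percentile
#' profiles, computed over jointly observed bins. Days observed in fewer
#' than `min_obs_fraction` of bins are dropped; pairs with fewer than 3
#' joint bins or zero variance are skipped.
#'
#' @param profile a `daily_profile_matrix`.
#' @param min_obs_fraction minimum observed-bin fraction for a usable
#'   day (default 0.5).
#' @return list: `stability` (mean r, NA if undefined), `n_pairs`,
#'   `n_days_used`.
#' @export
day_to_day_stability <- function(profile, min_obs_fraction = 0.5) {
  ok <- rowMeans(profile$mask) >= min_obs_fraction
  idx <- which(ok)
  if (length(idx) < 2) {
    return(list(stability = NA_real_, n_pairs = 0L, n_days_used = length(idx)))
  }
  cors <- c()
  for (j in seq_len(length(idx) - 1)) {
    d1 <- idx[j]; d2 <- idx[j + 1]
    if (d2 - d1 != 1) next                       # only consecutive calendar days
    joint <- profile$mask[d1, ] & profile$mask[d2, ]
    if (sum(joint) < 3) next
    a <- profile$values[d1, joint]; b <- profile$values[d2, joint]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cors <- c(cors, stats::cor(a, b))
  }
  list(stability = if (length(cors)) mean(cors) else NA_real_,
       n_pairs = length(cors), n_days_used = length(idx))
}

#' Circadian power ratio
#'
#' Periodogram of the concatenated multi-day percentile series
#' (whole days only; masked bins imputed at the within-day neutral
#' percentile 50, then the series is mean-centered). The ratio is the
#' power at exactly 1 cycle per 24 hours (optionally +/- `halfwidth`
#' neighboring Fourier frequencies) divided by total non-DC power. With
#' D whole days of T bins, 1 cycle/day is Fourier index D.
#'
#' @param profile a `daily_profile_matrix` with >= 2 days.
#' @param halfwidth number of neighboring Fourier bins on each side to
#'   include as "24-hour" power (default 0: the single exact frequency).
#' @return list: `ratio` in `[0, 1]`, `n_days`, `power_24h`,
#'   `total_power`.
#' @export
circadian_power_ratio <- function(profile, halfwidth = 0) {
  D <- nrow(profile$values)
  if (D < 2) stop("need >= 2 whole days for a 24-h spectral estimate",
                  call. = FALSE)
  T_bins <- ncol(profile$values)
  x <- as.vector(t(profile$values))
  x[is.na(x)] <- 50
  x <- x - mean(x)
  N <- length(x)
  f <- stats::fft(x)
  pow <- Mod(f)^2 / N
  # one-sided: indices 2..floor(N/2)+1 in R (index 1 is DC)
  half <- floor(N / 2)
  k24 <- D                                       # 1 cycle/day
  sel <- pmax(1, k24 - halfwidth):pmin(half, k24 + halfwidth)
  p24 <- sum(pow[sel + 1])
  total <- sum(pow[2:(half + 1)])
  list(ratio = if (total > 0) p24 / total else NA_real_,
       n_days = D, power_24h = p24, total_power = total)
}

#' Per-participant rhythm metrics
#'
#' @param profile a `daily_profile_matrix`.
#' @param min_obs_fraction usable-day threshold for stability.
#' @param halfwidth see [circadian_power_ratio()].
#' @return data.frame row: participant_id, stability,
#'   circadian_power_ratio, n_days_used.
#' @export
rhythm_metrics <- function(profile, min_obs_fraction = 0.5, halfwidth = 0) {
  st <- day_to_day_stability(profile, min_obs_fraction)
  cp <- tryCatch(circadian_power_ratio(profile, halfwidth),
                 error = function(e) list(ratio = NA_real_, n_days = nrow(profile$values)))
  data.frame(participant_id = profile$participant_id,
             stability = st$stability,
             circadian_power_ratio = cp$ratio,
             n_days_used = st$n_days_used,
             stringsAsFactors = FALSE)
}

#' Cluster participants in rhythm-metric space
#'
#' z-scores each metric, then k-means with k = 2 (k-means++-style
#' multi-start via `nstart`, seeded). Labels are oriented so cluster 0
#' has the higher mean stability ("more routine"). Zero-variance
#' features are dropped with a warning; participants with missing
#' metrics are excluded.
#'
#' @param metrics data.frame from [rhythm_metrics()] rows.
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 50).
#' @return data.frame: participant_id, cluster (0 = more routine),
#'   z-scored features; attribute `centers` (in z space).
#' @export
cluster_rhythms <- function(metrics, seed = 1, nstart = 50) {
  feat_cols <- c("stability", "circadian_power_ratio")
  ok <- stats::complete.cases(metrics[feat_cols])
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) < 2) stop("need >= 2 participants with defined metrics",
                        call. = FALSE)
  X <- as.matrix(m[feat_cols])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance feature(s) dropped: ",
            paste(feat_cols[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) stop("all features have zero variance", call. = FALSE)
  }
  Z <- scale(X)
  set.seed(seed)
  km <- stats::kmeans(Z, centers = 2, nstart = nstart)
  # orient: cluster 0 = higher mean stability (fall back to first feature)
  ref <- if ("stability" %in% colnames(X)) m$stability else X[, 1]
  mean1 <- mean(ref[km$cluster == 1]); mean2 <- mean(ref[km$cluster == 2])
  lab <- if (mean1 >= mean2) c(0L, 1L) else c(1L, 0L)
  out <- data.frame(participant_id = m$participant_id,
                    cluster = lab[km$cluster],
                    stringsAsFactors = FALSE)
  zdf <- as.data.frame(Z)
  names(zdf) <- paste0("z_", colnames(X))
  out <- cbind(out, zdf)
  rownames(out) <- NULL
  attr(out, "centers") <- km$centers[order(lab), , drop = FALSE]
  out
}

#' Radial-grid representation of a profile matrix
#'
#' Long-format polar mapping for radial heatmaps: bin t at angle
#' `360 * t / T` degrees (midnight at 0, clockwise), day d on ring d;
#' night flag covers 20:00-08:00 local; weekend flag from the local
#' calendar.
#'
#' @param profile a `daily_profile_matrix`.
#' @return data.frame: participant_id, day, date, bin, angle_deg, value,
#'   observed, night, weekend.
#' @export
radial_grid <- function(profile) {
  D <- nrow(profile$values); T_bins <- ncol(profile$values)
  bw_h <- 24 / T_bins
  grid <- expand.grid(bin = 0:(T_bins - 1), day = 0:(D - 1))
  hour <- grid$bin * bw_h
  data.frame(
    participant_id = profile$participant_id,
    day = grid$day,
    date = profile$dates[grid$day + 1],
    bin = grid$bin,
    angle_deg = 360 * grid$bin / T_bins,
    value = profile$values[cbind(grid$day + 1, grid$bin + 1)],
    observed = profile$mask[cbind(grid$day + 1, grid$bin + 1)],
    night = hour >= 20 | hour < 8,
    weekend = weekdays(profile$dates[grid$day + 1]) %in% c("Saturday", "Sunday"),
    stringsAsFactors = FALSE
  )
}

#' Activity onset and offset for one day
#'
#' Onset is the start of the first run of at least `min_run` bins above
#' the threshold percentile; offset is the end of the last such run.
#' Times are hours from local midnight.
#'
#' @param day_percentiles one row of a profile matrix (percentiles, NA
#'   where masked).
#' @param threshold percentile threshold (default 60).
#' @param min_run minimum run length in bins (default 3, i.e. 30 min at
#'   10-min bins).
#' @param bin_width bin width in minutes.
#' @return list `onset_h`, `offset_h` (NA if no qualifying run).
#' @export
onset_offset <- function(day_percentiles, threshold = 60, min_run = 3,
                         bin_width = 10) {
  above <- !is.na(day_percentiles) & day_percentiles > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  q <- which(r$values & r$lengths >= min_run)
  if (length(q) == 0) return(list(onset_h = NA_real_, offset_h = NA_real_))
  list(onset_h = (starts[q[1]] - 1) * bin_width / 60,
       offset_h = ends[q[length(q)]] * bin_width / 60)
}

#' Sleep-wake contrast of percentile profiles
#'
#' Mean percentile over sleep-annotated vs wake observed bins and their
#' difference (wake minus sleep; positive = lower upload activity during
#' sleep).
#'
#' @param profile a `daily_profile_matrix`.
#' @param sleep_intervals data.frame (`start_s`, `end_s`): sleep episodes
#'   in seconds from local midnight of the first profile day.
#' @return list: `sleep_mean`, `wake_mean`, `difference`, `n_sleep_bins`,
#'   `n_wake_bins`.
#' @export
sleep_wake_contrast <- function(profile, sleep_intervals) {
  D <- nrow(profile$values); T_bins <- ncol(profile$values)
  bin_s <- 86400 / T_bins
  start_s <- (rep(0:(D - 1), each = T_bins) * 86400 +
                rep(0:(T_bins - 1), D) * bin_s)
  asleep <- rep(FALSE, length(start_s))
  for (i in seq_len(nrow(sleep_intervals))) {
    asleep <- asleep | (start_s >= sleep_intervals$start_s[i] &
                          start_s < sleep_intervals$end_s[i])
  }
  vals <- as.vector(t(profile$values))
  obs <- !is.na(vals)
  if (!any(obs & asleep) || !any(obs & !asleep)) {
    stop("sleep annotations do not overlap observed bins", call. = FALSE)
  }
  sm <- mean(vals[obs & asleep]); wm <- mean(vals[obs & !asleep])
  list(sleep_mean = sm, wake_mean = wm, difference = wm - sm,
       n_sleep_bins = sum(obs & asleep), n_wake_bins = sum(obs & !asleep))
}
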
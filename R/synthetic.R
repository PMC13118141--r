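#' Synthetic cohort generation
#'
#' Generates flow-metadata logs with the statistical structure the
#' downstream analyses assume: diurnal upload intensity with
#' person-specific phase and regularity, low-level always-on background
#' traffic, app sessions contacting both app-unique and shared
#' infrastructure domains, VPN off-gaps (reboots, deliberate disabling),
#' staggered onboarding, and annotated sleep intervals. Every generator
#' returns ground truth alongside the data, so parameter-recovery and
#' precision properties are testable end to end.
#'
#' @name synthetic_data
NULL

#' Define an app for simulation
#'
#' @param bundle_id reverse-DNS style id, unique in the app universe.
#' @param name display name.
#' @param genre primary genre (e.g. "Social", "Games").
#' @param unique_domains registered domains used by this app only;
#'   must be disjoint across the app universe.
#' @param shared_domains infrastructure domains drawn from a pool shared
#'   with other apps (CDNs, analytics, OS services).
#' @param session_rate expected user sessions per day.
#' @param session_upload_scale typical upload bytes per 10-s session window.
#' @param deep_domains extra app-unique domains that surface only under
#'   sustained, authenticated ("deep-state") use.
#' @return an `app_spec` list.
#' @export
app_spec <- function(bundle_id, name, genre, unique_domains,
                     shared_domains, session_rate = 2,
                     session_upload_scale = 4000, deep_domains = character()) {
  stopifnot(nzchar(bundle_id), nzchar(name), length(unique_domains) >= 1)
  structure(list(bundle_id = bundle_id, name = name, genre = genre,
                 unique_domains = unique_domains,
                 shared_domains = shared_domains,
                 session_rate = session_rate,
                 session_upload_scale = session_upload_scale,
                 deep_domains = deep_domains),
            class = "app_spec")
}

# Shared infrastructure pool: every domain here is contacted by at least
# two apps, so global disambiguation must exclude all of them.
SHARED_POOL <- c("cdn-edge.net", "app-measurement.com", "analytics-hub.com",
                 "cloudstore.net", "pushgateway.io", "adservice.net",
                 "os-infra.example", "fastcache.io")

#' Default simulated app universe
#'
#' Twelve apps across the genres the study's category analysis uses.
#' Most apps have name-derived unique domains (semantically
#' identifiable); a few use opaque backend domains, so identifiability
#' from domain tokens alone is deliberately imperfect, as it is for real
#' App Privacy Report corpora.
#'
#' @return list of `app_spec`.
#' @export
default_apps <- function() {
  mk <- function(id, name, genre, uniq, shared_idx, rate, scale,
                 deep = character())
    app_spec(paste0("com.sim.", id), name, genre, uniq,
             SHARED_POOL[shared_idx], rate, scale, deep)
  list(
    mk("chatter",    "Chatter",       "Social",         c("chatter.com", "chatter-img.com"), c(1, 2, 6), 15,   3000, "chatter-auth.com"),
    mk("snapshare",  "SnapShare",     "Social",         "snapshare.com",                      c(1, 3, 5), 12,   5000),
    mk("streamflix", "StreamFlix",    "Entertainment",  c("streamflix.com", "streamflix-cdn.net"), c(1, 2, 4), 6, 1500),
    mk("tubewatch",  "TubeWatch",     "Entertainment",  "tubewatch.com",                      c(1, 4, 6), 8,   2000, "tubewatch-live.net"),
    mk("puzzle",     "PuzzleQuest",   "Games",          "puzzlequest.com",                    c(2, 5),    4,   1200),
    mk("nraid",      "NightRaid",     "Games",          "nr-gamenet.io",                      c(2, 6),    4,   2500),
    mk("fooddash",   "FoodDash",      "Food & Drink",   "fooddash.com",                       c(3, 6),    2,   2200),
    mk("mbites",     "MidnightBites", "Food & Drink",   "mb-delivery.net",                    c(3, 5),    1, 2200),
    mk("mailpro",    "MailPro",       "Business",       "mailpro.com",                        c(4, 7),    10,   1800),
    mk("campus",     "CampusLearn",   "Education",      "campuslearn.com",                    c(4, 7),    3, 1000),
    mk("fittrack",   "FitTrack",      "Health & Fitness", "fittrack.com",                     c(5, 8),    4,    900),
    mk("wxnow",      "WeatherNow",    "Weather",        "wx-datafeed.net",                    c(7, 8),    6,    400)
  )
}

#' Behavioral phenotype configuration
#'
#' Two canonical phenotypes drive the cohort: `routine` participants keep
#' a regular sleep schedule (small day-to-day jitter, near-zero night
#' activity, strongly peaked daytime usage), `fragmented` participants
#' have irregular schedules (large jitter, frequent night-activity
#' episodes, flatter daytime shape).
#'
#' @param label `"routine"` or `"fragmented"`.
#' @param sleep_onset_min,sleep_offset_min sleep episode bounds, minutes
#'   after local midnight (onset < offset: episode within one day).
#' @param sleep_jitter_sd day-to-day SD of onset/offset, minutes.
#' @param day_amplitude amplitude of the raised-cosine daytime usage
#'   shape (0 = flat, 1 = strongly peaked mid-afternoon).
#' @param night_activity_prob probability per night of a mid-sleep
#'   activity episode (30-90 min).
#' @param background_prob per-10-s Bernoulli probability of a background
#'   keep-alive flow while the VPN is on.
#' @param sleep_rate_fraction session intensity during sleep relative to
#'   wake (default 0.1: sleeping phones emit a tenth the upload sessions).
#' @param wake_burst_prob probability per day of a phone-check burst right
#'   at sleep offset (notification catch-up on waking).
#' @param app_weights session-mix weights over the app universe; recycled
#'   and normalized to sum to 1.
#' @return a `phenotype_config` list.
#' @export
phenotype_config <- function(label = c("routine", "fragmented"),
                             sleep_onset_min = if (label == "routine") 60 else 150,
                             sleep_offset_min = if (label == "routine") 480 else 600,
                             sleep_jitter_sd = if (label == "routine") 20 else 150,
                             day_amplitude = if (label == "routine") 0.9 else 0.2,
                             night_activity_prob = if (label == "routine") 0.02 else 0.5,
                             background_prob = 0.04,
                             sleep_rate_fraction = 0.1,
                             wake_burst_prob = 0.85,
                             app_weights = NULL) {
  label <- match.arg(label)
  structure(list(label = label,
                 sleep_onset_min = sleep_onset_min,
                 sleep_offset_min = sleep_offset_min,
                 sleep_jitter_sd = sleep_jitter_sd,
                 day_amplitude = day_amplitude,
                 night_activity_prob = night_activity_prob,
                 background_prob = background_prob,
                 sleep_rate_fraction = sleep_rate_fraction,
                 wake_burst_prob = wake_burst_prob,
                 app_weights = app_weights),
            class = "phenotype_config")
}

#' Cohort-level simulation configuration
#'
#' @param n_participants cohort size.
#' @param days monitored days per participant.
#' @param stagger_days onboarding staggered uniformly over this many days.
#' @param reboot_prob per-day probability of a VPN-off lapse (reboot or
#'   manual disable).
#' @param reactivation_median_h median off-gap duration, hours; gaps are
#'   lognormal (short gaps common, rare multi-day lapses).
#' @param reactivation_sdlog lognormal sigma of gap durations.
#' @param forced_off_h optional list (by participant index) of
#'   data.frames with columns `start_h`, `end_h`: deliberate off
#'   intervals in hours from that participant's local start midnight.
#' @param tz_offset_min fixed local UTC offset, minutes (single value or
#'   per participant).
#' @param start_date first possible onboarding date (local).
#' @param seed master seed; fixed seed gives bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 24, days = 14, stagger_days = 7,
                          reboot_prob = 0.15, reactivation_median_h = 2,
                          reactivation_sdlog = 1.2, forced_off_h = NULL,
                          tz_offset_min = -300, start_date = as.Date("2025-03-03"),
                          seed = 1) {
  stopifnot(n_participants >= 1, days >= 1)
  structure(list(n_participants = n_participants, days = days,
                 stagger_days = stagger_days, reboot_prob = reboot_prob,
                 reactivation_median_h = reactivation_median_h,
                 reactivation_sdlog = reactivation_sdlog,
                 forced_off_h = forced_off_h,
                 tz_offset_min = tz_offset_min, start_date = start_date,
                 seed = seed),
            class = "cohort_config")
}

# Merge overlapping/adjacent [start, end) intervals given as a 2-col matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Simulate one participant's flow log
#'
#' Emits background keep-alive flows (Bernoulli per 10-s window,
#' lognormal bytes) in every VPN-on window, and app sessions (Poisson
#' counts, bursty runs of 10-s windows) whose start times follow the
#' phenotype's diurnal intensity: down-weighted during the night's sleep
#' episode by `sleep_rate_fraction` and shaped by a raised-cosine daytime
#' profile. Session flows target a mix of the app's unique and shared
#' domains, so attribution has both signal and ambiguity to work with.
#' No flow is emitted inside a VPN-off interval.
#'
#' @param phenotype a [phenotype_config()].
#' @param days number of monitored days.
#' @param apps app universe (list of [app_spec()]).
#' @param seed RNG seed.
#' @param participant_id id string stamped on the records.
#' @param start_date local calendar date of day 0.
#' @param tz_offset_min fixed local UTC offset in minutes.
#' @param reboot_prob per-day probability of an off-gap.
#' @param reactivation_median_h,reactivation_sdlog lognormal off-gap
#'   duration parameters (hours).
#' @param forced_off_h optional data.frame (`start_h`, `end_h`) of
#'   deliberate off intervals, hours from local start midnight.
#' @return list with `flows` (a `flow_log`) and `truth` (sleep intervals,
#'   sessions, VPN-off intervals, phenotype label).
#' @export
simulate_participant <- function(phenotype, days, apps, seed,
                                 participant_id = "P001",
                                 start_date = as.Date("2025-03-03"),
                                 tz_offset_min = -300,
                                 reboot_prob = 0, reactivation_median_h = 2,
                                 reactivation_sdlog = 1.2,
                                 forced_off_h = NULL) {
  if (length(apps) == 0) stop("empty app set", call. = FALSE)
  stopifnot(days >= 1)
  set.seed(seed)
  n_win <- days * 8640L                     # 10-s windows
  win_start_s <- (seq_len(n_win) - 1) * 10  # seconds from local midnight day 0
  horizon_s <- days * 86400

  ## --- sleep episodes (one per night, jittered) ---
  onset <- pmax(0, phenotype$sleep_onset_min +
                  stats::rnorm(days, 0, phenotype$sleep_jitter_sd))
  offset <- pmin(1439, pmax(onset + 60, phenotype$sleep_offset_min +
                              stats::rnorm(days, 0, phenotype$sleep_jitter_sd)))
  sleep_iv <- cbind((seq_len(days) - 1) * 86400 + onset * 60,
                    (seq_len(days) - 1) * 86400 + offset * 60)

  ## night-activity episodes punch wake holes into the sleep mask
  night_ep <- which(stats::runif(days) < phenotype$night_activity_prob)
  wake_holes <- NULL
  for (d in night_ep) {
    span <- sleep_iv[d, 2] - sleep_iv[d, 1]
    dur <- stats::runif(1, 30, 90) * 60
    s0 <- sleep_iv[d, 1] + stats::runif(1, 0.2, 0.7) * span
    wake_holes <- rbind(wake_holes, c(s0, min(s0 + dur, sleep_iv[d, 2])))
  }

  in_iv <- function(t, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(t)))
    res <- rep(FALSE, length(t))
    for (i in seq_len(nrow(iv))) res <- res | (t >= iv[i, 1] & t < iv[i, 2])
    res
  }
  asleep <- in_iv(win_start_s, sleep_iv) & !in_iv(win_start_s, wake_holes)

  ## --- VPN-off intervals ---
  off_iv <- NULL
  reboot_days <- which(stats::runif(days) < reboot_prob)
  for (d in reboot_days) {
    s0 <- (d - 1) * 86400 + stats::runif(1, 0, 86400)
    dur <- stats::rlnorm(1, log(reactivation_median_h), reactivation_sdlog) * 3600
    off_iv <- rbind(off_iv, c(s0, min(s0 + dur, horizon_s)))
  }
  if (!is.null(forced_off_h) && nrow(forced_off_h) > 0) {
    off_iv <- rbind(off_iv, cbind(forced_off_h$start_h * 3600,
                                  pmin(forced_off_h$end_h * 3600, horizon_s)))
  }
  off_iv <- merge_intervals(off_iv)
  vpn_on <- !in_iv(win_start_s, off_iv)

  ## --- background keep-alives ---
  bg_idx <- which(stats::runif(n_win) < phenotype$background_prob & vpn_on)
  # keep-alives never stop, but push/refresh volume drops while the user
  # sleeps (app refresh, notification fan-out follow use)
  bg_vol_scale <- ifelse(asleep[bg_idx], 0.5, 1)
  bg <- data.frame(
    win = bg_idx,
    hostname = paste0(c("push.", "api.", "metrics.")[1 + bg_idx %% 3],
                      sample(SHARED_POOL, length(bg_idx), replace = TRUE)),
    bytes_up = round(bg_vol_scale * stats::rlnorm(length(bg_idx), log(120), 0.8)),
    bytes_down = round(bg_vol_scale * stats::rlnorm(length(bg_idx), log(800), 0.8)),
    app = NA_character_, stringsAsFactors = FALSE
  )

  ## --- app sessions ---
  w <- phenotype$app_weights
  if (is.null(w)) w <- vapply(apps, function(a) a$session_rate, numeric(1))
  w <- rep_len(w, length(apps)); w <- w / sum(w)
  total_rate <- sum(vapply(apps, function(a) a$session_rate, numeric(1)))

  # diurnal session-start intensity: sleep down-weighted, daytime shaped
  # by a raised cosine peaking at 15:00 local
  tod_h <- (win_start_s %% 86400) / 3600
  shape <- 1 + phenotype$day_amplitude * cos((tod_h - 15) / 24 * 2 * pi)
  lambda <- shape * ifelse(asleep, phenotype$sleep_rate_fraction, 1) * vpn_on
  n_sessions <- stats::rpois(1, total_rate * days)
  sess_rows <- NULL
  truth_sessions <- NULL
  if (n_sessions > 0 && sum(lambda) > 0) {
    app_of <- sample(seq_along(apps), n_sessions, replace = TRUE, prob = w)
    start_win <- sample(n_win, n_sessions, replace = TRUE, prob = lambda)
    dur_win <- pmax(3L, stats::rpois(n_sessions, 18L))    # ~3 min typical
    sr <- vector("list", n_sessions)
    ts <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      a <- apps[[app_of[s]]]
      wins <- start_win[s]:min(start_win[s] + dur_win[s] - 1L, n_win)
      wins <- wins[vpn_on[wins]]
      if (length(wins) == 0) next
      to_unique <- stats::runif(length(wins)) < 0.5
      host <- character(length(wins))
      host[to_unique] <- paste0(sample(c("", "api.", "cdn.", "img."),
                                       sum(to_unique), replace = TRUE),
                                sample(a$unique_domains, sum(to_unique), replace = TRUE))
      host[!to_unique] <- sample(a$shared_domains, sum(!to_unique), replace = TRUE)
      up <- round(stats::rlnorm(length(wins), log(a$session_upload_scale), 0.9))
      dn <- round(stats::rlnorm(length(wins), log(a$session_upload_scale * 4), 0.9))
      sr[[s]] <- data.frame(
        win = wins, hostname = host, bytes_up = up, bytes_down = dn,
        app = a$bundle_id, stringsAsFactors = FALSE)
      ts[[s]] <- data.frame(
        app = a$bundle_id,
        start_s = (wins[1] - 1) * 10, end_s = utils::tail(wins, 1) * 10,
        bytes_up = sum(up), stringsAsFactors = FALSE)
    }
    sess_rows <- do.call(rbind, sr)
    truth_sessions <- do.call(rbind, ts)
  }

  ## wake-time phone-check burst: notification catch-up right at sleep offset
  wb <- vector("list", days)
  for (d in seq_len(days)) {
    if (stats::runif(1) >= phenotype$wake_burst_prob) next
    w0 <- as.integer(sleep_iv[d, 2] %/% 10) + 1L + sample(0:30, 1)  # <=5 min delay
    wins <- w0:min(w0 + 30L + stats::rpois(1, 150L), n_win)  # 20-40 min scroll
    wins <- wins[wins >= 1 & vpn_on[wins]]
    if (length(wins) == 0) next
    a <- apps[[sample(seq_along(apps), 1, prob = w)]]
    to_unique <- stats::runif(length(wins)) < 0.5
    host <- character(length(wins))
    host[to_unique] <- sample(a$unique_domains, sum(to_unique), replace = TRUE)
    host[!to_unique] <- sample(a$shared_domains, sum(!to_unique), replace = TRUE)
    up <- round(stats::rlnorm(length(wins), log(a$session_upload_scale), 0.9))
    dn <- round(stats::rlnorm(length(wins), log(a$session_upload_scale * 4), 0.9))
    wb[[d]] <- data.frame(win = wins, hostname = host, bytes_up = up,
                          bytes_down = dn, app = a$bundle_id,
                          stringsAsFactors = FALSE)
    truth_sessions <- rbind(truth_sessions, data.frame(
      app = a$bundle_id, start_s = (wins[1] - 1) * 10,
      end_s = utils::tail(wins, 1) * 10, bytes_up = sum(up),
      stringsAsFactors = FALSE))
  }
  sess_rows <- rbind(sess_rows, do.call(rbind, wb))

  all_rows <- rbind(bg, sess_rows)
  all_rows <- all_rows[order(all_rows$win), , drop = FALSE]

  midnight0_utc <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") -
    tz_offset_min * 60
  flows <- data.frame(
    participant_id = participant_id,
    window_start = midnight0_utc + (all_rows$win - 1) * 10,
    utc_offset_min = as.integer(tz_offset_min),
    duration_s = 10,
    hostname = all_rows$hostname,
    bytes_up = as.numeric(all_rows$bytes_up),
    bytes_down = as.numeric(all_rows$bytes_down),
    packets_up = pmax(1, round(all_rows$bytes_up / 1200)),
    packets_down = pmax(1, round(all_rows$bytes_down / 1200)),
    stringsAsFactors = FALSE
  )
  rownames(flows) <- NULL
  class(flows) <- c("flow_log", "data.frame")

  to_time <- function(s) midnight0_utc + s
  truth <- list(
    participant_id = participant_id,
    phenotype = phenotype$label,
    start_date = start_date,
    tz_offset_min = as.integer(tz_offset_min),
    days = days,
    sleep_intervals = data.frame(start_s = sleep_iv[, 1], end_s = sleep_iv[, 2]),
    wake_holes = if (is.null(wake_holes)) NULL else
      data.frame(start_s = wake_holes[, 1], end_s = wake_holes[, 2]),
    vpn_off = if (is.null(off_iv)) data.frame(start_s = numeric(0), end_s = numeric(0))
      else data.frame(start_s = off_iv[, 1], end_s = off_iv[, 2]),
    sessions = truth_sessions,
    flows_app = all_rows$app   # per-flow true app (NA for background), row-aligned with flows
  )
  list(flows = flows, truth = truth)
}

#' Simulate a cohort
#'
#' Runs [simulate_participant()] for a staggered cohort split between the
#' supplied phenotypes (alternating assignment by default), with opaque
#' participant ids and a manifest linking ids to ground truth.
#'
#' @param config a [cohort_config()].
#' @param phenotypes list of [phenotype_config()] recycled over
#'   participants (default one routine, one fragmented, alternating).
#' @param apps app universe.
#' @return list with `flows` (cohort `flow_log`), `truth` (per-id list),
#'   and `manifest` (data.frame: id, phenotype, start date, days).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            phenotypes = list(phenotype_config("routine"),
                                              phenotype_config("fragmented")),
                            apps = default_apps()) {
  n <- config$n_participants
  set.seed(config$seed)
  starts <- config$start_date + (seq_len(n) - 1) %% max(1, config$stagger_days)
  ids <- sprintf("P%03d", seq_len(n))
  tz <- rep_len(config$tz_offset_min, n)
  flows_list <- vector("list", n)
  truth <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    ph <- phenotypes[[(i - 1) %% length(phenotypes) + 1]]
    fo <- if (!is.null(config$forced_off_h) && length(config$forced_off_h) >= i)
      config$forced_off_h[[i]] else NULL
    res <- simulate_participant(
      ph, config$days, apps, seed = derive_seed(config$seed, i),
      participant_id = ids[i], start_date = starts[i], tz_offset_min = tz[i],
      reboot_prob = config$reboot_prob,
      reactivation_median_h = config$reactivation_median_h,
      reactivation_sdlog = config$reactivation_sdlog,
      forced_off_h = fo)
    flows_list[[i]] <- res$flows
    truth[[ids[i]]] <- res$truth
  }
  flows <- do.call(rbind, flows_list)
  rownames(flows) <- NULL
  class(flows) <- c("flow_log", "data.frame")
  manifest <- data.frame(
    participant_id = ids,
    phenotype = vapply(truth, function(t) t$phenotype, character(1)),
    start_date = as.character(starts),
    days = config$days,
    stringsAsFactors = FALSE
  )
  rownames(manifest) <- NULL
  list(flows = flows, truth = truth, manifest = manifest)
}

#' Emit App Privacy Report style app-to-domain reports
#'
#' Scripted mode mimics brief controlled app launches: each app's unique
#' domains plus a subset of its shared infrastructure. Participant
#' ("deep-state") mode mimics sustained naturalistic use: the same
#' app-identifying domains, more shared/infrastructure domains, and only
#' rarely a genuinely new app-unique domain -- sustained use mostly
#' surfaces more shared infrastructure, not more app-specific signal.
#'
#' @param apps app universe.
#' @param mode `"scripted"` or `"participant"`.
#' @param seed RNG seed.
#' @param shared_frac fraction of each app's shared domains included
#'   (scripted default 0.6; participant uses `min(1, shared_frac + 0.4)`).
#' @param extra_unique_prob per-app probability that participant mode
#'   reveals a deep-state-only unique domain.
#' @return an `apr_report`: list with `source` and `entries` (per app:
#'   `bundle_id`, `name`, `domains`).
#' @export
emit_apr_reports <- function(apps, mode = c("scripted", "participant"),
                             seed = 1, shared_frac = 0.6,
                             extra_unique_prob = 0.05) {
  mode <- match.arg(mode)
  set.seed(derive_seed(seed, if (mode == "scripted") 101 else 102))
  if (length(apps) == 0) {
    return(structure(list(source = mode, entries = list()), class = "apr_report"))
  }
  frac <- if (mode == "scripted") shared_frac else min(1, shared_frac + 0.4)
  entries <- lapply(apps, function(a) {
    shared_n <- max(1, round(frac * length(a$shared_domains)))
    shared <- sample(a$shared_domains, min(shared_n, length(a$shared_domains)))
    doms <- c(a$unique_domains,
              paste0("api.", a$unique_domains[1]),   # subdomained variants
              shared)
    if (mode == "participant") {
      doms <- c(doms, paste0("cdn.", shared))
      if (length(a$deep_domains) > 0 && stats::runif(1) < extra_unique_prob) {
        doms <- c(doms, a$deep_domains)
      }
    }
    list(bundle_id = a$bundle_id, name = a$name, domains = unique(doms))
  })
  structure(list(source = mode, entries = entries), class = "apr_report")
}

#' Write an APR-style report to JSON
#' @param report an `apr_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_apr_report <- function(report, path) {
  jsonlite::write_json(list(source = report$source, entries = report$entries),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an APR-style JSON report
#' @param path JSON file with `source` and `entries`.
#' @return an `apr_report`.
#' @export
read_apr_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(source = obj$source, entries = obj$entries),
            class = "apr_report")
}

#' Emit the app-to-category map
#'
#' One row per app: bundle id, display name, primary genre. Stands in for
#' a store-metadata lookup; static so runs are deterministic and offline.
#'
#' @param apps app universe.
#' @param path optional CSV output path.
#' @return data.frame with `bundle_id`, `app_name`, `genre`.
#' @export
emit_category_map <- function(apps, path = NULL) {
  ids <- vapply(apps, function(a) a$bundle_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate bundle_id in app universe: ", ids[anyDuplicated(ids)],
         call. = FALSE)
  }
  df <- data.frame(
    bundle_id = ids,
    app_name = vapply(apps, function(a) a$name, character(1)),
    genre = vapply(apps, function(a) a$genre, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Read an app-to-category CSV
#' @param path CSV with columns `bundle_id`, `app_name`, `genre`.
#' @return data.frame category map.
#' @export
read_category_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bundle_id", "app_name", "genre")
  if (!all(req %in% names(df))) {
    stop("category map must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df[req]
}
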
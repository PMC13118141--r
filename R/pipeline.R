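#' End-to-end pipeline orchestration
#'
#' Runs simulate -> feasibility -> attribute -> rhythms in dependency
#' order against either a simulated scenario or input files, writes all
#' stage outputs under one directory, and records a JSON manifest with
#' content hashes so seeded reruns are verifiable byte-for-byte.
#'
#' @name cli_report
NULL

#' Pipeline configuration
#'
#' @param flow_log path to an existing flow log, or `NULL` to simulate.
#' @param simulate a [cohort_config()] used when `flow_log` is `NULL`.
#' @param out_dir output directory.
#' @param bin_width rhythm bin width, minutes.
#' @param threshold_days retention threshold.
#' @param bootstrap_reps bootstrap replicates for mean-coverage CI.
#' @param min_obs_fraction usable-day threshold for stability.
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(flow_log = NULL, simulate = cohort_config(),
                            out_dir = tempfile("netrhythm_run_"),
                            bin_width = 10, threshold_days = 5,
                            bootstrap_reps = 10000, min_obs_fraction = 0.5,
                            seed = 1) {
  if (!is.null(flow_log) && !file.exists(flow_log)) {
    stop("flow_log does not exist: ", flow_log, call. = FALSE)
  }
  structure(list(flow_log = flow_log, simulate = simulate, out_dir = out_dir,
                 bin_width = bin_width, threshold_days = threshold_days,
                 bootstrap_reps = bootstrap_reps,
                 min_obs_fraction = min_obs_fraction, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: (1) obtain flows (read or simulate, with APR reports and a
#' category map when simulating); (2) per-participant coverage summary
#' CSV; (3) attribution via the unique-domain map, coverage statistics;
#' (4) rhythm metrics and k-means cluster CSVs; (5) cohort report (JSON
#' and text). Every output file is listed in `manifest.json` with its
#' MD5 hash.
#'
#' @param config a [pipeline_config()].
#' @return list: `manifest` (data.frame file/hash), `paths`, plus the
#'   in-memory stage results (`coverage`, `retention`, `attribution`,
#'   `metrics`, `clusters`, `report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  ## stage 1: inputs
  if (is.null(config$flow_log)) {
    message("stage simulate: generating cohort")
    sim <- simulate_cohort(config$simulate)
    flows <- sim$flows
    apps <- default_apps()
    reports <- list(emit_apr_reports(apps, "scripted", seed = config$seed),
                    emit_apr_reports(apps, "participant", seed = config$seed))
    cats <- emit_category_map(apps)
    paths$flow_log <- file.path(config$out_dir, "flows.jsonl")
    write_flow_log(flows, paths$flow_log)
    paths$manifest_truth <- file.path(config$out_dir, "cohort_manifest.csv")
    utils::write.csv(sim$manifest, paths$manifest_truth, row.names = FALSE)
  } else {
    message("stage read: ", config$flow_log)
    flows <- read_flow_log(config$flow_log)
    reports <- NULL
    cats <- NULL
  }

  ids <- unique(flows$participant_id)
  series60 <- lapply(ids, function(id)
    bin_traffic(flows[flows$participant_id == id, ], 60))
  series10 <- lapply(ids, function(id)
    bin_traffic(flows[flows$participant_id == id, ], config$bin_width))
  names(series60) <- names(series10) <- ids

  ## stage 2: feasibility
  message("stage feasibility: ", length(ids), " participants")
  covs <- lapply(series60, coverage_summary)
  coverage_df <- do.call(rbind, lapply(covs, function(cv) {
    data.frame(participant_id = cv$participant_id,
               window_start = cv$window_start, window_end = cv$window_end,
               window_hours = cv$window_hours, active_hours = cv$active_hours,
               coverage_fraction = cv$coverage_fraction,
               valid_days = cv$valid_days,
               n_gaps = length(cv$gaps),
               median_gap_h = if (length(cv$gaps)) stats::median(cv$gaps) else NA,
               max_gap_h = if (length(cv$gaps)) max(cv$gaps) else NA,
               t(cv$strata),
               stringsAsFactors = FALSE)
  }))
  rownames(coverage_df) <- NULL
  paths$coverage <- file.path(config$out_dir, "coverage.csv")
  utils::write.csv(coverage_df, paths$coverage, row.names = FALSE)

  vd <- stats::setNames(coverage_df$valid_days, coverage_df$participant_id)
  retention <- retention_summary(
    vd, list(consented = length(ids)), config$threshold_days)
  boot_ci <- bootstrap_mean_ci(coverage_df$coverage_fraction,
                               reps = config$bootstrap_reps,
                               seed = derive_seed(config$seed, 7))

  ## stage 3: attribution (only when APR corpora are available)
  attribution <- NULL
  if (!is.null(reports)) {
    message("stage attribute: building unique-domain map")
    corpus <- build_corpus(reports)
    umap <- unique_app_domains(corpus)
    paths$domain_map <- file.path(config$out_dir, "unique_domains.tsv")
    write_unique_domain_map(umap, paths$domain_map)
    attributed <- attribute_flows(flows, umap, cats)
    ac <- attribution_coverage(attributed, bin_width = config$bin_width)
    attribution <- list(map = umap, coverage = ac)
  } else {
    attributed <- NULL
  }

  ## stage 4: rhythms
  message("stage rhythms: profiles and clustering")
  profiles <- lapply(series10, build_profile_matrix)
  metrics <- do.call(rbind, lapply(profiles, rhythm_metrics,
                                   min_obs_fraction = config$min_obs_fraction))
  rownames(metrics) <- NULL
  paths$metrics <- file.path(config$out_dir, "rhythm_metrics.csv")
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  clusters <- cluster_rhythms(metrics, seed = derive_seed(config$seed, 9))
  paths$clusters <- file.path(config$out_dir, "clusters.csv")
  utils::write.csv(clusters, paths$clusters, row.names = FALSE)
  radial <- do.call(rbind, lapply(profiles, radial_grid))
  paths$radial <- file.path(config$out_dir, "radial_grid.csv")
  utils::write.csv(radial, paths$radial, row.names = FALSE)

  ## stage 5: report
  report <- write_report(
    coverage_csv = paths$coverage, metrics_csv = paths$metrics,
    clusters_csv = paths$clusters, retention = retention,
    bootstrap_ci = boot_ci, attribution = attribution,
    out_json = file.path(config$out_dir, "report.json"),
    out_txt = file.path(config$out_dir, "report.txt"))
  paths$report_json <- file.path(config$out_dir, "report.json")
  paths$report_txt <- file.path(config$out_dir, "report.txt")

  files <- unlist(paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, bin_width = config$bin_width,
         threshold_days = config$threshold_days,
         bootstrap_reps = config$bootstrap_reps,
         min_obs_fraction = config$min_obs_fraction,
         files = manifest),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, paths = paths, coverage = coverage_df,
       retention = retention, bootstrap_ci = boot_ci,
       attribution = attribution, metrics = metrics, clusters = clusters,
       report = report)
}

#' Cohort summary report
#'
#' Recomputes every reported number from the stage CSVs (the reporter
#' has no arithmetic of its own beyond summaries of those files) and
#' writes a JSON and a short human-readable text report: mean/median/IQR
#' coverage overall and per stratum, retention proportions with Wilson
#' CIs, gap summaries, rhythm-metric distributions, cluster sizes.
#'
#' @param coverage_csv,metrics_csv,clusters_csv stage output CSVs.
#' @param retention a `retention_table`.
#' @param bootstrap_ci bootstrap CI of mean coverage.
#' @param attribution optional attribution stage result.
#' @param out_json,out_txt output paths (optional).
#' @return report list, invisibly when writing.
#' @export
write_report <- function(coverage_csv, metrics_csv, clusters_csv,
                         retention, bootstrap_ci = NULL, attribution = NULL,
                         out_json = NULL, out_txt = NULL) {
  read_stage <- function(p) tryCatch(
    utils::read.csv(p, stringsAsFactors = FALSE),
    error = function(e) data.frame())
  cov <- read_stage(coverage_csv)
  if (nrow(cov) == 0) stop("empty cohort: no coverage rows", call. = FALSE)
  met <- read_stage(metrics_csv)
  clu <- read_stage(clusters_csv)

  pct <- function(x) round_half_up(100 * x, 1)
  strata_cols <- intersect(c("night", "morning", "afternoon", "evening",
                             "weekday", "weekend"), names(cov))
  report <- list(
    n_participants = nrow(cov),
    coverage = list(
      mean_pct = pct(mean(cov$coverage_fraction)),
      median_pct = pct(stats::median(cov$coverage_fraction)),
      iqr_pct = pct(stats::quantile(cov$coverage_fraction, c(0.25, 0.75),
                                    names = FALSE)),
      range_pct = pct(range(cov$coverage_fraction)),
      bootstrap_ci_pct = if (!is.null(bootstrap_ci)) pct(unname(bootstrap_ci)) else NULL,
      strata_mean_pct = as.list(stats::setNames(
        vapply(strata_cols, function(sc) pct(mean(cov[[sc]], na.rm = TRUE)), 0),
        strata_cols))
    ),
    valid_days = list(mean = mean(cov$valid_days),
                      range = range(cov$valid_days)),
    gaps = list(
      median_h = stats::median(cov$median_gap_h, na.rm = TRUE),
      max_h = if (all(is.na(cov$max_gap_h))) NA else max(cov$max_gap_h, na.rm = TRUE)
    ),
    retention = as.list(as.data.frame(retention)),
    rhythm_metrics = list(
      stability_mean = mean(met$stability, na.rm = TRUE),
      stability_range = range(met$stability, na.rm = TRUE),
      power_ratio_mean = mean(met$circadian_power_ratio, na.rm = TRUE)
    ),
    clusters = as.list(table(clu$cluster)),
    attribution = if (!is.null(attribution)) list(
      byte_fraction_pct = pct(attribution$coverage$byte_fraction),
      bin_fraction_pct = pct(attribution$coverage$bin_fraction),
      unique_domain_fraction_pct = pct(attribution$map$unique_fraction)
    ) else NULL
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(out_txt)) {
    lines <- c(
      sprintf("Cohort summary (%d participants)", report$n_participants),
      sprintf("  coverage: mean %.1f%%, median %.1f%% (IQR %.1f-%.1f%%)",
              report$coverage$mean_pct, report$coverage$median_pct,
              report$coverage$iqr_pct[1], report$coverage$iqr_pct[2]),
      if (!is.null(bootstrap_ci))
        sprintf("  bootstrap 95%% CI of mean coverage: %.1f%%-%.1f%%",
                report$coverage$bootstrap_ci_pct[1],
                report$coverage$bootstrap_ci_pct[2]),
      sprintf("  valid days: mean %.1f (range %d-%d)",
              report$valid_days$mean, report$valid_days$range[1],
              report$valid_days$range[2]),
      sprintf("  median within-participant gap: %.1f h",
              report$gaps$median_h),
      "  retention:",
      sprintf("    %s: %d/%d = %d%% (Wilson 95%% CI %d%%-%d%%)",
              retention$measure, retention$numerator, retention$denominator,
              retention$percent, retention$percent_ci_lower,
              retention$percent_ci_upper),
      sprintf("  rhythm: stability mean %.2f, circadian power ratio mean %.3f",
              report$rhythm_metrics$stability_mean,
              report$rhythm_metrics$power_ratio_mean),
      sprintf("  clusters: %s",
              paste(sprintf("cluster %s: n=%s", names(report$clusters),
                            unlist(report$clusters)), collapse = ", ")),
      if (!is.null(report$attribution))
        sprintf("  attribution: %.2f%% of upload bytes, %.1f%% of bins",
                report$attribution$byte_fraction_pct,
                report$attribution$bin_fraction_pct)
    )
    writeLines(lines[!vapply(lines, is.null, logical(1))], out_txt)
  }
  invisible(report)
}
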
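# netrhythm

Digital phenotyping from encrypted network-traffic metadata. netrhythm
implements an analysis pipeline for VPN-captured smartphone flow logs —
one record per 10-second window per destination hostname, with byte and
packet counts but no content — and turns them into:

- **feasibility metrics**: per-participant monitoring windows,
  hour-level coverage, valid days, off-gap statistics, time-of-day and
  weekday/weekend stratified coverage, and cohort retention proportions
  with Wilson score CIs plus a bootstrap CI for mean coverage;
- **app/category attribution**: hostname → registered-domain
  normalization (public-suffix rules, bundled snapshot), a union corpus
  over App Privacy Report–style app→domain reports, global
  unique-domain disambiguation (only domains used by exactly one app
  are kept), conservative flow labeling, and attribution-coverage
  statistics;
- **behavioral rhythms**: within-day percentile-normalized upload
  profiles, day-to-day stability (mean correlation of consecutive daily
  profiles), the circadian power ratio (share of non-DC spectral power
  at 1 cycle/24 h), activity onset/offset, sleep–wake contrasts, radial
  heatmap grids, and k-means (k = 2) clustering of the cohort in
  z-scored metric space.

It is aimed at researchers running passive mobile-sensing or behavioral
chronobiology studies who need the full path from raw flow metadata to
cohort-level summaries, and at methodologists who want the pipeline
testable without any participant data: a synthetic cohort generator
produces flow logs with ground-truth sleep intervals, app sessions,
VPN-off gaps, and phenotype labels.

## The core quantities

For participant *i*, day *d* and 10-minute bin *t*, let *x*(d,t) be
upload bytes. Percentile normalization replaces *x*(d,t) by its
within-day empirical percentile, (rank − 0.5)/n × 100 over the day's
observed bins (ties averaged) — invariant to monotone rescaling of a
day's volumes. Then

- stability = mean over consecutive days of Pearson r between day
  profiles (jointly observed bins);
- circadian power ratio = P(1 cycle/day) / Σ P(f) over non-DC Fourier
  frequencies of the concatenated, mean-centered profile series;
- coverage = active hours / window hours, where an hour is active if it
  contains ≥ 1 byte, and the window spans first to last active hour;
- Wilson 95% bounds for a proportion p̂ = k/n use the score formula
  with z = 1.959964.

## Worked example

```r
library(netrhythm)
res <- run_pipeline(pipeline_config(
  simulate = cohort_config(n_participants = 6, days = 10, seed = 42),
  out_dir = "run1", bootstrap_reps = 2000, seed = 42))
```

The run directory contains the simulated flow log, per-participant
coverage CSV, rhythm-metric and cluster CSVs, the unique-domain map,
and a report. `run1/report.txt` from this exact call:

```
Cohort summary (6 participants)
  coverage: mean 98.6%, median 98.8% (IQR 97.5-100.0%)
  bootstrap 95% CI of mean coverage: 97.5%-99.6%
  valid days: mean 9.8 (range 9-10)
  median within-participant gap: 4.0 h
  retention:
    retention_ge5d_of_contributors: 6/6 = 100% (Wilson 95% CI 61%-100%)
    retention_ge5d_of_consented: 6/6 = 100% (Wilson 95% CI 61%-100%)
  rhythm: stability mean 0.21, circadian power ratio mean 0.192
  clusters: cluster 0: n=3, cluster 1: n=3
  attribution: 49.40% of upload bytes, 48.0% of bins
```

Reading it: the six simulated participants kept the VPN on through
almost their whole monitoring windows (mean coverage 98.6%), every
participant passed the 5-valid-day retention threshold (100%, with the
wide Wilson interval a small cohort warrants), and k-means split the
cohort into the three regular and three irregular phenotypes the
generator planted (cluster 0 = higher stability). About half of upload
bytes hit app-unique domains in this small synthetic app universe;
shared-infrastructure flows are never labeled.

Individual pieces work standalone:

```r
wilson_interval(27, 29)
#>     lower     upper
#> 0.7804    0.9809
flows <- read_flow_log("run1/flows.jsonl")
s <- bin_traffic(flows[flows$participant_id == "P001", ], 60)
hour_coverage(s)$coverage_fraction
```

## Package layout

- `R/flow_io.R` — flow-log parsing/writing, validation, time binning
- `R/synthetic.R` — cohort generator, APR-style reports, category map
- `R/feasibility.R` — coverage, gaps, strata, Wilson/bootstrap CIs, retention
- `R/attribution.R` — domain normalization, union corpus, disambiguation, labeling
- `R/rhythms.R` — percentile profiles, stability, circadian power ratio, clustering
- `R/pipeline.R` — orchestration, manifest hashing, cohort report
- `vignettes/netrhythm-methods.Rmd` — the methods account: model,
  assumptions, parameter defaults, generator scope, limitations
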
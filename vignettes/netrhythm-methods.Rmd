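---
title: "Methods: feasibility and behavioral rhythms from VPN flow metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feasibility and behavioral rhythms from VPN flow metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrhythm)
```

## The measurement model

netrhythm analyzes encrypted smartphone traffic metadata captured by an
on-device VPN: one record per 10-second window per destination hostname,
carrying only a pseudonymous participant id, a timestamp with explicit UTC
offset, the hostname, and byte/packet counts in each direction. No payloads
and no content. Three analysis families are built on this substrate:

1. **Feasibility** — how continuously did monitoring run?
2. **Attribution** — which app (and behavioral category) generated a flow?
3. **Rhythms** — what diurnal structure does upload traffic reveal?

All time arithmetic is done in each participant's local time, defined as
the UTC timestamp shifted by a fixed per-participant offset. Daylight
saving transitions are deliberately not modeled: the intended use is
short (about two-week) deployments restricted to participants who remain
in one time zone, and a fixed offset keeps day boundaries (local
midnight) unambiguous. Raw 10-second windows are summed onto contiguous,
non-overlapping bins (10-minute bins for rhythms, 60-minute for
coverage), each window assigned by its start time; since windows are two
orders of magnitude shorter than bins, the assignment error is bounded
by 10 s and byte totals are conserved exactly.

## Feasibility metrics

An hour is *active* if at least one byte was observed in it. The
*monitoring window* runs from a participant's first to last active hour,
inclusive; *coverage* is active hours over window hours. A *valid day*
is a local calendar day with at least one active hour. *Gaps* are
maximal runs of inactive hours strictly inside the window, reported at
the hour resolution of the coverage unit — sub-hour interruptions are
invisible by construction, and fractional cohort-level summaries (e.g. a
median gap of 7.5 h) arise from aggregating integer-length gaps across
participants.

Stratified coverage restricts the active/eligible ratio to six-hour
local-time blocks — night 00–06, morning 06–12, afternoon 12–18,
evening 18–24, all half-open — and to weekday (Mon–Fri) versus weekend
(Sat–Sun). The blocks are configurable; the symmetric 6-hour partition
is the package default because it matches the stratum labels commonly
used in adherence tables and tiles the day exactly, which the code
asserts.

Retention proportions (e.g. the share of contributing participants with
at least 5 valid days) carry Wilson score 95% intervals, computed from
the closed-form score formula with z = 1.959964. The Wilson interval is
preferred over the Wald interval because retention numerators sit near
the boundary (27/29) where Wald intervals degenerate. Printed
percentages use round-half-up, matching how proportions are
conventionally reported (49.89 prints as 50).

The mean-coverage interval uses a seeded percentile bootstrap (default
10,000 replicates). The percentile method was chosen for its
transparency; its small-sample under-coverage is documented in the test
suite, which measures empirical coverage of about 95% at samples of
n = 100.

## Attribution: conservative unique-domain disambiguation

App Privacy Report (APR) corpora list, per app, the hostnames the app
contacted. Hostnames are lowercased, stripped of trailing dots, and
reduced to *registered (base) domains* against a bundled plain-text
snapshot of public-suffix rules (longest-suffix match; unknown top-level
labels fall back to the standard default rule). IP literals,
single-label names, and names under special-use suffixes (`.local`,
`.internal`, `.test`, ...) are rejected as non-routable. The `.example`
top-level label is deliberately *accepted* as routable in the bundled
snapshot, so documentation-style synthetic domains can flow through the
full pipeline.

All reports — participant-collected ("deep-state") and scripted — are
unioned into one corpus mapping each registered domain to the set of
apps seen contacting it. Only domains mapped to exactly one app across
the *entire* union survive disambiguation; everything else (CDNs,
analytics, OS services) is excluded as shared infrastructure. Flow
attribution through this map is therefore conservative by construction:
a flow either hits an app-unique domain and is labeled with that single
app, or it is left unattributed. On synthetic cohorts, where the true
app behind every session flow is known, this yields attribution
precision 1.0 — a structural property, not a tuned one — which the test
suite verifies. Attribution coverage is summarized two ways: the
fraction of upload bytes attributable, and the fraction of 10-minute
bins containing at least one attributable flow.

"Semantic identifiability" of an app from a domain set is
operationalized as: at least one app-unique registered domain sharing an
alphanumeric token (length ≥ 3) with the app's name, with an explicit
override list for curated exceptions. This predicate is configurable;
it is a stand-in for manual review, and the default is intentionally
conservative.

## Rhythms

Upload bytes are used as the activity proxy because outbound traffic
more directly reflects user-initiated actions than content downloads.
Each day's 10-minute bins are transformed to within-day empirical
percentiles, `(average rank − 0.5) / n_observed × 100`, with ties
averaged. The transform is invariant to any strictly monotone rescaling
of a day's raw volumes — asserted as a property test — which removes
between-person differences in absolute throughput while preserving
intraday phase structure. Bins inside hours with no observed traffic are
treated as VPN-off (missing), not as zeros: an unobserved bin carries no
rank information, and the day's percentiles are computed over observed
bins only.

Two per-participant metrics summarize the profile matrix:

* **Day-to-day stability** — mean Pearson correlation between
  consecutive daily percentile profiles over jointly observed bins.
  Days observed in fewer than 50% of bins (configurable) are dropped;
  pairs with under 3 joint bins or zero variance are skipped. Pearson
  on rank-normalized inputs behaves near-identically to Spearman on the
  raw volumes, which is why no separate rank correlation is offered.
* **Circadian power ratio** — the share of non-DC periodogram power at
  exactly 1 cycle per 24 hours. The profile matrix is concatenated into
  one series of whole days (missing bins imputed at the neutral
  percentile 50), mean-centered, and transformed with a plain FFT
  periodogram; with D whole days the 24-hour line is Fourier index D
  exactly, so no band integration is needed (a configurable half-width
  exists for sensitivity analysis). Parseval's identity is asserted
  numerically in the tests. A per-day-averaged spectral variant was
  considered and not implemented; the concatenated estimator is the
  package's single definition.

Cohort structure is explored with k-means (k = 2) on the z-scored
(stability, power ratio) pair — 50 restarts under a fixed seed, labels
oriented so cluster 0 has the higher mean stability ("more routine").
Zero-variance features are dropped with a warning rather than producing
NaN z-scores.

Activity **onset/offset** is estimated per day as the start of the first
and end of the last run of at least 3 bins (30 min) above the 60th
percentile. These defaults are explicitly an operationalization choice,
not a literature value. On simulated routine participants the median
onset error against true wake time is within a bin or two; the *mean*
error is larger because evenings that cross midnight legitimately anchor
a calendar-day onset at 00:00 — a limitation of any midnight-split day
convention.

The **sleep–wake contrast** compares mean percentiles over
sleep-annotated versus wake observed bins; on simulated sleepers the
observed difference exceeds the 95th percentile of contrasts under
randomly shifted annotations (a permutation check in the test suite).

## The synthetic cohort generator

No raw participant data ships with the package; every downstream stage
is exercised against a generator whose defaults define the study
conditions once:

* **Cohort**: 24 participants (12 routine, 12 fragmented), 14 days each,
  onboarding staggered over 7 days, fixed UTC−05:00 — matching the
  rhythm-analysis cohort size and planned deployment length the
  pipeline targets.
* **Background traffic**: per-10-s Bernoulli emission (p = 0.04) of
  keep-alive flows to shared-infrastructure domains with lognormal byte
  volumes; volume halves during sleep (push and refresh traffic follow
  use). This guarantees that a VPN-on hour is active with probability
  essentially 1, so hour-level coverage cleanly identifies VPN-off time.
* **Sessions**: Poisson counts at roughly 75 sessions/day across a
  12-app universe (realistic daily pickup counts), placed by a diurnal
  intensity — a raised cosine peaking mid-afternoon, down-weighted to
  10% during sleep (the configurable sleep/wake upload effect; no
  quantitative published value exists for it, so the default is a free
  parameter of the generator). Sessions emit bursts of 10-s windows to
  a mix of the app's unique and shared domains. A morning phone-check
  burst (20–40 min, 85% of days) starts at sleep offset, giving wake a
  sharp traffic signature, as real users' onsets show.
* **Phenotypes**: routine sleeps 01:00–08:00 with 20-min day-to-day
  jitter and near-zero night activity; fragmented sleeps 02:30–10:00
  with 150-min jitter, frequent mid-sleep activity episodes, and a
  flatter daytime shape. These produce clearly separated
  (stability, power ratio) distributions, which is what makes the
  label-recovery clustering check meaningful.
* **Gaps**: per-day reboot probability 0.15 with lognormal off
  durations (median 2 h, σ = 1.2 log-hours): short gaps common, rare
  multi-day lapses. Deliberate off intervals can be forced explicitly.

Ground truth (sleep intervals, per-flow true app, VPN-off intervals,
phenotype label) is returned alongside the flows, enabling
parameter-recovery tests: clustering recovers phenotype labels,
attribution precision is 1.0, forced gaps reappear in gap statistics,
and sleep bins rank below wake bins.

What the generator does **not** emulate: packet-level timing, TLS
handshakes, realistic hostname grammar beyond registered-domain
structure, travel/timezone changes, DST, weekday–weekend behavioral
differences, and seasonal trends. Passing tests therefore demonstrate
the pipeline's correctness and its statistical behavior under the
generator's assumptions — not that real cohorts will show the same
effect sizes.

## Numerical and scale choices

* Tests run on reduced problem sizes chosen for tight feedback loops
  (cohorts of 4 for unit tests; the full 24 × 14-day cohort for the
  cohort-level checks; 200–1000 replicates for Monte-Carlo bounds).
* Bootstrap and k-means are seeded everywhere; cohort generation is
  bit-identical under a fixed seed, and the pipeline manifest records
  MD5 hashes so reruns are verifiable.
* Degenerate inputs fail loudly and early: all-zero series ("no
  monitoring window"), empty app sets, zero denominators, all-masked
  days, sub-2-day spectral requests.

## Worked example

```{r, eval = FALSE}
sim <- simulate_cohort(cohort_config(n_participants = 24, days = 14, seed = 1))
res <- run_pipeline(pipeline_config(
  simulate = cohort_config(n_participants = 24, days = 14, seed = 1),
  out_dir = "run1", seed = 1))
res$retention
res$clusters
```

The text report in `run1/report.txt` prints cohort coverage, retention
with Wilson CIs, gap summaries, rhythm metric means, cluster sizes, and
attribution coverage; every number is recomputed from the stage CSVs.
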
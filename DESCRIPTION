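Package: netrhythm
Title: Behavioral Rhythm and Feasibility Analysis of VPN Flow Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phenotyping pipeline for encrypted network-traffic
    metadata captured through an on-device VPN. Parses per-flow logs
    aggregated in 10-second windows, computes monitoring feasibility
    metrics (hour-level coverage, valid days, gap statistics, retention
    with Wilson and bootstrap confidence intervals), attributes traffic
    to apps and behavioral categories through conservative unique-domain
    disambiguation of App Privacy Report corpora, and derives behavioral
    rhythm metrics from percentile-normalized diurnal upload profiles
    (day-to-day stability, circadian power ratio, k-means rhythm
    clustering). Includes a synthetic cohort generator with ground-truth
    annotations so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
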
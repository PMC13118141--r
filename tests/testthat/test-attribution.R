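test_that("hostname normalization reduces to registered domains and rejects non-routable names", {
  n <- normalize_hostname(c("video.cdn.youtube.com", "a.b.example.co.uk",
                            "YouTube.COM.", "api.chatter.com"))
  expect_equal(n$registered_domain,
               c("youtube.com", "example.co.uk", "youtube.com", "chatter.com"))
  expect_true(all(is.na(n$rejected_reason)))

  r <- normalize_hostname(c("192.168.1.5", "fe80::1", "router.local",
                            "localhost", "mdns", "co.uk"))
  expect_true(all(is.na(r$registered_domain)))
  expect_equal(r$rejected_reason[1:4], rep("non_routable", 4))
  expect_equal(r$rejected_reason[5:6], rep("single_label", 2))

  # unknown TLD falls back to the default rule (last label = suffix)
  u <- normalize_hostname("deep.api.service.zz")
  expect_equal(u$registered_domain, "service.zz")
})

test_that("corpus union merges app sets per normalized domain", {
  r1 <- structure(list(source = "scripted", entries = list(
    list(bundle_id = "A", name = "AlphaChat",
         domains = list("alphachat.com", "cdn.shared-x.com")),
    list(bundle_id = "B", name = "BetaGames",
         domains = list("betagames.io", "shared-x.com")))), class = "apr_report")
  r2 <- structure(list(source = "participant", entries = list(
    list(bundle_id = "A", name = "AlphaChat",
         domains = list("img.alphachat.com", "extra.alphachat.com")))),
    class = "apr_report")
  corpus <- build_corpus(list(r1, r2))
  expect_equal(corpus$n_apps, 2)
  expect_setequal(names(corpus$domains),
                  c("alphachat.com", "shared-x.com", "betagames.io"))
  expect_setequal(corpus$domains[["shared-x.com"]], c("A", "B"))
  expect_setequal(corpus$sources[["alphachat.com"]],
                  c("scripted", "participant"))
})

test_that("corpus building equals a brute-force set union on random reports", {
  set.seed(31)
  apps <- paste0("app", 1:6)
  doms <- c(paste0("dom", 1:10, ".com"), "shared.net")
  mk_report <- function(src) {
    entries <- lapply(sample(apps, 4), function(a)
      list(bundle_id = a, name = a,
           domains = as.list(sample(doms, sample(2:5, 1)))))
    structure(list(source = src, entries = entries), class = "apr_report")
  }
  reports <- list(mk_report("scripted"), mk_report("participant"), mk_report("scripted"))
  corpus <- build_corpus(reports)
  # brute force
  want <- list()
  for (r in reports) for (e in r$entries) for (d in unlist(e$domains)) {
    want[[d]] <- union(want[[d]], e$bundle_id)
  }
  expect_setequal(names(corpus$domains), names(want))
  for (d in names(want)) expect_setequal(corpus$domains[[d]], want[[d]])
})

test_that("unique-domain disambiguation keeps only single-app domains", {
  corpus <- structure(list(domains = list(
    "a.example" = "A", "s.example" = c("A", "B"), "b.example" = "B"),
    apps = c(A = "AppA", B = "AppB"), n_apps = 2, n_domains = 3),
    class = "domain_corpus")
  m <- unique_app_domains(corpus)
  expect_equal(m$map, c("a.example" = "A", "b.example" = "B"))
  expect_equal(m$excluded$domain, "s.example")
  expect_equal(m$unique_fraction, 2 / 3)

  all_shared <- structure(list(domains = list("x.com" = c("A", "B"),
                                              "y.com" = c("B", "C")),
                               apps = c(A = "a", B = "b", C = "c"),
                               n_apps = 3, n_domains = 2),
                          class = "domain_corpus")
  expect_length(unique_app_domains(all_shared)$map, 0)

  # randomized: equality with an exhaustive per-domain app-count oracle
  set.seed(8)
  for (i in 1:10) {
    doms <- stats::setNames(lapply(1:12, function(j)
      sample(LETTERS[1:5], sample(1:3, 1))), paste0("d", 1:12, ".com"))
    cp <- structure(list(domains = doms, apps = stats::setNames(LETTERS[1:5], LETTERS[1:5]),
                         n_apps = 5, n_domains = 12), class = "domain_corpus")
    m2 <- unique_app_domains(cp)
    expect_setequal(names(m2$map), names(doms)[lengths(doms) == 1])
  }
})

test_that("adding a report never turns a shared domain unique", {
  apps <- tiny_apps()
  base <- list(emit_apr_reports(apps, "scripted", seed = 1))
  grown <- c(base, list(emit_apr_reports(apps, "participant", seed = 1)))
  shared_before <- unique_app_domains(build_corpus(base))$excluded$domain
  shared_after <- unique_app_domains(build_corpus(grown))$excluded$domain
  expect_true(all(shared_before %in% shared_after))
})

test_that("flows are labeled conservatively: unique-domain hits only", {
  umap <- structure(list(
    map = c("youtube.com" = "com.google.youtube"),
    excluded = data.frame(domain = "apple.com", reason = "shared"),
    unique_fraction = 0.5,
    apps = c(com.google.youtube = "YouTube")), class = "unique_domain_map")
  cats <- data.frame(bundle_id = "com.google.youtube", app_name = "YouTube",
                     genre = "Entertainment")
  fl <- make_flows(c("2025-03-03 10:00:00", "2025-03-03 10:00:10"),
                   hostname = c("youtube.com", "cdn.apple.com"))
  at <- attribute_flows(fl, umap, cats)
  expect_equal(at$app, c("com.google.youtube", NA))
  expect_equal(at$genre, c("Entertainment", NA))

  # app missing from the category map -> genre "unknown" with a warning
  cats2 <- cats[0, ]
  expect_warning(at2 <- attribute_flows(fl, umap, cats2), "unknown")
  expect_equal(at2$genre[1], "unknown")
})

test_that("attribution on simulated cohorts has precision 1 against ground truth", {
  co <- small_cohort()
  apps <- default_apps()
  reports <- list(emit_apr_reports(apps, "scripted", seed = 2),
                  emit_apr_reports(apps, "participant", seed = 2))
  umap <- unique_app_domains(build_corpus(reports))
  cats <- emit_category_map(apps)
  at <- attribute_flows(co$flows, umap, cats)

  true_app <- unlist(lapply(names(co$truth), function(id) co$truth[[id]]$flows_app))
  labeled <- !is.na(at$app)
  # every label matches the ground-truth session app; zero false labels
  expect_gt(sum(labeled), 0)
  expect_true(all(at$app[labeled] == true_app[labeled]))
  # background (shared-domain) flows are never labeled
  expect_true(all(is.na(at$app[is.na(true_app)])))
  # genres joined correctly from the category map
  gmap <- stats::setNames(cats$genre, cats$bundle_id)
  expect_equal(at$genre[labeled], unname(gmap[at$app[labeled]]))
})

test_that("attribution coverage fractions match a brute-force tally", {
  umap <- structure(list(map = c("u.com" = "A"), excluded = NULL,
                         unique_fraction = 1, apps = c(A = "A")),
                    class = "unique_domain_map")
  fl <- make_flows(c("2025-03-03 10:00:00", "2025-03-03 10:30:00",
                     "2025-03-03 11:00:00"),
                   hostname = c("u.com", "s.cdn-edge.net", "x.u.com"),
                   bytes_up = c(1, 99, 50))
  at <- attribute_flows(fl, umap)
  ac <- attribution_coverage(at)
  expect_equal(ac$byte_fraction, 51 / 150)
  expect_equal(ac$bin_fraction, 2 / 3)   # 3 active 10-min bins, 2 attributable

  all_u <- attribute_flows(make_flows("2025-03-03 10:00:00", hostname = "u.com"), umap)
  acu <- attribution_coverage(all_u)
  expect_equal(acu$byte_fraction, 1)
  expect_equal(acu$bin_fraction, 1)

  zero <- make_flows("2025-03-03 10:00:00", bytes_up = 0)
  expect_error(attribution_coverage(attribute_flows(zero, umap)), "zero total")

  # random mix vs brute force
  co <- small_cohort()
  apps <- default_apps()
  umap2 <- unique_app_domains(build_corpus(list(
    emit_apr_reports(apps, "scripted", seed = 2))))
  at2 <- attribute_flows(co$flows, umap2)
  ac2 <- attribution_coverage(at2, bin_width = 10)
  expect_equal(ac2$byte_fraction,
               sum(at2$bytes_up[!is.na(at2$app)]) / sum(at2$bytes_up))
})

test_that("scripted vs deep-state comparison flags identifiable apps per source", {
  apps <- default_apps()
  scripted <- list(emit_apr_reports(apps, "scripted", seed = 13))
  participant <- list(emit_apr_reports(apps, "participant", seed = 13))
  tab <- scripted_vs_deep_overlap(scripted, participant)
  expect_equal(attr(tab, "n_shared"), length(apps))
  # name-derived domains are identifiable from scripted launches alone
  expect_true(tab$scripted_identifiable[tab$name == "Chatter"])
  # opaque backend domains are not
  expect_false(tab$scripted_identifiable[tab$name == "NightRaid"])
  # deep-state usage never identifies fewer apps than scripted
  expect_gte(attr(tab, "n_participant_identifiable"),
             attr(tab, "n_scripted_identifiable"))

  other <- list(structure(list(source = "scripted", entries = list(
    list(bundle_id = "zz", name = "ZZ", domains = list("zz.com")))),
    class = "apr_report"))
  expect_error(scripted_vs_deep_overlap(other, participant), "no apps shared")
})

test_that("semantic identifiability tokenizes names against domains", {
  expect_true(semantically_identifiable("YouTube", "youtube.com"))
  expect_true(semantically_identifiable("StreamFlix", "streamflix-cdn.net"))
  expect_false(semantically_identifiable("NightRaid", "nr-gamenet.io"))
  expect_true(semantically_identifiable("NightRaid", "nr-gamenet.io",
                                        extra_identifying = "nr-gamenet.io"))
  expect_false(semantically_identifiable("App", character(0)))
})
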
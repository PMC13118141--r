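#' Hostname-to-app-to-category attribution
#'
#' Encrypted flows expose destination hostnames but not the apps behind
#' them. App Privacy Report (APR) corpora give app-level hostname sets;
#' after normalizing hostnames to registered (base) domains and dropping
#' non-routable destinations, only domains that map to exactly one app
#' across the entire union corpus are retained ("global unique-domain
#' disambiguation"). Attribution through this map is conservative: it is
#' a lower bound on app presence, and on synthetic data it cannot
#' mislabel -- a flow is either labeled with the one app that owns its
#' domain, or left unattributed.
#'
#' @name attribution
NULL

RESERVED_TLDS <- c("local", "localhost", "internal", "lan", "home", "corp",
                   "invalid", "onion", "test", "arpa")

#' Load the bundled public-suffix rule snapshot
#'
#' Plain suffix rules (no wildcards/exceptions), longest-match semantics
#' with the standard default rule (unknown TLD: the last label is the
#' suffix). Bundled so runs never touch the network.
#'
#' @param path optional path to an alternative rules file.
#' @return character vector of suffix rules.
#' @export
load_suffix_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "public_suffix_snapshot.txt",
                        package = "netrhythm")
  }
  rules <- readLines(path, warn = FALSE)
  rules <- trimws(rules)
  tolower(rules[nzchar(rules) & !startsWith(rules, "#")])
}

#' Normalize a hostname to its registered (base) domain
#'
#' Lowercases, strips a trailing dot, then rejects IP literals,
#' single-label names, and names under local/special-use suffixes;
#' everything else is reduced to suffix-plus-one-label using the rule
#' snapshot. Rejection is a return state, not an error.
#'
#' @param hostnames character vector of raw hostnames.
#' @param rules suffix rules from [load_suffix_rules()].
#' @return data.frame: `hostname`, `registered_domain` (NA if rejected),
#'   `rejected_reason` (NA, `"non_routable"`, or `"single_label"`).
#' @export
normalize_hostname <- function(hostnames, rules = load_suffix_rules()) {
  h <- tolower(trimws(hostnames))
  h <- sub("\\.$", "", h)
  n <- length(h)
  reg <- rep(NA_character_, n)
  why <- rep(NA_character_, n)

  is_ipv4 <- grepl("^\\d{1,3}(\\.\\d{1,3}){3}$", h)
  is_ipv6 <- grepl(":", h, fixed = TRUE)
  bad_chars <- !grepl("^[a-z0-9._-]+$", h)
  labels <- strsplit(h, ".", fixed = TRUE)
  nlab <- lengths(labels)
  tld <- vapply(labels, function(l) if (length(l)) l[length(l)] else "", "")
  reserved <- tld %in% RESERVED_TLDS

  nonroutable <- is_ipv4 | is_ipv6 | reserved | bad_chars
  why[nonroutable] <- "non_routable"
  single <- !nonroutable & nlab < 2
  why[single] <- "single_label"

  ok <- !nonroutable & !single
  rset <- rules
  for (i in which(ok)) {
    l <- labels[[i]]
    if (paste(l, collapse = ".") %in% rset) {  # hostname IS a public suffix
      why[i] <- "single_label"
      next
    }
    # longest suffix rule that matches; default rule = last label alone
    suf_len <- 1L
    for (k in seq_len(length(l) - 1L)) {
      cand <- paste(l[(length(l) - k + 1L):length(l)], collapse = ".")
      if (cand %in% rset) suf_len <- k
    }
    if (suf_len >= length(l)) {     # hostname IS a public suffix
      why[i] <- "single_label"
    } else {
      reg[i] <- paste(l[(length(l) - suf_len):length(l)], collapse = ".")
    }
  }
  data.frame(hostname = hostnames, registered_domain = reg,
             rejected_reason = why, stringsAsFactors = FALSE)
}

#' Build the union domain corpus from APR reports
#'
#' Normalizes every reported hostname and unions app sets per registered
#' domain across all reports (both sources). Non-routable and
#' single-label hostnames are dropped at the domain-entry level; apps
#' are never excluded at this stage.
#'
#' @param reports list of `apr_report` objects.
#' @param rules suffix rules.
#' @return a `domain_corpus`: list with `domains` (named list:
#'   registered domain -> character vector of bundle_ids), `apps`
#'   (bundle_id -> name), `sources` (domain -> sources seen in),
#'   `n_apps`, `n_domains`.
#' @export
build_corpus <- function(reports, rules = load_suffix_rules()) {
  if (length(reports) == 0) stop("need at least one APR report", call. = FALSE)
  domains <- list()
  sources <- list()
  apps <- character(0)
  for (rep in reports) {
    for (e in rep$entries) {
      apps[e$bundle_id] <- e$name
      norm <- normalize_hostname(unlist(e$domains), rules)
      for (d in unique(stats::na.omit(norm$registered_domain))) {
        domains[[d]] <- union(domains[[d]], e$bundle_id)
        sources[[d]] <- union(sources[[d]], rep$source)
      }
    }
  }
  structure(list(domains = domains, apps = apps, sources = sources,
                 n_apps = length(apps), n_domains = length(domains)),
            class = "domain_corpus")
}

#' Global unique-domain disambiguation
#'
#' Retains only domains mapped to exactly one app across the entire
#' union corpus; domains contacted by two or more apps are excluded as
#' shared infrastructure.
#'
#' @param corpus a `domain_corpus`.
#' @return a `unique_domain_map`: list with `map` (named character:
#'   domain -> bundle_id), `excluded` (data.frame: domain, reason),
#'   `unique_fraction` (share of corpus domains retained).
#' @export
unique_app_domains <- function(corpus) {
  n_apps_per_dom <- lengths(corpus$domains)
  uniq <- names(corpus$domains)[n_apps_per_dom == 1]
  shared <- names(corpus$domains)[n_apps_per_dom > 1]
  map <- vapply(corpus$domains[uniq], `[`, character(1), 1L)
  structure(list(
    map = map,
    excluded = data.frame(domain = shared,
                          reason = rep("shared", length(shared)),
                          stringsAsFactors = FALSE),
    unique_fraction = if (corpus$n_domains > 0)
      length(uniq) / corpus$n_domains else NA_real_,
    apps = corpus$apps),
    class = "unique_domain_map")
}

#' Export a unique-domain map as TSV
#' @param map a `unique_domain_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unique_domain_map <- function(map, path) {
  utils::write.table(
    data.frame(domain = names(map$map), bundle_id = unname(map$map)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attribute flows to apps and categories
#'
#' Each flow's hostname is normalized and looked up in the unique-domain
#' map: a hit labels the flow with that single app (and its genre); a
#' miss -- shared, unknown, or non-routable domain -- leaves it
#' unattributed. Attributed and unattributed flows partition the input.
#'
#' @param flows a `flow_log`.
#' @param map a `unique_domain_map`.
#' @param categories category map data.frame (`bundle_id`, `genre`);
#'   apps absent from it are labeled genre `"unknown"` with a warning.
#' @param rules suffix rules (must be the ones the map was built with).
#' @return `flows` with added columns `registered_domain`, `app`
#'   (bundle_id or NA), `genre` (or NA).
#' @export
attribute_flows <- function(flows, map, categories = NULL,
                            rules = load_suffix_rules()) {
  hosts <- unique(flows$hostname)
  norm <- normalize_hostname(hosts, rules)
  reg <- norm$registered_domain[match(flows$hostname, norm$hostname)]
  app <- unname(map$map[reg])
  genre <- rep(NA_character_, length(app))
  if (!is.null(categories)) {
    genre <- categories$genre[match(app, categories$bundle_id)]
    miss <- !is.na(app) & is.na(genre)
    if (any(miss)) {
      warning("app(s) missing from category map, genre set to 'unknown': ",
              paste(unique(app[miss]), collapse = ", "), call. = FALSE)
      genre[miss] <- "unknown"
    }
  }
  flows$registered_domain <- reg
  flows$app <- app
  flows$genre <- genre
  flows
}

#' Attribution coverage statistics
#'
#' Byte-level coverage: attributable upload bytes over total upload
#' bytes. Temporal coverage: fraction of bins with any traffic that
#' contain at least one attributable flow (10-minute bins by default).
#'
#' @param attributed output of [attribute_flows()] (single or multiple
#'   participants).
#' @param bin_width bin width in minutes for the temporal measure.
#' @return list: `byte_fraction`, `bin_fraction`, `n_bins_active`,
#'   `total_bytes_up`.
#' @export
attribution_coverage <- function(attributed, bin_width = 10) {
  total_up <- sum(attributed$bytes_up)
  if (total_up <= 0) stop("zero total upload bytes", call. = FALSE)
  attr_up <- sum(attributed$bytes_up[!is.na(attributed$app)])
  local <- attributed$window_start + attributed$utc_offset_min * 60
  binkey <- paste(attributed$participant_id,
                  floor(as.numeric(local) / (bin_width * 60)))
  active_bins <- unique(binkey)
  attr_bins <- unique(binkey[!is.na(attributed$app)])
  list(byte_fraction = attr_up / total_up,
       bin_fraction = length(attr_bins) / length(active_bins),
       n_bins_active = length(active_bins),
       total_bytes_up = total_up)
}

# Tokenize for semantic identifiability: lowercase alphanumeric runs,
# plus camel-case word splits of app names.
name_tokens <- function(x) {
  x2 <- gsub("([a-z])([A-Z])", "\\1 \\2", x)
  toks <- unlist(strsplit(tolower(paste(x, x2)), "[^a-z0-9]+"))
  toks <- toks[nchar(toks) >= 3]
  unique(c(toks, gsub("[^a-z0-9]", "", tolower(x))))
}

#' Is an app semantically identifiable from a domain set?
#'
#' Default predicate: at least one unique domain whose registered-domain
#' labels share a token (length >= 3) with the app's name. Supply
#' `extra_identifying` for curated exceptions.
#'
#' @param app_name display name.
#' @param domains character vector of registered domains unique to the app.
#' @param extra_identifying domains to treat as identifying regardless.
#' @return logical.
#' @export
semantically_identifiable <- function(app_name, domains,
                                      extra_identifying = character()) {
  if (length(domains) == 0) return(FALSE)
  if (any(domains %in% extra_identifying)) return(TRUE)
  toks <- name_tokens(app_name)
  dom_toks <- unlist(strsplit(tolower(domains), "[^a-z0-9]+"))
  any(vapply(toks, function(tk)
    any(grepl(tk, dom_toks, fixed = TRUE)), logical(1)))
}

#' Compare scripted vs participant ("deep-state") APR corpora
#'
#' For each app present in both corpora, determines whether it is
#' identifiable (owns at least one unique, semantically identifying
#' domain) from scripted reports alone, from participant reports alone,
#' or both. Unique-domain maps are rebuilt per source over the shared
#' cohort plus the full union (shared-infrastructure exclusions are
#' always global).
#'
#' @param scripted,participant lists of `apr_report` objects.
#' @param rules suffix rules.
#' @param identify_fn predicate `(app_name, domains) -> logical`
#'   (default [semantically_identifiable()]).
#' @return data.frame per shared app: bundle_id, name,
#'   `scripted_identifiable`, `participant_identifiable`; with attributes
#'   `n_shared`, `n_scripted_identifiable`, `n_participant_identifiable`.
#' @export
scripted_vs_deep_overlap <- function(scripted, participant,
                                     rules = load_suffix_rules(),
                                     identify_fn = semantically_identifiable) {
  apps_in <- function(reports) unique(unlist(lapply(reports, function(r)
    vapply(r$entries, function(e) e$bundle_id, character(1)))))
  shared_apps <- intersect(apps_in(scripted), apps_in(participant))
  if (length(shared_apps) == 0) stop("no apps shared between corpora",
                                     call. = FALSE)
  full <- build_corpus(c(scripted, participant), rules)
  umap <- unique_app_domains(full)
  per_source_domains <- function(reports, bid) {
    doms <- unlist(lapply(reports, function(r) {
      e <- Filter(function(x) x$bundle_id == bid, r$entries)
      unlist(lapply(e, function(x) x$domains))
    }))
    if (length(doms) == 0) return(character(0))
    unique(stats::na.omit(normalize_hostname(doms, rules)$registered_domain))
  }
  rows <- lapply(shared_apps, function(bid) {
    uniq_of_app <- names(umap$map)[umap$map == bid]
    nm <- full$apps[[bid]]
    sd <- intersect(per_source_domains(scripted, bid), uniq_of_app)
    pd <- intersect(per_source_domains(participant, bid), uniq_of_app)
    data.frame(bundle_id = bid, name = nm,
               scripted_identifiable = identify_fn(nm, sd),
               participant_identifiable = identify_fn(nm, pd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_shared") <- nrow(out)
  attr(out, "n_scripted_identifiable") <- sum(out$scripted_identifiable)
  attr(out, "n_participant_identifiable") <- sum(out$participant_identifiable)
  out
}
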
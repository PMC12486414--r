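#' Configuration for the synthetic survey generator
#'
#' Describes a survey with planted statistical structure: families of
#' related sequences descended from per-family ancestors (which descend
#' from a common root), controlled within/between-family divergence, a
#' PCR-fragment truncation model, exact-duplicate injection, two domains
#' with different reference gene lengths, and per-family environmental
#' source specificity.
#'
#' @param n_families Number of sequence families.
#' @param seqs_per_family Integer, or length-2 range sampled per family.
#' @param ancestor_length Named lengths of the domain reference genes in
#'   bp; defaults 1105 (bacterial-like) and 1425 (archaeal-like).
#' @param within_family_sub_rate Per-site substitution probability from
#'   the family ancestor to each member (default 0.03, well inside an 87%
#'   identity cluster).
#' @param between_family_divergence Per-site substitution probability from
#'   the root to each family ancestor (default 0.15: between-family
#'   identity around 73%, below an 87% clustering threshold yet still
#'   alignable, as expected for families of one gene; raise towards 0.45
#'   for a well-separated regime).
#' @param fragment_prob Probability a member is truncated to a
#'   PCR-fragment-like piece (default 0.5: surveys mix whole genes and
#'   amplicons).
#' @param fragment_len_range Length range of fragments in bp
#'   (default c(400, 800)).
#' @param duplicate_rate Probability an exact duplicate of a record is
#'   appended (default 0.05).
#' @param source_specificity Probability a family is single-source
#'   (default 0.75, the niche-specificity level typical of functional-gene
#'   surveys); otherwise the family spans 2-3 sources.
#' @param domain_mix Named proportions of families per domain
#'   (default 80% Bacteria, 20% Archaea).
#' @param aquatic_only If `TRUE` (default) family sources are drawn from
#'   the aquatic categories only; otherwise from all nine.
#' @param seed Master seed; the generator is bit-reproducible under it
#'   (per-family streams are split from the master seed).
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_families = 10,
                            seqs_per_family = c(5, 30),
                            ancestor_length = c(Bacteria = 1105,
                                                Archaea = 1425),
                            within_family_sub_rate = 0.03,
                            between_family_divergence = 0.15,
                            fragment_prob = 0.5,
                            fragment_len_range = c(400, 800),
                            duplicate_rate = 0.05,
                            source_specificity = 0.75,
                            domain_mix = c(Bacteria = 0.8, Archaea = 0.2),
                            aquatic_only = TRUE,
                            seed = 1) {
  cfg <- list(n_families = as.integer(n_families),
              seqs_per_family = as.integer(seqs_per_family),
              ancestor_length = unlist(ancestor_length),
              within_family_sub_rate = within_family_sub_rate,
              between_family_divergence = between_family_divergence,
              fragment_prob = fragment_prob,
              fragment_len_range = as.integer(fragment_len_range),
              duplicate_rate = duplicate_rate,
              source_specificity = source_specificity,
              domain_mix = unlist(domain_mix),
              aquatic_only = isTRUE(aquatic_only),
              seed = as.integer(seed))
  probs <- c(cfg$within_family_sub_rate, cfg$between_family_divergence,
             cfg$fragment_prob, cfg$duplicate_rate, cfg$source_specificity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_families < 1) stop("need at least one family")
  if (any(cfg$ancestor_length < 1)) stop("ancestor lengths must be positive")
  if (is.null(names(cfg$domain_mix)) ||
      !all(names(cfg$domain_mix) %in% c("Bacteria", "Archaea")))
    stop("domain_mix must be named with Bacteria/Archaea")
  if (is.null(names(cfg$ancestor_length)) ||
      !all(names(cfg$domain_mix) %in% names(cfg$ancestor_length)))
    stop("ancestor_length must name every domain in domain_mix")
  if (cfg$fragment_prob > 0 &&
      min(cfg$fragment_len_range) > max(cfg$ancestor_length))
    stop("fragment minimum exceeds ancestor length: infeasible")
  class(cfg) <- "SyntheticConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")

# sample() treats a length-1 numeric first argument as 1:n; always index
.resample <- function(x, n = 1L) x[sample.int(length(x), n)]

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# mutate each site independently with probability r to one of the 3 other
# bases (uniform), so P(two descendants agree at a site) = (1-r)^2 + r^2/3
.mutate <- function(seq, r) {
  x <- strsplit(seq, "")[[1L]]
  hit <- stats::runif(length(x)) < r
  if (any(hit))
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
  paste(x, collapse = "")
}

#' Simulate a survey with planted family and source structure
#'
#' A root sequence is drawn uniformly over A/C/G/T per domain; family
#' ancestors are the root mutated at `between_family_divergence`; members
#' are their ancestor mutated at `within_family_sub_rate`; members are
#' truncated to PCR-fragment-like pieces per the fragment model; exact
#' duplicates are appended at `duplicate_rate`. Each family is assigned a
#' single source with probability `source_specificity`, else 2-3 sources
#' (each realized by at least one member). Deterministic under the
#' config seed: per-family random streams are split from the master seed
#' so regenerating a family does not disturb the others.
#'
#' @param config A [syntheticConfig()].
#' @return A list with `survey` (a [GeneSurvey-class]) and `truth`:
#'   per-record `family`, `is_duplicate`, the family table (`domain`,
#'   `sources`, `single_source`), the family `ancestors` and domain
#'   `roots`.
#' @export
simulateSurvey <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  set.seed(cfg$seed)
  doms <- names(cfg$domain_mix)
  fam_domain <- sample(doms, cfg$n_families, replace = TRUE,
                       prob = cfg$domain_mix)
  # force every domain present when proportions allow it
  for (d in doms[cfg$domain_mix > 0])
    if (!d %in% fam_domain) fam_domain[sample(cfg$n_families, 1L)] <- d
  roots <- vapply(doms, function(d)
    .random_seq(cfg$ancestor_length[[d]]), character(1))
  fam_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_families)
  src_pool <- if (cfg$aquatic_only) {
    sourceLevels()[isAquaticSource(sourceLevels())]
  } else sourceLevels()

  fam_sources <- vector("list", cfg$n_families)
  records <- list()
  for (f in seq_len(cfg$n_families)) {
    set.seed(fam_seeds[f])
    anc <- .mutate(roots[[fam_domain[f]]], cfg$between_family_divergence)
    n_mem <- if (length(cfg$seqs_per_family) == 2L) {
      .resample(seq(cfg$seqs_per_family[1L], cfg$seqs_per_family[2L]))
    } else cfg$seqs_per_family[1L]
    single <- stats::runif(1) < cfg$source_specificity
    k_src <- if (single) 1L else .resample(2:3)
    srcs <- sample(src_pool, k_src)
    fam_sources[[f]] <- srcs
    min_len <- if (fam_domain[f] == "Bacteria") 400L else 300L
    for (m in seq_len(n_mem)) {
      s <- .mutate(anc, cfg$within_family_sub_rate)
      if (stats::runif(1) < cfg$fragment_prob) {
        lo <- max(cfg$fragment_len_range[1L], min_len)
        hi <- min(cfg$fragment_len_range[2L], nchar(s))
        if (lo <= hi) {
          len <- .resample(seq(lo, hi))
          start <- .resample(seq_len(nchar(s) - len + 1L))
          s <- substr(s, start, start + len - 1L)
        }
      }
      # multi-source families: first k_src members realize each source
      src <- if (m <= k_src) srcs[m] else .resample(srcs)
      records[[length(records) + 1L]] <- list(
        accession = sprintf("F%02dS%03d", f, m), seq = s,
        domain = fam_domain[f], source = src, family = f,
        is_duplicate = FALSE)
    }
  }
  # exact duplicates, appended with fresh accessions
  set.seed(fam_seeds[1L] %% 1000003L + 7L)
  n0 <- length(records)
  for (i in seq_len(n0)) {
    if (stats::runif(1) < cfg$duplicate_rate) {
      dup <- records[[i]]
      dup$accession <- paste0(dup$accession, "dup")
      dup$is_duplicate <- TRUE
      records[[length(records) + 1L]] <- dup
    }
  }
  acc <- vapply(records, `[[`, character(1), "accession")
  seqs <- stats::setNames(vapply(records, `[[`, character(1), "seq"), acc)
  meta <- data.frame(
    accession = acc,
    domain = vapply(records, `[[`, character(1), "domain"),
    source = vapply(records, `[[`, character(1), "source"))
  survey <- GeneSurvey(seqs, meta)
  fam_tab <- data.frame(
    family = seq_len(cfg$n_families), domain = fam_domain,
    single_source = vapply(fam_sources, length, integer(1)) == 1L)
  fam_tab$sources <- fam_sources
  truth <- list(
    family = stats::setNames(vapply(records, `[[`, numeric(1), "family"),
                             acc),
    is_duplicate = stats::setNames(
      vapply(records, `[[`, logical(1), "is_duplicate"), acc),
    families = fam_tab,
    roots = roots)
  list(survey = survey, truth = truth)
}

#' Build an alignment with a planted maximal-coverage window
#'
#' Constructs a staggered-fragment alignment whose optimal window under
#' the [extractWindow()] rule is known by construction: `k = ceiling(
#' coverage_fraction * n_rows)` core rows span exactly the planted
#' interval gap-free, and the remaining rows are shorter fragments placed
#' elsewhere, so no interval longer than the core reaches the coverage
#' floor and every qualifying interval inside the core is shorter.
#'
#' @param n_rows Total rows (default 10).
#' @param n_cols Alignment width (default 600).
#' @param core_start 0-based start of the planted window (default 150).
#' @param core_length Planted window length (default 277, the bacterial
#'   window geometry; use 161 for the archaeal geometry).
#' @param coverage_fraction Coverage floor the core satisfies
#'   (default 0.5).
#' @param seed Seed for the random bases and fragment placement.
#' @return A list with `alignment` (a [SurveyAlignment-class]) and `truth`
#'   (`start`, `end`, `coverage` of the planted window).
#' @export
plantWindow <- function(n_rows = 10, n_cols = 600, core_start = 150,
                        core_length = 277, coverage_fraction = 0.5,
                        seed = 1) {
  if (core_start + core_length > n_cols)
    stop("planted window exceeds alignment width")
  set.seed(seed)
  k <- as.integer(ceiling(coverage_fraction * n_rows))
  if (k < 1L || k > n_rows) stop("infeasible coverage fraction")
  s <- core_start; e <- core_start + core_length
  rows <- character(n_rows)
  span_row <- function(from, len) {
    r <- rep("-", n_cols)
    r[seq(from + 1L, from + len)] <- sample(.BASES, len, replace = TRUE)
    paste(r, collapse = "")
  }
  for (i in seq_len(k)) rows[i] <- span_row(s, core_length)
  for (i in seq(k + 1L, length.out = n_rows - k)) {
    len <- .resample(seq(10L, max(10L, core_length - 1L)))
    from <- .resample(seq(0L, n_cols - len))
    rows[i] <- span_row(from, len)
  }
  names(rows) <- sprintf("row%02d", seq_len(n_rows))
  list(alignment = new("SurveyAlignment", rows = rows),
       truth = list(start = s, end = e, coverage = k))
}
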
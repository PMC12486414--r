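#' Greedy maximal-coverage archetype/OTU assignment
#'
#' Repeatedly picks the window sequence that matches the largest number of
#' still-unassigned window sequences at identity >= `threshold` as a new
#' archetype, assigns those sequences to it, and repeats until every
#' sequence is assigned (an archetype always matches itself, so the loop
#' terminates). Ties are broken by larger source-cluster size, then by
#' lexicographic id. Membership forms a partition, and every member is
#' within the threshold of its archetype.
#'
#' @param window_seqs Named character vector of ungapped window-region
#'   sequences (names = cluster ids or accessions).
#' @param threshold Identity threshold in `(0, 1]`, default 0.87.
#' @param weights Optional named numeric vector: the number of survey
#'   sequences each window sequence stands for (cluster sizes;
#'   individuals default to 1). Used only for tie-breaking.
#' @return An [OTUSet-class] (empty table for empty input).
#' @export
assignArchetypes <- function(window_seqs, threshold = 0.87, weights = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- length(window_seqs)
  ids <- names(window_seqs)
  if (n && (is.null(ids) || anyDuplicated(ids)))
    stop("window sequences must have unique names")
  if (is.null(weights)) weights <- stats::setNames(rep(1, n), ids)
  w <- rep(1, n); names(w) <- ids
  w[names(weights)] <- weights
  if (n == 0L)
    return(new("OTUSet",
               table = {
                 t <- DataFrame(otu_id = character(0),
                                archetype = character(0), size = integer(0))
                 t$members <- list(); t
               },
               threshold = threshold))
  # symmetric identity-at-threshold match matrix
  match_mat <- diag(TRUE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        hit <- pairwiseIdentity(window_seqs[[i]], window_seqs[[j]]) >=
          threshold
        match_mat[i, j] <- hit
        match_mat[j, i] <- hit
      }
    }
  }
  unassigned <- rep(TRUE, n)
  arch <- character(0)
  members <- list()
  while (any(unassigned)) {
    cover <- colSums(match_mat[unassigned, , drop = FALSE])
    cover[!unassigned] <- -Inf  # archetypes come from unassigned sequences
    best <- max(cover)
    cand <- which(cover == best)
    cand <- cand[order(-w[cand], ids[cand], method = "radix")]
    pick <- cand[1L]
    got <- which(unassigned & match_mat[pick, ])
    arch <- c(arch, ids[pick])
    members <- c(members, list(ids[got]))
    unassigned[got] <- FALSE
  }
  tab <- DataFrame(otu_id = sprintf("OTU%04d", seq_along(arch)),
                   archetype = arch,
                   size = vapply(members, length, integer(1)))
  tab$members <- members
  new("OTUSet", table = tab, threshold = threshold)
}

# Expand OTU members (cluster ids or accessions) to survey accessions.
.otu_accessions <- function(otus, survey, clusters = NULL) {
  cl_members <- list()
  if (!is.null(clusters)) {
    tab <- clusterTable(clusters)
    cl_members <- stats::setNames(as.list(tab$members), tab$cluster_id)
  }
  acc <- names(surveySeqs(survey))
  lapply(stats::setNames(otuTable(otus)$members, otuTable(otus)$otu_id),
         function(mem) {
           out <- unlist(lapply(mem, function(m) {
             if (!is.null(cl_members[[m]])) cl_members[[m]]
             else if (m %in% acc) m
             else stop("OTU member '", m,
                       "' is neither a cluster id nor an accession")
           }), use.names = FALSE)
           out
         })
}

#' Environmental-source profile of each OTU
#'
#' Looks up the source label of every survey sequence represented by each
#' OTU (expanding cluster members through the `ClusterSet`) and reports
#' the distinct sources per OTU.
#'
#' @param otus An [OTUSet-class].
#' @param survey The [GeneSurvey-class] with source labels.
#' @param clusters Optional [ClusterSet-class] used to expand members that
#'   are cluster ids.
#' @return A `data.frame` with columns `otu_id`, `n_seqs`, `n_sources` and
#'   a list column `sources` (sorted distinct source labels).
#' @export
otuSourceProfile <- function(otus, survey, clusters = NULL) {
  stopifnot(is(otus, "OTUSet"), is(survey, "GeneSurvey"))
  meta <- surveyMeta(survey)
  src <- stats::setNames(meta$source, meta$accession)
  accs <- .otu_accessions(otus, survey, clusters)
  srcs <- lapply(accs, function(a) sort(unique(unname(src[a]))))
  out <- data.frame(otu_id = names(accs),
                    n_seqs = vapply(accs, length, integer(1)),
                    n_sources = vapply(srcs, length, integer(1)),
                    row.names = NULL)
  out$sources <- unname(srcs)
  out
}

#' Fraction of OTUs restricted to a single environmental source
#'
#' The headline niche-specificity statistic: the percentage of OTUs whose
#' member sequences all derive from one source category.
#'
#' @param profiles Output of [otuSourceProfile()] (any data.frame with an
#'   `n_sources` column).
#' @return Percentage, rounded to one decimal (half away from zero).
#' @examples
#' singleSourceFraction(data.frame(n_sources = c(1, 1, 1, 2)))  # 75
#' @export
singleSourceFraction <- function(profiles) {
  n <- nrow(profiles)
  if (!n) stop("no OTUs: single-source fraction undefined")
  roundHalfUp(100 * sum(profiles$n_sources == 1) / n, 1)
}

#' Per-source OTU percentage tables
#'
#' For each group (all OTUs, or OTUs grouped by a taxonomy rank), counts
#' how many OTUs represent each environmental source and converts the
#' counts to percentages. Under the default `rule = "all-sources"` an OTU
#' contributes one count to every distinct source among its members (so
#' multi-source OTUs appear under several sources and the denominator is
#' the total number of OTU-source pairs); `rule = "majority"` credits only
#' the most frequent member source (ties alphabetical). Percentages in a
#' breakdown sum to 100 up to rounding.
#'
#' @param otus An [OTUSet-class].
#' @param survey The [GeneSurvey-class].
#' @param clusters Optional [ClusterSet-class] for member expansion.
#' @param group_by `NULL` (one table over all OTUs) or a taxonomy rank in
#'   `c("phylum", "class", "order", "family", "genus")`: OTUs are grouped
#'   by the rank label shared by the majority of their member sequences
#'   ("unknown" if none).
#' @param rule Counting rule, `"all-sources"` (default) or `"majority"`.
#' @param hypersaline Optional character vector of accessions to relabel
#'   post hoc from `aquatic other` to `hypersaline` before counting.
#' @return A `data.frame` with columns `group`, `source`, `n`, `percent`.
#' @export
sourcePercentages <- function(otus, survey, clusters = NULL, group_by = NULL,
                              rule = c("all-sources", "majority"),
                              hypersaline = NULL) {
  rule <- match.arg(rule)
  stopifnot(is(otus, "OTUSet"), is(survey, "GeneSurvey"))
  meta <- surveyMeta(survey)
  src <- stats::setNames(meta$source, meta$accession)
  if (length(hypersaline)) {
    hs <- intersect(hypersaline, names(src)[src == "aquatic other"])
    src[hs] <- "hypersaline"
  }
  accs <- .otu_accessions(otus, survey, clusters)
  grp <- rep("all", length(accs))
  if (!is.null(group_by)) {
    stopifnot(group_by %in% .TAX_RANKS)
    tax <- stats::setNames(meta[[group_by]], meta$accession)
    grp <- vapply(accs, function(a) .majority_label(unname(tax[a])),
                  character(1))
  }
  per_otu_sources <- lapply(accs, function(a) {
    s <- unname(src[a])
    if (rule == "all-sources") sort(unique(s)) else .majority_label(s)
  })
  rows <- do.call(rbind, lapply(seq_along(accs), function(i)
    data.frame(group = grp[i], source = per_otu_sources[[i]])))
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(rows))) ~ group + source,
                          data = rows, FUN = sum)
  agg <- do.call(rbind, lapply(split(agg, agg$group), function(d) {
    d$percent <- roundHalfUp(100 * d$n / sum(d$n), 1)
    d[order(-d$n, d$source), ]
  }))
  rownames(agg) <- NULL
  agg
}

.majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("unknown")
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

#' Consensus taxonomy label of an OTU
#'
#' The most specific taxonomy rank label shared by at least half of the
#' classified member sequences; `"unknown"` when no rank reaches that
#' majority (or no member is classified).
#'
#' @param otus An [OTUSet-class].
#' @param survey The [GeneSurvey-class].
#' @param clusters Optional [ClusterSet-class] for member expansion.
#' @return A `data.frame` with `otu_id`, `rank`, `label`.
#' @export
otuTaxonomy <- function(otus, survey, clusters = NULL) {
  meta <- surveyMeta(survey)
  accs <- .otu_accessions(otus, survey, clusters)
  res <- lapply(accs, function(a) {
    idx <- match(a, meta$accession)
    for (r in rev(.TAX_RANKS)) { # genus -> phylum, most specific first
      lab <- meta[[r]][idx]
      lab <- lab[lab != "unknown"]
      if (!length(lab)) next
      tab <- sort(table(lab), decreasing = TRUE)
      classified <- sum(meta[[r]][idx] != "unknown")
      if (tab[1L] * 2L >= classified)
        return(c(r, names(tab)[1L]))
    }
    c("domain", "unknown")
  })
  data.frame(otu_id = names(accs),
             rank = vapply(res, `[`, character(1), 1L),
             label = vapply(res, `[`, character(1), 2L),
             row.names = NULL)
}
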
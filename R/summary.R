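#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals: 0.05 at one decimal
#' rounds to 0.1, -0.05 to -0.1. Base `round()` rounds half to even, which
#' does not reproduce the percentages conventionally printed in survey
#' tables.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep (default 1).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(24.65)   # 24.7 (round() would give 24.6)
#' roundHalfUp(92.477)  # 92.5
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Bookkeeping percentages from integer survey counts
#'
#' The core of the survey summary: given the integer bookkeeping counts of
#' one domain track, derives the standard percentages (one decimal, half
#' away from zero). Every percentage is a pure function of the stored
#' counts, so printed tables can be re-derived exactly.
#'
#' @param n_clusters Total number of (aquatic) clusters.
#' @param n_large Number of clusters with more than 2 sequences.
#' @param n_seqs Total number of (aquatic) sequences.
#' @param n_seqs_large Sequences contained in the large clusters.
#' @param n_individuals Sequences treated as individual sequences.
#' @param largest_cluster Size of the largest cluster.
#' @return A one-row `data.frame` with the input counts and the derived
#'   percentages `pct_clusters_large`, `pct_clusters_individual`,
#'   `pct_seqs_large`, `pct_seqs_individual`, `pct_largest_cluster`.
#' @examples
#' surveyPercentages(n_clusters = 729, n_large = 180, n_seqs = 2876,
#'                   n_seqs_large = 2314, n_individuals = 562,
#'                   largest_cluster = 167)
#' @export
surveyPercentages <- function(n_clusters, n_large, n_seqs, n_seqs_large,
                              n_individuals, largest_cluster) {
  if (n_clusters < 1 || n_seqs < 1)
    stop("cannot derive percentages from zero clusters or sequences")
  data.frame(
    n_clusters = n_clusters, n_large = n_large, n_seqs = n_seqs,
    n_seqs_large = n_seqs_large, n_individuals = n_individuals,
    largest_cluster = largest_cluster,
    pct_clusters_large = roundHalfUp(100 * n_large / n_clusters),
    pct_clusters_individual = roundHalfUp(
      100 * (n_clusters - n_large) / n_clusters),
    pct_seqs_large = roundHalfUp(100 * n_seqs_large / n_seqs),
    pct_seqs_individual = roundHalfUp(100 * n_individuals / n_seqs),
    pct_largest_cluster = roundHalfUp(100 * largest_cluster / n_seqs))
}

#' Survey bookkeeping summary from pipeline objects
#'
#' Computes the integer counts of a domain track from its clustering and
#' size partition, then derives the percentage table with
#' [surveyPercentages()]. When an [OTUSet-class] is supplied, OTU counts
#' and the largest-OTU size are appended.
#'
#' @param clusters The (aquatic-filtered) [ClusterSet-class] of the track.
#' @param partition Output of [partitionBySize()] on `clusters`.
#' @param otus Optional [OTUSet-class].
#' @return A one-row `data.frame` of counts and percentages.
#' @export
surveySummary <- function(clusters, partition, otus = NULL) {
  stopifnot(is(clusters, "ClusterSet"))
  sizes <- clusterSizes(clusters)
  large_sizes <- clusterSizes(partition$large)
  out <- surveyPercentages(
    n_clusters = length(sizes),
    n_large = length(large_sizes),
    n_seqs = sum(sizes),
    n_seqs_large = sum(large_sizes),
    n_individuals = length(partition$individuals),
    largest_cluster = if (length(sizes)) max(sizes) else 0L)
  if (!is.null(otus)) {
    out$n_otus <- length(otus)
    out$largest_otu <- if (length(otus)) max(otuTable(otus)$size) else 0L
  }
  out
}
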
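#' Greedy identity-threshold clustering (CD-HIT style)
#'
#' Records are processed in descending length order (ties by lexicographic
#' accession). Each record is compared against the representatives of the
#' clusters founded so far, in founding order, and joins the first one
#' whose [pairwiseIdentity()] is at least `threshold`; otherwise it founds
#' a new cluster and becomes its representative. Because processing is by
#' descending length, every representative is the longest member of its
#' cluster, and representatives of distinct clusters are pairwise below
#' the threshold.
#'
#' @param x A [GeneSurvey-class] (deduplicated).
#' @param threshold Identity threshold in `(0, 1]`; default 0.87, the
#'   species-level cutoff established for functional genes such as `amoA`
#'   and used here for `nirK`.
#' @return A [ClusterSet-class].
#' @export
greedyCluster <- function(x, threshold = 0.87) {
  stopifnot(is(x, "GeneSurvey"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  seqs <- as.character(surveySeqs(x))
  acc <- names(seqs)
  ord <- order(-nchar(seqs), acc, method = "radix")
  reps <- character(0)       # representative accessions, founding order
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwiseIdentity(seqs[[i]], seqs[[reps[k]]]) >= threshold) {
        members[[k]] <- c(members[[k]], acc[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, acc[i])
      members[[length(reps)]] <- acc[i]
    }
  }
  tab <- DataFrame(
    cluster_id = sprintf("C%04d", seq_along(reps)),
    representative = reps,
    size = vapply(members, length, integer(1)))
  tab$members <- members
  new("ClusterSet", table = tab, threshold = threshold)
}

#' Retain clusters containing at least one aquatic sequence
#'
#' A cluster is kept exactly when any of its members carries an aquatic
#' source label (see [isAquaticSource()]); clusters of purely terrestrial
#' or animal-microbiome origin are removed from further consideration.
#'
#' @param clusters A [ClusterSet-class].
#' @param survey The [GeneSurvey-class] the members resolve against.
#' @return The filtered `ClusterSet`.
#' @export
filterAquaticClusters <- function(clusters, survey) {
  stopifnot(is(clusters, "ClusterSet"), is(survey, "GeneSurvey"))
  meta <- surveyMeta(survey)
  src <- stats::setNames(meta$source, meta$accession)
  tab <- clusterTable(clusters)
  keep <- vapply(tab$members, function(mem) {
    missing <- setdiff(mem, names(src))
    if (length(missing))
      stop("member accession(s) not in survey: ",
           paste(missing, collapse = ", "))
    any(isAquaticSource(src[mem]))
  }, logical(1))
  if (any(!keep))
    message("removed ", sum(!keep), " cluster(s) with no aquatic member")
  new("ClusterSet", table = tab[keep, , drop = FALSE],
      threshold = clusters@threshold)
}

#' Partition clusters into large clusters and individual sequences
#'
#' Clusters with at least `min_large` members stay clusters; the members
#' of smaller clusters are released and treated as individual sequences
#' identified by their accessions. Total sequence count is conserved.
#' The default `min_large = 3` keeps exactly the clusters with more than
#' 2 sequences.
#'
#' @param clusters A [ClusterSet-class].
#' @param min_large Minimum size for a cluster to stay a cluster.
#' @return A list with `large` (a `ClusterSet`) and `individuals`
#'   (character vector of accessions).
#' @export
partitionBySize <- function(clusters, min_large = 3) {
  stopifnot(is(clusters, "ClusterSet"))
  tab <- clusterTable(clusters)
  big <- tab$size >= min_large
  individuals <- unlist(tab$members[!big], use.names = FALSE)
  if (is.null(individuals)) individuals <- character(0)
  list(large = new("ClusterSet", table = tab[big, , drop = FALSE],
                   threshold = clusters@threshold),
       individuals = individuals)
}

#' Rank-abundance table of cluster sizes
#'
#' Cluster sizes sorted non-increasing against rank, with the cutoff rank
#' separating clusters of more than `unique_max` members from the
#' "unique" clusters (1-2 sequences, treated downstream as individual
#' sequences).
#'
#' @param clusters A [ClusterSet-class].
#' @param unique_max Sizes of at most this many sequences count as unique
#'   (default 2).
#' @return A `data.frame` with columns `rank`, `size`, `cluster_id` and
#'   attribute `unique_cutoff`: the first rank with size <= `unique_max`
#'   (`NA` if none).
#' @export
rankAbundance <- function(clusters, unique_max = 2) {
  stopifnot(is(clusters, "ClusterSet"))
  tab <- clusterTable(clusters)
  ord <- order(-tab$size, tab$cluster_id, method = "radix")
  out <- data.frame(rank = seq_len(nrow(tab)),
                    size = as.integer(tab$size[ord]),
                    cluster_id = tab$cluster_id[ord])
  cut <- which(out$size <= unique_max)
  attr(out, "unique_cutoff") <- if (length(cut)) cut[1L] else NA_integer_
  out
}
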
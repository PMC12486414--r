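#' Majority-rule consensus of an alignment
#'
#' Per column: if the gap fraction exceeds 0.5 the column is dropped;
#' otherwise the most frequent non-gap base is emitted, ties broken
#' alphabetically. The consensus of k identical rows is that row, for any
#' k >= 1.
#'
#' @param alignment A [SurveyAlignment-class].
#' @return The consensus nucleotide string.
#' @examples
#' aln <- new("SurveyAlignment", rows = c(a = "ACGT", b = "ACGT", c = "ATGT"))
#' majorityConsensus(aln)  # "ACGT"
#' @export
majorityConsensus <- function(alignment) {
  stopifnot(is(alignment, "SurveyAlignment"))
  mat <- .aln_matrix(alignment)
  n <- nrow(mat)
  cols <- apply(mat, 2L, function(col) {
    gapfrac <- mean(col == "-")
    if (gapfrac > 0.5) return(NA_character_)
    tab <- table(col[col != "-"])
    # ties broken alphabetically: table() is already sorted by name
    names(tab)[which.max(tab)]
  })
  paste(cols[!is.na(cols)], collapse = "")
}

.aln_matrix <- function(alignment) {
  rows <- alignmentRows(alignment)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  mat
}

#' Per-cluster consensus sequences
#'
#' Aligns the members of each cluster with [centerStarAlign()] and derives
#' a [majorityConsensus()] per cluster. Clusters whose members cannot be
#' aligned meaningfully (mean pairwise identity of members to the center
#' below `min_center_identity`) are set aside whole and reported, mirroring
#' the removal of extremely divergent clusters from downstream analysis.
#'
#' @param survey A [GeneSurvey-class] with the clustered records.
#' @param clusters A [ClusterSet-class]; only clusters of size >= 2 are
#'   aligned (a singleton's consensus is its sequence).
#' @param min_center_identity Divergence guard, default 0.40.
#' @return A list with `consensus` (named character vector, names =
#'   cluster ids) and `divergent` (character vector of set-aside cluster
#'   ids).
#' @export
clusterConsensus <- function(survey, clusters, min_center_identity = 0.40) {
  stopifnot(is(survey, "GeneSurvey"), is(clusters, "ClusterSet"))
  tab <- clusterTable(clusters)
  seqs <- as.character(surveySeqs(survey))
  cons <- character(0)
  divergent <- character(0)
  for (k in seq_len(nrow(tab))) {
    mem <- tab$members[[k]]
    missing <- setdiff(mem, names(seqs))
    if (length(missing))
      stop("cluster member(s) not in survey: ", paste(missing, collapse = ", "))
    if (length(mem) == 1L) {
      cons[tab$cluster_id[k]] <- seqs[[mem]]
      next
    }
    s <- seqs[mem]
    # divergence guard: identity of each member to the cluster representative
    rep_seq <- seqs[[tab$representative[k]]]
    others <- setdiff(mem, tab$representative[k])
    mpid <- mean(vapply(others, function(a)
      pairwiseIdentity(seqs[[a]], rep_seq), numeric(1)))
    if (mpid < min_center_identity) {
      divergent <- c(divergent, tab$cluster_id[k])
      next
    }
    aln <- centerStarAlign(s)
    cons[tab$cluster_id[k]] <- majorityConsensus(aln)
  }
  if (length(divergent))
    message(length(divergent), " cluster(s) set aside: too divergent to align")
  list(consensus = cons, divergent = divergent)
}

#' Extract the maximal-overlap alignment window
#'
#' Among all contiguous column intervals whose coverage is at least
#' `ceil(min_coverage_fraction * n_rows)`, returns the longest; ties are
#' broken by higher coverage, then leftmost start. A row covers an
#' interval when it has a non-gap character at both interval ends and a
#' gap fraction of at most `max_gap_frac` inside. This resolves the
#' bi-objective "longest region where the greatest number of sequences
#' overlap" as: coverage floor first, then maximize length.
#'
#' @param alignment A [SurveyAlignment-class].
#' @param min_coverage_fraction Coverage floor as a fraction of rows
#'   (default 0.5).
#' @param max_gap_frac Maximum internal gap fraction for a row to count as
#'   covering (default 0.1).
#' @return An [AlignmentWindow-class] (0-based, half-open coordinates).
#' @export
extractWindow <- function(alignment, min_coverage_fraction = 0.5,
                          max_gap_frac = 0.1) {
  stopifnot(is(alignment, "SurveyAlignment"))
  mat <- .aln_matrix(alignment)
  gap <- mat == "-"
  min_cover <- as.integer(ceiling(min_coverage_fraction * nrow(mat)))
  res <- .window_search_cpp(gap, max(min_cover, 1L), max_gap_frac)
  if (!isTRUE(res$found))
    stop("no contiguous interval reaches coverage ", min_cover, " of ",
         nrow(mat), " rows; lower min_coverage_fraction")
  new("AlignmentWindow", start = as.integer(res$start),
      end = as.integer(res$end), coverage = as.integer(res$coverage))
}

.row_covers <- function(row_chars, window, max_gap_frac = 0.1) {
  s <- window@start + 1L; e <- window@end # 1-based inclusive
  if (row_chars[s] == "-" || row_chars[e] == "-") return(FALSE)
  mean(row_chars[s:e] == "-") <= max_gap_frac
}

#' Split alignment rows into window-covering and divergent rows
#'
#' Rows failing the coverage rule for the window (non-gap at both window
#' ends, internal gap fraction at most `max_gap_frac`) are excluded: these
#' are the sequences that "do not align" in the window region.
#'
#' @param alignment A [SurveyAlignment-class].
#' @param window An [AlignmentWindow-class] for that alignment.
#' @param max_gap_frac As in [extractWindow()].
#' @return A list with character vectors `kept` and `excluded` (row ids).
#' @export
excludeDivergent <- function(alignment, window, max_gap_frac = 0.1) {
  stopifnot(is(alignment, "SurveyAlignment"), is(window, "AlignmentWindow"))
  if (window@end > ncol(alignment)) stop("window exceeds alignment width")
  mat <- .aln_matrix(alignment)
  ok <- apply(mat, 1L, .row_covers, window = window,
              max_gap_frac = max_gap_frac)
  if (any(!ok))
    message(sum(!ok), " row(s) did not align in the window and were excluded")
  list(kept = rownames(mat)[ok], excluded = rownames(mat)[!ok])
}

#' Ungapped window-region sequences for kept rows
#'
#' Cuts the window columns out of each kept row and removes gaps, yielding
#' the per-row window sequences used for OTU assignment.
#'
#' @inheritParams excludeDivergent
#' @param ids Row ids to extract (default: all kept rows per
#'   [excludeDivergent()]).
#' @return Named character vector of ungapped window sequences.
#' @export
windowSequences <- function(alignment, window, ids = NULL,
                            max_gap_frac = 0.1) {
  if (is.null(ids))
    ids <- excludeDivergent(alignment, window, max_gap_frac)$kept
  rows <- alignmentRows(alignment)[ids]
  out <- substr(rows, window@start + 1L, window@end)
  vapply(out, .degap, character(1), USE.NAMES = FALSE) |>
    stats::setNames(ids)
}

#' Report a window in 1-based inclusive coordinates
#'
#' Internally all coordinates are 0-based half-open; reports use the
#' 1-based inclusive convention common in the genetics literature.
#'
#' @param window An [AlignmentWindow-class].
#' @return A one-row `data.frame` with `start`, `end`, `length`,
#'   `coverage` (1-based inclusive start/end).
#' @export
windowReport <- function(window) {
  data.frame(start = window@start + 1L, end = window@end,
             length = window@end - window@start, coverage = window@coverage)
}
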
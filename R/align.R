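#' Pairwise global alignment with free end gaps
#'
#' Needleman-Wunsch alignment with free terminal gaps (overlap alignment):
#' match +1 for an identical `A`/`C`/`G`/`T` pair, -1 otherwise (ambiguity
#' codes and `N` never match), -2 per internal gap position. Among all
#' score-optimal alignments the reported match count is the maximum
#' attainable one, so identity values do not depend on traceback
#' tie-breaking.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @return A list with `score`, `matches`, and the gapped strings
#'   `aligned_a`, `aligned_b`.
#' @seealso [pairwiseIdentity()]
#' @export
nwAlign <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .nw_align_cpp(a, b)
}

#' Pairwise sequence identity (shorter-sequence convention)
#'
#' Identity between two nucleotide sequences under the free-end-gap global
#' alignment of [nwAlign()]:
#' number of identical aligned positions divided by the length of the
#' shorter sequence — the convention used by CD-HIT, which lets a fragment
#' nested in a full-length gene score as identical.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @return Identity fraction in `[0, 1]`; symmetric, and 1 for identical
#'   sequences.
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGT")  # 1
#' pairwiseIdentity("AAAA", "TTTT")          # 0
#' @export
pairwiseIdentity <- function(a, b) {
  al <- nwAlign(a, b)
  al$matches / min(nchar(a), nchar(b))
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Center-star multiple sequence alignment
#'
#' Picks the center sequence (maximum summed pairwise identity to all
#' others; ties by input order), aligns every other sequence to the center
#' with [nwAlign()], and merges the pairwise alignments under the
#' "once a gap, always a gap" rule. De-gapping any row reproduces its input
#' sequence exactly. Deterministic and adequate at the identity levels
#' used for within-cluster alignment; not a progressive aligner.
#'
#' @param sequences Named character vector of >= 2 nucleotide sequences.
#' @param center Optional: `"identity"` (default; maximize summed pairwise
#'   identity) or `"length"` (use the longest sequence, cheaper for large
#'   row sets).
#' @return A [SurveyAlignment-class] with one row per input, in input order.
#' @examples
#' aln <- centerStarAlign(c(x = "ACGT", y = "ACT"))
#' alignmentRows(aln)
#' @export
centerStarAlign <- function(sequences, center = c("identity", "length")) {
  center <- match.arg(center)
  ids <- names(sequences)
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 2L) stop("center-star alignment needs >= 2 sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  names(sequences) <- ids
  if (center == "identity") {
    idsum <- numeric(n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        pid <- pairwiseIdentity(sequences[i], sequences[j])
        idsum[i] <- idsum[i] + pid
        idsum[j] <- idsum[j] + pid
      }
    }
    ci <- which.max(idsum)
  } else {
    ci <- which.max(nchar(sequences))
  }

  cen <- sequences[ci]
  # master center row as a character vector; gaps inserted as we merge
  master <- strsplit(cen, "")[[1L]]
  rows <- list()
  for (i in seq_len(n)) {
    if (i == ci) next
    al <- nwAlign(cen, sequences[i])
    pa <- strsplit(al$aligned_a, "")[[1L]] # center with this pair's gaps
    pb <- strsplit(al$aligned_b, "")[[1L]]
    # merge pair alignment into master coordinates
    res <- .merge_into_master(master, pa, pb, rows)
    master <- res$master
    rows <- res$rows
    rows[[ids[i]]] <- res$new_row
  }
  width <- length(master)
  pad <- function(r) {
    if (length(r) < width) c(r, rep("-", width - length(r))) else r
  }
  out <- c(stats::setNames(list(master), ids[ci]), rows)
  out <- vapply(out[ids], function(r) paste(pad(r), collapse = ""),
                character(1))
  new("SurveyAlignment", rows = out)
}

# Merge one pairwise alignment (center pa vs new sequence pb) into the
# running master alignment. master holds the center row with all gaps
# accumulated so far; rows are the already-merged non-center rows. "Once a
# gap, always a gap": new gaps needed by this pair are inserted into master
# and into every existing row.
.merge_into_master <- function(master, pa, pb, rows) {
  mi <- 1L; pi <- 1L
  new_master <- character(0)
  new_row <- character(0)
  ins <- integer(0) # positions (in old master coords) where a gap opened
  nm <- length(master); np <- length(pa)
  while (mi <= nm || pi <= np) {
    mc <- if (mi <= nm) master[mi] else NULL
    pc <- if (pi <= np) pa[pi] else NULL
    if (!is.null(mc) && mc == "-" && (is.null(pc) || pc != "-")) {
      # master has a gap this pair does not: keep it, pad the new row
      new_master <- c(new_master, "-")
      new_row <- c(new_row, "-")
      mi <- mi + 1L
    } else if (!is.null(pc) && pc == "-" && (is.null(mc) || mc != "-")) {
      # this pair opens a gap the master lacks: insert into master and all
      # previously merged rows
      new_master <- c(new_master, "-")
      new_row <- c(new_row, pb[pi])
      ins <- c(ins, mi)
      pi <- pi + 1L
    } else {
      # both non-gap (same center base) or both gap
      new_master <- c(new_master, mc)
      new_row <- c(new_row, pb[pi])
      mi <- mi + 1L
      pi <- pi + 1L
    }
  }
  if (length(ins) && length(rows)) {
    rows <- lapply(rows, function(r) {
      out <- character(length(r) + length(ins))
      take <- rep(TRUE, length(r) + length(ins))
      # insert gaps before old positions in 'ins' (counted with multiplicity)
      pos <- ins + seq_along(ins) - 1L
      take[pos] <- FALSE
      out[take] <- r
      out[!take] <- "-"
      out
    })
  }
  list(master = new_master, rows = rows, new_row = new_row)
}

#' Master alignment of consensus and individual sequences
#'
#' One alignment containing every cluster consensus and every individual
#' sequence as a row, built with the center-star aligner. With many rows
#' the center is chosen as the longest sequence (documented in
#' [centerStarAlign()]).
#'
#' @param consensus_seqs Named character vector of cluster consensus
#'   sequences (names = cluster ids).
#' @param individual_seqs Named character vector of individual sequences
#'   (names = accessions).
#' @param center Passed to [centerStarAlign()]; default `"length"`.
#' @return A [SurveyAlignment-class].
#' @export
buildMasterAlignment <- function(consensus_seqs, individual_seqs,
                                 center = "length") {
  seqs <- c(consensus_seqs, individual_seqs)
  if (length(seqs) < 2L) stop("need >= 2 sequences in total")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("consensus and individual sequence names must be unique")
  centerStarAlign(seqs, center = center)
}
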
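#' Jukes-Cantor distance matrix from an alignment
#'
#' For every pair of rows, gap columns are deleted pairwise (a column is
#' used only when both rows are non-gap there) and the mismatch fraction
#' `p` over the shared columns is converted to the Jukes-Cantor distance
#' `d = -(3/4) * log(1 - (4/3) * p)`. Saturated pairs (`p >= 0.75`) are
#' capped at `max_distance` with a warning so the matrix stays finite.
#'
#' @param alignment A [SurveyAlignment-class] of the window region.
#' @param max_distance Cap for saturated pairs (default 5).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = row
#'   ids.
#' @export
jcDistance <- function(alignment, max_distance = 5) {
  stopifnot(is(alignment, "SurveyAlignment"))
  mat <- .aln_matrix(alignment)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  saturated <- FALSE
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- mat[i, ] != "-" & mat[j, ] != "-"
        if (sum(shared) < 2L)
          stop("rows '", rownames(mat)[i], "' and '", rownames(mat)[j],
               "' share fewer than 2 non-gap columns")
        p <- mean(mat[i, shared] != mat[j, shared])
        if (p >= 0.75) {
          saturated <- TRUE
          dij <- max_distance
        } else {
          dij <- min(-0.75 * log(1 - 4 * p / 3), max_distance)
        }
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  if (saturated)
    warning("saturated pair(s) (p >= 0.75) capped at ", max_distance)
  d
}

#' Neighbor-joining tree of OTU representatives
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) on a
#' symmetric distance matrix; on an additive (four-point-condition)
#' matrix it recovers the generating topology and branch lengths exactly.
#' Distance-based inference replaces likelihood tree building here: it is
#' deterministic, desk-scale, and sufficient for clade-level structure.
#'
#' @param d Symmetric numeric matrix (>= 3 taxa) with zero diagonal, or a
#'   `dist` object.
#' @return An unrooted `phylo` tree; negative branch lengths (a known NJ
#'   artifact on noisy matrices) are clamped to zero.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write / read a Newick tree
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; branch
#' lengths survive a write-read round trip to at least 6 decimals and
#' no internal node labels are written by default.
#'
#' @param tree A `phylo` object.
#' @param path Output (or input) file path.
#' @return `writeNewick` invisibly returns `path`; `readNewick` returns a
#'   `phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Leaf annotation table for external tree viewers
#'
#' Emits a simple `otu_id` / `source` color-key table (one row per leaf
#' per distinct source) so trees can be annotated by environmental source
#' in external viewers.
#'
#' @param otus An [OTUSet-class].
#' @param profiles Output of [otuSourceProfile()] for those OTUs.
#' @return A `data.frame` with `otu_id` and `source`.
#' @export
leafAnnotation <- function(otus, profiles) {
  stopifnot(is(otus, "OTUSet"))
  do.call(rbind, lapply(seq_len(nrow(profiles)), function(i)
    data.frame(otu_id = profiles$otu_id[i],
               source = profiles$sources[[i]])))
}
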
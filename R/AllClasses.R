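#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Controlled vocabulary of environmental source labels
#'
#' The nine environmental source categories used throughout the survey.
#' All categories except `terrestrial` and `animal` are considered aquatic.
#'
#' @return Character vector of the nine source labels.
#' @examples
#' sourceLevels()
#' @export
sourceLevels <- function() {
  c("marine sediment", "marine water column", "marine OMZ",
    "freshwater and estuary", "hydrothermal vent", "wastewater",
    "aquatic other", "terrestrial", "animal")
}

#' Is a source label aquatic?
#'
#' Pure function of the category: every source except `terrestrial` and
#' `animal` (animal microbiome) counts as marine/aquatic.
#'
#' @param source Character vector of source labels (see [sourceLevels()]).
#' @return Logical vector.
#' @examples
#' isAquaticSource(c("marine sediment", "terrestrial"))
#' @export
isAquaticSource <- function(source) {
  stopifnot(all(source %in% sourceLevels()))
  !(source %in% c("terrestrial", "animal"))
}

.TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

#' GeneSurvey: gene sequences with survey metadata
#'
#' Container pairing a [Biostrings::DNAStringSet] of gene sequences with a
#' per-record metadata table (accession, domain, environmental source and
#' optional taxonomy ranks). Accessions are unique and name the sequences.
#'
#' @slot seqs A `DNAStringSet`, names are accessions.
#' @slot meta A `DataFrame` with columns `accession`, `domain` (Bacteria or
#'   Archaea), `source` (one of [sourceLevels()]) and taxonomy ranks
#'   `phylum`, `class`, `order`, `family`, `genus` (`"unknown"` allowed).
#'
#' @export
setClass("GeneSurvey", slots = c(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("GeneSurvey", function(object) {
  msg <- character()
  acc <- names(object@seqs)
  if (length(object@seqs) != nrow(object@meta))
    msg <- c(msg, "sequence and metadata row counts differ")
  if (is.null(acc) || anyNA(acc) || any(!nzchar(acc)))
    msg <- c(msg, "every sequence must be named by a non-empty accession")
  else if (anyDuplicated(acc))
    msg <- c(msg, "accessions must be unique")
  need <- c("accession", "domain", "source", .TAX_RANKS)
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("metadata must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (!identical(acc, object@meta$accession))
      msg <- c(msg, "metadata accessions must match sequence names in order")
    if (!all(object@meta$domain %in% c("Bacteria", "Archaea")))
      msg <- c(msg, "domain must be 'Bacteria' or 'Archaea'")
    if (!all(object@meta$source %in% sourceLevels()))
      msg <- c(msg, "source must be one of the nine controlled labels")
  }
  if (length(object@seqs) && any(Biostrings::width(object@seqs) < 1L))
    msg <- c(msg, "sequences must have length >= 1")
  if (length(msg)) msg else TRUE
})

#' ClusterSet: identity-threshold clusters of survey records
#'
#' Result of greedy identity clustering. Each cluster has a representative
#' (the longest member, the greedy founder), a member list and a size.
#'
#' @slot table A `DataFrame` with columns `cluster_id`, `representative`,
#'   `size` and a list column `members` (character vectors of accessions,
#'   representative included).
#' @slot threshold Numeric identity threshold used for clustering.
#'
#' @export
setClass("ClusterSet", slots = c(table = "DataFrame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  need <- c("cluster_id", "representative", "size", "members")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("cluster table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    sz <- vapply(object@table$members, length, integer(1))
    if (!identical(as.integer(object@table$size), sz))
      msg <- c(msg, "size must equal the number of members")
    if (nrow(object@table) && any(sz < 1L))
      msg <- c(msg, "clusters must have size >= 1")
    ok <- mapply(function(rep, mem) rep %in% mem,
                 object@table$representative, object@table$members)
    if (nrow(object@table) && !all(ok))
      msg <- c(msg, "representative must be among members")
  }
  if (length(object@threshold) != 1L ||
      object@threshold <= 0 || object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SurveyAlignment: a simple multiple sequence alignment
#'
#' Gapped, equal-width rows keyed by sequence id. De-gapping a row always
#' reproduces the source sequence (validity does not re-check this against
#' the originals, but every aligner in the package guarantees it).
#'
#' @slot rows Named character vector of gapped rows (gap = `-`).
#'
#' @export
setClass("SurveyAlignment", slots = c(rows = "character"))

setValidity("SurveyAlignment", function(object) {
  msg <- character()
  if (length(object@rows) < 1L) msg <- c(msg, "alignment needs >= 1 row")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    msg <- c(msg, "rows must have unique names")
  if (length(unique(nchar(object@rows))) > 1L)
    msg <- c(msg, "all rows must have equal width")
  if (length(msg)) msg else TRUE
})

#' AlignmentWindow: a contiguous column interval of an alignment
#'
#' 0-based half-open interval `[start, end)` together with the number of
#' rows covering it (non-gap at both ends, bounded internal gap fraction).
#'
#' @slot start,end Integer column bounds, 0-based half-open.
#' @slot coverage Integer number of covering rows.
#'
#' @export
setClass("AlignmentWindow",
         slots = c(start = "integer", end = "integer", coverage = "integer"))

setValidity("AlignmentWindow", function(object) {
  msg <- character()
  if (object@start < 0L || object@end <= object@start)
    msg <- c(msg, "need 0 <= start < end")
  if (object@coverage < 1L) msg <- c(msg, "coverage must be >= 1")
  if (length(msg)) msg else TRUE
})

#' OTUSet: operational taxonomic units over window sequences
#'
#' Greedy maximal-coverage archetype assignment at an identity threshold.
#' Members are ids of window sequences (cluster consensus ids or individual
#' accessions); every member is within the threshold of its archetype.
#'
#' @slot table A `DataFrame` with columns `otu_id`, `archetype`, `size` and
#'   list column `members`.
#' @slot threshold Numeric identity threshold.
#'
#' @export
setClass("OTUSet", slots = c(table = "DataFrame", threshold = "numeric"))

setValidity("OTUSet", function(object) {
  msg <- character()
  need <- c("otu_id", "archetype", "size", "members")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("OTU table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    sz <- vapply(object@table$members, length, integer(1))
    if (!identical(as.integer(object@table$size), sz))
      msg <- c(msg, "size must equal the number of members")
  }
  if (length(msg)) msg else TRUE
})
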
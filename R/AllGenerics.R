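#' @rdname GeneSurvey-class
#' @param object,x A package object.
#' @export
setGeneric("surveySeqs", function(x) standardGeneric("surveySeqs"))

#' @rdname GeneSurvey-class
#' @export
setGeneric("surveyMeta", function(x) standardGeneric("surveyMeta"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname OTUSet-class
#' @export
setGeneric("otuTable", function(x) standardGeneric("otuTable"))

#' @rdname SurveyAlignment-class
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

# ---- accessors ----

#' @rdname GeneSurvey-class
#' @export
setMethod("surveySeqs", "GeneSurvey", function(x) x@seqs)

#' @rdname GeneSurvey-class
#' @export
setMethod("surveyMeta", "GeneSurvey", function(x) x@meta)

#' @rdname GeneSurvey-class
#' @export
setMethod("length", "GeneSurvey", function(x) length(x@seqs))

#' @rdname GeneSurvey-class
#' @export
setMethod("names", "GeneSurvey", function(x) names(x@seqs))

#' @rdname GeneSurvey-class
#' @param i Index (accessions, logical or integer positions).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "GeneSurvey", function(x, i, j, ..., drop = TRUE) {
  new("GeneSurvey", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' @rdname ClusterSet-class
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@table)

#' @rdname ClusterSet-class
#' @export
setMethod("clusterSizes", "ClusterSet",
          function(x) stats::setNames(as.integer(x@table$size),
                                      x@table$cluster_id))

#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@table))

#' @rdname OTUSet-class
#' @export
setMethod("otuTable", "OTUSet", function(x) x@table)

#' @rdname OTUSet-class
#' @export
setMethod("length", "OTUSet", function(x) nrow(x@table))

#' @rdname SurveyAlignment-class
#' @export
setMethod("alignmentRows", "SurveyAlignment", function(x) x@rows)

#' @rdname SurveyAlignment-class
#' @export
setMethod("ncol", "SurveyAlignment",
          function(x) nchar(x@rows[[1L]]))

#' @rdname SurveyAlignment-class
#' @export
setMethod("nrow", "SurveyAlignment", function(x) length(x@rows))

# ---- show methods ----

setMethod("show", "GeneSurvey", function(object) {
  m <- object@meta
  cat("GeneSurvey with", length(object@seqs), "records\n")
  if (length(object@seqs)) {
    cat("  domains:",
        paste(sprintf("%s (%d)", names(table(m$domain)), table(m$domain)),
              collapse = ", "), "\n")
    cat("  length range:", paste(range(Biostrings::width(object@seqs)),
                                 collapse = "-"), "bp\n")
    cat("  sources:", length(unique(m$source)), "distinct\n")
  }
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@table), "clusters at",
      sprintf("%.0f%%", 100 * object@threshold), "identity\n")
  if (nrow(object@table))
    cat("  sizes:", paste(utils::head(sort(object@table$size,
                                           decreasing = TRUE), 8),
                          collapse = " "),
        if (nrow(object@table) > 8) "..." else "", "\n")
})

setMethod("show", "SurveyAlignment", function(object) {
  cat("SurveyAlignment:", length(object@rows), "rows x",
      nchar(object@rows[[1L]]), "columns\n")
})

setMethod("show", "AlignmentWindow", function(object) {
  cat(sprintf("AlignmentWindow [%d, %d) length %d, coverage %d\n",
              object@start, object@end, object@end - object@start,
              object@coverage))
})

setMethod("show", "OTUSet", function(object) {
  cat("OTUSet:", nrow(object@table), "OTUs at",
      sprintf("%.0f%%", 100 * object@threshold), "identity\n")
})
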
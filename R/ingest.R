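#' Construct a GeneSurvey from sequences and metadata
#'
#' Sequences are normalized on construction: uppercased and RNA-style `U`
#' converted to `T` (public database exports mix cases and alphabets).
#' Eukaryota records are dropped with a message; only Bacteria and Archaea
#' are carried through the survey.
#'
#' @param seqs Named character vector or `DNAStringSet`; names = accessions.
#' @param meta `data.frame` or `DataFrame` with columns `accession`,
#'   `domain`, `source` and optionally `phylum`, `class`, `order`, `family`,
#'   `genus` (`NA` or missing ranks become `"unknown"`). Rows are matched to
#'   sequences by accession.
#' @return A [GeneSurvey-class] object, records in sequence order.
#' @examples
#' gs <- GeneSurvey(c(s1 = "ACGTACGT", s2 = "ACGTTTTT"),
#'   data.frame(accession = c("s1", "s2"), domain = "Bacteria",
#'              source = "marine sediment"))
#' gs
#' @export
GeneSurvey <- function(seqs, meta) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by accession")
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  meta <- as.data.frame(meta)
  need <- c("accession", "domain", "source")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  missing_rows <- setdiff(names(seqs), meta$accession)
  if (length(missing_rows))
    stop("no metadata row for accession(s): ",
         paste(missing_rows, collapse = ", "))
  meta <- meta[match(names(seqs), meta$accession), , drop = FALSE]
  for (r in .TAX_RANKS) {
    if (!r %in% colnames(meta)) meta[[r]] <- "unknown"
    meta[[r]][is.na(meta[[r]])] <- "unknown"
  }
  euk <- meta$domain == "Eukaryota"
  if (any(euk)) {
    message("dropping ", sum(euk), " Eukaryota record(s)")
    seqs <- seqs[!euk]
    meta <- meta[!euk, , drop = FALSE]
  }
  meta <- DataFrame(meta[, c("accession", "domain", "source", .TAX_RANKS)])
  rownames(meta) <- NULL
  new("GeneSurvey", seqs = Biostrings::DNAStringSet(seqs), meta = meta)
}

.check_fasta_lines <- function(lines, path) {
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("malformed FASTA '", path, "': file is empty")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA '", path, "': line ", first,
         " does not start a record ('>' expected)")
  bad <- grep("^[^>].*>", trimws(lines[nonblank]))
  if (length(bad)) {
    ln <- nonblank[bad[1L]]
    stop("malformed FASTA '", path, "': line ", ln,
         " contains '>' inside a sequence line")
  }
  invisible(TRUE)
}

#' Read a survey from a FASTA file and a metadata table
#'
#' FASTA ids (first whitespace-delimited token of each header) must resolve
#' 1:1 against metadata rows keyed by `accession`; a FASTA id without a
#' metadata row is a hard error naming the accession. Records are returned
#' in file order.
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param metadata_path Path to a tab-separated table with header
#'   `accession domain source phylum class order family genus`
#'   (`NA` for unknown ranks; taxonomy columns optional).
#' @return A [GeneSurvey-class] object.
#' @examples
#' fa <- system.file("extdata", "toy_survey.fasta", package = "GeneSurvey")
#' tsv <- system.file("extdata", "toy_survey.tsv", package = "GeneSurvey")
#' readSurvey(fa, tsv)
#' @export
readSurvey <- function(fasta_path, metadata_path) {
  .check_fasta_lines(readLines(fasta_path, warn = FALSE), fasta_path)
  dss <- Biostrings::readDNAStringSet(fasta_path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE,
                            na.strings = "NA", check.names = FALSE)
  GeneSurvey(dss, meta)
}

#' Write a survey back to FASTA + TSV
#'
#' Inverse of [readSurvey()]: `readSurvey(fasta, tsv)` on the written files
#' reproduces the survey exactly.
#'
#' @param x A [GeneSurvey-class] object.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `x`.
#' @export
writeSurvey <- function(x, fasta_path, metadata_path) {
  stopifnot(is(x, "GeneSurvey"))
  Biostrings::writeXStringSet(surveySeqs(x), fasta_path)
  utils::write.table(as.data.frame(surveyMeta(x)), metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Remove duplicate sequences, keeping the first instance
#'
#' Two records are duplicates when their (normalized, uppercased)
#' nucleotide strings are identical; the accession plays no part in the
#' key. For each duplicate set the earliest record survives and the
#' relative order of survivors is preserved, so the operation is
#' idempotent and order-preserving.
#'
#' @param x A [GeneSurvey-class] object.
#' @return A `GeneSurvey` without duplicate sequences.
#' @examples
#' gs <- GeneSurvey(c(a = "ACGT", b = "ACGT", c = "AAAA"),
#'   data.frame(accession = c("a", "b", "c"), domain = "Bacteria",
#'              source = "marine sediment"))
#' names(deduplicate(gs))  # "a" "c"
#' @export
deduplicate <- function(x) {
  stopifnot(is(x, "GeneSurvey"))
  keep <- !duplicated(as.character(surveySeqs(x)))
  if (any(!keep))
    message("removed ", sum(!keep), " duplicate sequence(s), kept first ",
            "instance of each")
  x[keep]
}

#' Filter records by domain-specific minimum length
#'
#' Bacterial records shorter than `min_bacteria` and archaeal records
#' shorter than `min_archaea` are removed; both thresholds are inclusive
#' (a bacterial record of exactly `min_bacteria` bp is retained).
#'
#' @param x A [GeneSurvey-class] object.
#' @param min_bacteria,min_archaea Inclusive minimum lengths in bp
#'   (defaults 400 and 300).
#' @return The filtered `GeneSurvey`.
#' @export
filterByLength <- function(x, min_bacteria = 400, min_archaea = 300) {
  stopifnot(is(x, "GeneSurvey"))
  dom <- surveyMeta(x)$domain
  if (anyNA(dom) || !all(dom %in% c("Bacteria", "Archaea")))
    stop("every record must have domain Bacteria or Archaea")
  w <- Biostrings::width(surveySeqs(x))
  keep <- ifelse(dom == "Bacteria", w >= min_bacteria, w >= min_archaea)
  if (any(!keep))
    message("removed ", sum(!keep), " record(s) below the length floor (",
            sum(!keep & dom == "Bacteria"), " bacterial, ",
            sum(!keep & dom == "Archaea"), " archaeal)")
  x[keep]
}
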
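# Independent oracles and small fixture builders used across the suite.

.B <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.B, n, replace = TRUE), collapse = "")

mutate_seq <- function(seq, r) {
  x <- strsplit(seq, "")[[1L]]
  hit <- runif(length(x)) < r
  x[hit] <- vapply(x[hit], function(b) sample(setdiff(.B, b), 1L),
                   character(1))
  paste(x, collapse = "")
}

# Pure-R dynamic-programming oracle for the free-end-gap global alignment:
# same scoring contract as the package (match +1 on identical ACGT,
# mismatch -1, gap -2/position, free terminal gaps), with the match count
# maximized over all score-optimal alignments. Independent implementation
# (matrix DP, no traceback).
nw_oracle <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1L]]; b <- strsplit(toupper(b), "")[[1L]]
  m <- length(a); n <- length(b)
  H <- matrix(0L, m + 1L, n + 1L)
  M <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (a[i] == b[j] && a[i] %in% .B) 1L else -1L
      mm <- if (s > 0L) 1L else 0L
      cand_h <- c(H[i, j] + s, H[i, j + 1L] - 2L, H[i + 1L, j] - 2L)
      cand_m <- c(M[i, j] + mm, M[i, j + 1L], M[i + 1L, j])
      h <- max(cand_h)
      H[i + 1L, j + 1L] <- h
      M[i + 1L, j + 1L] <- max(cand_m[cand_h == h])
    }
  }
  ends_h <- c(H[, n + 1L], H[m + 1L, seq_len(n)])
  ends_m <- c(M[, n + 1L], M[m + 1L, seq_len(n)])
  best <- max(ends_h)
  list(score = best, matches = max(ends_m[ends_h == best]))
}

identity_oracle <- function(a, b) {
  nw_oracle(a, b)$matches / min(nchar(a), nchar(b))
}

# All-pairs single-linkage clustering oracle at an identity threshold:
# connected components of the >= threshold graph.
single_linkage_oracle <- function(seqs, threshold) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (pairwiseIdentity(seqs[[i]], seqs[[j]]) >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  setNames(match(comp, unique(comp)), names(seqs))
}

# Exhaustive interval-search oracle for window extraction (same coverage
# rule as the package, re-implemented in plain R).
window_oracle <- function(rows, min_coverage_fraction = 0.5,
                          max_gap_frac = 0.1) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  gap <- mat == "-"
  R <- nrow(gap); C <- ncol(gap)
  k <- ceiling(min_coverage_fraction * R)
  pg <- cbind(0L, t(apply(gap, 1L, cumsum)))
  best <- NULL
  for (s in seq_len(C)) {
    for (e in s:C) {
      len <- e - s + 1L
      covers <- !gap[, s] & !gap[, e] &
        (pg[, e + 1L] - pg[, s]) <= max_gap_frac * len
      cov <- sum(covers)
      if (cov < k) next
      if (is.null(best) || len > best$len ||
          (len == best$len && cov > best$cov)) {
        best <- list(start = s - 1L, end = e, len = len, cov = cov)
      }
    }
  }
  best
}

# survey of a few hand-made records
toy_survey <- function() {
  GeneSurvey(
    c(b1 = strrep("ACGT", 120), b2 = strrep("ACGT", 110),
      b3 = paste0(strrep("AC", 220), strrep("GT", 10)),
      a1 = strrep("TTGCA", 70), a2 = strrep("TTGCA", 62)),
    data.frame(accession = c("b1", "b2", "b3", "a1", "a2"),
               domain = c("Bacteria", "Bacteria", "Bacteria",
                          "Archaea", "Archaea"),
               source = c("marine sediment", "terrestrial",
                          "marine water column", "aquatic other",
                          "freshwater and estuary")))
}

# ClusterSet built directly from a vector of sizes (dummy members)
cluster_set_from_sizes <- function(sizes, threshold = 0.87) {
  members <- lapply(seq_along(sizes), function(i)
    sprintf("s%04d_%03d", i, seq_len(sizes[i])))
  tab <- S4Vectors::DataFrame(
    cluster_id = sprintf("C%04d", seq_along(sizes)),
    representative = vapply(members, `[`, character(1), 1L),
    size = as.integer(sizes))
  tab$members <- members
  new("ClusterSet", table = tab, threshold = threshold)
}

write_toy_files <- function(dir, seqs, meta) {
  fa <- file.path(dir, "toy.fasta")
  tsv <- file.path(dir, "toy.tsv")
  writeLines(unlist(lapply(names(seqs), function(a)
    c(paste0(">", a), seqs[[a]]))), fa)
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, meta = tsv)
}
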
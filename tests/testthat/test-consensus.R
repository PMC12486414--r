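column_identity <- function(aln) {
  mat <- do.call(rbind, strsplit(unname(alignmentRows(aln)), ""))
  mean(apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) < 2) return(NA)
    max(table(col)) / length(col)
  }), na.rm = TRUE)
}

test_that("center-star alignment handles identical and near pairs", {
  aln <- centerStarAlign(c(p = "ACGTACGT", q = "ACGTACGT"))
  expect_identical(unname(alignmentRows(aln)),
                   c("ACGTACGT", "ACGTACGT")) # gap-free
  aln2 <- centerStarAlign(c(x = "ACGT", y = "ACT"))
  rows <- alignmentRows(aln2)
  expect_identical(nchar(rows[["x"]]), 4L)
  expect_identical(rows[["x"]], "ACGT")
  expect_identical(sum(strsplit(rows[["y"]], "")[[1]] == "-"), 1L)
  # pairwise DP oracle agreement on the gap placement score
  expect_identical(nwAlign("ACGT", "ACT")$matches, nw_oracle("ACGT", "ACT")$matches)
})

test_that("rows of a center-star alignment de-gap to their inputs", {
  set.seed(21)
  anc <- random_dna(200)
  seqs <- setNames(c(vapply(1:6, function(i) mutate_seq(anc, 0.05),
                            character(1)),
                     substr(anc, 30, 150)), # one fragment
                   paste0("s", 1:7))
  aln <- centerStarAlign(seqs)
  expect_identical(length(unique(nchar(alignmentRows(aln)))), 1L)
  for (id in names(seqs))
    expect_identical(gsub("-", "", alignmentRows(aln)[[id]], fixed = TRUE),
                     unname(seqs[[id]]))
})

test_that("a 5%-mutated family aligns with high mean column identity", {
  set.seed(2)
  anc <- random_dna(300)
  seqs <- setNames(vapply(1:10, function(i) mutate_seq(anc, 0.05),
                          character(1)), paste0("m", 1:10))
  aln <- centerStarAlign(seqs)
  expect_gte(column_identity(aln), 0.85)
})

test_that("majority consensus follows per-column plurality with gap dropping", {
  aln <- new("SurveyAlignment",
             rows = c(r1 = "ACGT", r2 = "ACGT", r3 = "ACGT"))
  expect_identical(majorityConsensus(aln), "ACGT")
  # column {A, A, T} -> A; gap-majority column dropped; tie -> alphabetical
  aln2 <- new("SurveyAlignment", rows = c(a = "AA-C", b = "AA-G",
                                          c = "TAAC"))
  # col1 {A,A,T}->A; col2 {A,A,A}->A; col3 gap frac 2/3 -> dropped;
  # col4 {C,G,C}->C
  expect_identical(majorityConsensus(aln2), "AAC")
  tie <- new("SurveyAlignment", rows = c(a = "G", b = "T"))
  expect_identical(majorityConsensus(tie), "G") # alphabetical tie-break
  one <- new("SurveyAlignment", rows = c(solo = "ACGT"))
  expect_identical(majorityConsensus(one), "ACGT")
})

test_that("consensus recovers the ancestor of a simulated cluster", {
  set.seed(22)
  anc <- random_dna(400)
  seqs <- setNames(vapply(1:20, function(i) mutate_seq(anc, 0.05),
                          character(1)), paste0("c", 1:20))
  cons <- majorityConsensus(centerStarAlign(seqs))
  al <- nwAlign(cons, anc)
  expect_gte(al$matches / nchar(anc), 0.99)
})

test_that("window extraction: gap-free alignment gives the whole alignment", {
  aln <- new("SurveyAlignment",
             rows = setNames(replicate(4, random_dna(50)), paste0("r", 1:4)))
  w <- extractWindow(aln)
  expect_identical(c(w@start, w@end), c(0L, 50L))
  expect_identical(w@coverage, 4L)
})

test_that("window extraction matches the exhaustive-interval oracle on staggered rows", {
  span_row <- function(n, from, to) { # inclusive 0-based columns
    r <- rep("-", n)
    r[(from + 1):(to + 1)] <- sample(c("A", "C", "G", "T"),
                                     to - from + 1, TRUE)
    paste(r, collapse = "")
  }
  set.seed(31)
  rows <- c(r1 = span_row(101, 0, 50), r2 = span_row(101, 25, 75),
            r3 = span_row(101, 40, 100))
  aln <- new("SurveyAlignment", rows = rows)
  w <- extractWindow(aln, min_coverage_fraction = 2 / 3)
  o <- window_oracle(rows, 2 / 3)
  expect_identical(c(w@start, w@end, w@coverage),
                   c(o$start, o$end, o$cov))
  # coverage-floor-first, longest-interval rule: the two-row overlap
  # [40, 76) beats the three-row core [40, 51)
  expect_identical(c(w@start, w@end), c(40L, 76L))
  expect_identical(w@coverage, 2L)

  # random staggered layouts against the oracle
  for (k in 1:8) {
    n <- sample(80:150, 1)
    rws <- vapply(1:6, function(i) {
      a <- sort(sample(0:(n - 1), 2))
      span_row(n, a[1], a[2])
    }, character(1))
    names(rws) <- paste0("x", 1:6)
    aln <- new("SurveyAlignment", rows = rws)
    o <- window_oracle(rws, 0.5)
    if (is.null(o)) {
      expect_error(extractWindow(aln, 0.5), "coverage")
    } else {
      w <- extractWindow(aln, 0.5)
      expect_identical(c(w@start, w@end, w@coverage),
                       c(o$start, o$end, o$cov))
    }
  }
})

test_that("window length never grows as the coverage floor rises", {
  set.seed(33)
  pw <- plantWindow(n_rows = 12, n_cols = 300, core_start = 60,
                    core_length = 120, seed = 5)
  lens <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    w <- tryCatch(extractWindow(pw$alignment, f), error = function(e) NULL)
    if (is.null(w)) 0L else w@end - w@start
  }, integer(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("divergent rows are excluded by the window coverage rule", {
  rows <- c(full = strrep("A", 100),
            left = paste0(strrep("C", 30), strrep("-", 70)),
            mid  = paste0(strrep("-", 35), strrep("G", 30), strrep("-", 35)))
  aln <- new("SurveyAlignment", rows = rows)
  w <- new("AlignmentWindow", start = 40L, end = 90L, coverage = 1L)
  res <- suppressMessages(excludeDivergent(aln, w))
  expect_identical(res$kept, "full")
  expect_setequal(res$excluded, c("left", "mid"))
})

test_that("planted short fragments are exactly the excluded rows", {
  set.seed(34)
  core <- vapply(1:6, function(i) paste0(strrep("-", 20),
                                         random_dna(60),
                                         strrep("-", 20)), character(1))
  frag <- vapply(1:5, function(i) paste0(random_dna(15), strrep("-", 85)),
                 character(1))
  rows <- setNames(c(core, frag), c(paste0("c", 1:6), paste0("f", 1:5)))
  aln <- new("SurveyAlignment", rows = rows)
  w <- extractWindow(aln, 0.5)
  res <- suppressMessages(excludeDivergent(aln, w))
  expect_setequal(res$excluded, paste0("f", 1:5))
  ws <- windowSequences(aln, w, ids = res$kept)
  expect_identical(unique(nchar(ws)), 60L)
})
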
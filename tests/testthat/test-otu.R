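make_window_set <- function(n_fam, n_per, len, within, between, seed) {
  set.seed(seed)
  root <- random_dna(len)
  seqs <- character(0); fam <- integer(0)
  for (f in seq_len(n_fam)) {
    anc <- mutate_seq(root, between)
    for (m in seq_len(n_per)) {
      seqs <- c(seqs, mutate_seq(anc, within))
      fam <- c(fam, f)
    }
  }
  names(seqs) <- sprintf("w%02d_%02d", fam, seq_along(seqs))
  list(seqs = seqs, family = setNames(fam, names(seqs)))
}

# exhaustive minimum set-cover size over archetype candidates
min_cover_oracle <- function(seqs, threshold) {
  n <- length(seqs)
  m <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    pairwiseIdentity(seqs[[i]], seqs[[j]]) >= threshold))
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combos))) {
      if (all(colSums(m[combos[, c_i], , drop = FALSE]) > 0)) return(k)
    }
  }
  n
}

test_that("mutually similar sequences form a single OTU", {
  set.seed(40)
  anc <- random_dna(150)
  seqs <- setNames(vapply(1:6, function(i) mutate_seq(anc, 0.02),
                          character(1)), paste0("u", 1:6))
  otus <- assignArchetypes(seqs)
  expect_identical(length(otus), 1L)
  expect_setequal(otuTable(otus)$members[[1]], names(seqs))
})

test_that("planted families are recovered as OTUs and match the set-cover optimum", {
  fx <- make_window_set(n_fam = 4, n_per = 5, len = 120,
                        within = 0.02, between = 0.45, seed = 3)
  otus <- assignArchetypes(fx$seqs, 0.87)
  expect_identical(length(otus), 4L)
  got <- integer(length(fx$seqs)); names(got) <- names(fx$seqs)
  for (k in seq_len(length(otus)))
    got[otuTable(otus)$members[[k]]] <- k
  expect_equal(mclust::adjustedRandIndex(got, fx$family), 1.0)
  expect_identical(length(otus), min_cover_oracle(fx$seqs, 0.87))
})

test_that("OTU membership partitions the input within the identity threshold", {
  fx <- make_window_set(n_fam = 3, n_per = 8, len = 100,
                        within = 0.04, between = 0.30, seed = 8)
  otus <- assignArchetypes(fx$seqs, 0.87)
  tab <- otuTable(otus)
  mem <- unlist(tab$members)
  expect_setequal(mem, names(fx$seqs))
  expect_identical(anyDuplicated(mem), 0L)
  for (k in seq_len(nrow(tab)))
    for (a in tab$members[[k]])
      expect_gte(pairwiseIdentity(fx$seqs[[a]],
                                  fx$seqs[[tab$archetype[k]]]), 0.87)
  expect_identical(length(assignArchetypes(character(0))), 0L)
})

test_that("source profiles equal a set-union oracle over member records", {
  set.seed(41)
  acc <- sprintf("p%02d", 1:20)
  srcs <- sample(sourceLevels(), 20, replace = TRUE)
  gs <- GeneSurvey(setNames(vapply(1:20, function(i) random_dna(60),
                                   character(1)), acc),
                   data.frame(accession = acc, domain = "Bacteria",
                              source = srcs))
  # three hand-made OTUs over accessions
  tab <- S4Vectors::DataFrame(otu_id = c("O1", "O2", "O3"),
                              archetype = c("p01", "p08", "p15"),
                              size = c(7L, 7L, 6L))
  tab$members <- list(acc[1:7], acc[8:14], acc[15:20])
  otus <- new("OTUSet", table = tab, threshold = 0.87)
  prof <- otuSourceProfile(otus, gs)
  want <- vapply(tab$members, function(m)
    length(unique(srcs[match(m, acc)])), integer(1))
  expect_identical(prof$n_sources, want)
  expect_identical(prof$n_seqs, c(7L, 7L, 6L))

  # members that are cluster ids expand through the ClusterSet
  ctab <- S4Vectors::DataFrame(cluster_id = "CL1", representative = "p01",
                               size = 5L)
  ctab$members <- list(acc[1:5])
  cl <- new("ClusterSet", table = ctab, threshold = 0.87)
  tab2 <- S4Vectors::DataFrame(otu_id = "O1", archetype = "CL1", size = 2L)
  tab2$members <- list(c("CL1", "p06"))
  prof2 <- otuSourceProfile(new("OTUSet", table = tab2, threshold = 0.87),
                            gs, cl)
  expect_identical(prof2$n_seqs, 6L)
  expect_identical(prof2$n_sources[1],
                   length(unique(srcs[match(c(acc[1:5], "p06"), acc)])))
})

test_that("single-source fraction reproduces the survey arithmetic", {
  expect_equal(singleSourceFraction(
    data.frame(n_sources = c(rep(1, 267), rep(2, 86)))), 75.6)
  expect_equal(singleSourceFraction(
    data.frame(n_sources = c(rep(1, 37), rep(3, 13)))), 74.0)
  expect_equal(singleSourceFraction(data.frame(n_sources = rep(1, 5))), 100)
  expect_error(singleSourceFraction(data.frame(n_sources = integer(0))),
               "no OTUs")
})

test_that("source percentage tables follow the counting rule and sum to 100", {
  set.seed(42)
  # Betaproteobacteria-like geometry: 8 single-source OTUs, 5 wastewater
  acc <- sprintf("q%02d", 1:8)
  srcs <- c(rep("wastewater", 5), "marine sediment", "terrestrial",
            "freshwater and estuary")
  gs <- GeneSurvey(setNames(vapply(1:8, function(i) random_dna(50),
                                   character(1)), acc),
                   data.frame(accession = acc, domain = "Bacteria",
                              source = srcs, class = "Betaproteobacteria"))
  tab <- S4Vectors::DataFrame(otu_id = sprintf("O%d", 1:8), archetype = acc,
                              size = rep(1L, 8))
  tab$members <- as.list(acc)
  otus <- new("OTUSet", table = tab, threshold = 0.87)
  sp <- sourcePercentages(otus, gs, group_by = "class")
  expect_identical(unique(sp$group), "Betaproteobacteria")
  expect_equal(sp$percent[sp$source == "wastewater"], 62.5)
  expect_lte(abs(sum(sp$percent) - 100), 0.3)

  # multi-source OTU appears in several bars under the all-sources rule
  tab2 <- S4Vectors::DataFrame(otu_id = "O1", archetype = "q01", size = 8L)
  tab2$members <- list(acc)
  otus2 <- new("OTUSet", table = tab2, threshold = 0.87)
  sp2 <- sourcePercentages(otus2, gs)
  expect_identical(nrow(sp2), 4L) # 4 distinct sources, one OTU
  expect_lte(abs(sum(sp2$percent) - 100), 0.3)
  sp3 <- sourcePercentages(otus2, gs, rule = "majority")
  expect_identical(sp3$source, "wastewater")
  expect_equal(sp3$percent, 100)

  # counting oracle on a random fixture
  srcs2 <- sample(sourceLevels()[1:4], 8, replace = TRUE)
  gs2 <- GeneSurvey(surveySeqs(gs),
                    data.frame(accession = acc, domain = "Bacteria",
                               source = srcs2))
  spr <- sourcePercentages(otus, gs2)
  want <- table(srcs2) # one single-member OTU per record
  expect_identical(setNames(spr$n, spr$source)[names(want)],
                   setNames(as.integer(want), names(want)))
})

test_that("hypersaline relabeling splits 'aquatic other' post hoc", {
  acc <- c("h1", "h2", "h3")
  gs <- GeneSurvey(setNames(c(random_dna(40), random_dna(40),
                              random_dna(40)), acc),
                   data.frame(accession = acc, domain = "Archaea",
                              source = c("aquatic other", "aquatic other",
                                         "marine water column")))
  tab <- S4Vectors::DataFrame(otu_id = c("O1", "O2", "O3"), archetype = acc,
                              size = rep(1L, 3))
  tab$members <- as.list(acc)
  otus <- new("OTUSet", table = tab, threshold = 0.87)
  sp <- sourcePercentages(otus, gs, hypersaline = c("h1", "h2"))
  expect_setequal(sp$source, c("hypersaline", "marine water column"))
  expect_equal(sp$percent[sp$source == "hypersaline"], 66.7)
})

test_that("OTU taxonomy takes the most specific majority rank", {
  acc <- c("t1", "t2", "t3", "t4")
  gs <- GeneSurvey(setNames(vapply(1:4, function(i) random_dna(30),
                                   character(1)), acc),
                   data.frame(accession = acc, domain = "Bacteria",
                              source = "marine sediment",
                              phylum = "Pseudomonadota",
                              class = c("Alphaproteobacteria",
                                        "Alphaproteobacteria",
                                        "Gammaproteobacteria", "unknown"),
                              genus = "unknown"))
  tab <- S4Vectors::DataFrame(otu_id = "O1", archetype = "t1", size = 4L)
  tab$members <- list(acc)
  otus <- new("OTUSet", table = tab, threshold = 0.87)
  tx <- otuTaxonomy(otus, gs)
  expect_identical(tx$rank, "class")
  expect_identical(tx$label, "Alphaproteobacteria")
})
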
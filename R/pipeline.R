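#' Assemble and validate a pipeline configuration
#'
#' A pipeline run is configured by input paths (FASTA + metadata TSV) or a
#' synthetic-survey specification, the survey thresholds (all defaulting
#' to the pipeline's standard settings: 87% identity, 400/300 bp length
#' floors, large-cluster minimum 3, window coverage floor 0.5) and an
#' output directory. Validation happens before any stage runs.
#'
#' @param fasta,meta Input paths (both or neither).
#' @param synthetic A [syntheticConfig()] (used when no input paths).
#' @param identity_threshold Clustering/OTU identity threshold.
#' @param min_len_bacteria,min_len_archaea Length floors in bp.
#' @param min_large Minimum size for a cluster to stay a cluster.
#' @param window_coverage Coverage floor for [extractWindow()].
#' @param max_gap_frac Window coverage gap tolerance.
#' @param domains Domain tracks to run.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest and used for synthetic input.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(fasta = NULL, meta = NULL, synthetic = NULL,
                           identity_threshold = 0.87,
                           min_len_bacteria = 400, min_len_archaea = 300,
                           min_large = 3, window_coverage = 0.5,
                           max_gap_frac = 0.1,
                           domains = c("Bacteria", "Archaea"),
                           out_dir = tempfile("genesurvey_run_"),
                           seed = 1) {
  if (is.null(synthetic) && (is.null(fasta) || is.null(meta)))
    stop("provide fasta + meta paths, or a synthetic config")
  if (!is.null(fasta) && !file.exists(fasta))
    stop("input FASTA not found: ", fasta)
  if (!is.null(meta) && !file.exists(meta))
    stop("input metadata not found: ", meta)
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (min_len_bacteria < 1 || min_len_archaea < 1 || min_large < 1)
    stop("length floors and min_large must be positive")
  if (window_coverage <= 0 || window_coverage > 1)
    stop("window_coverage must be in (0, 1]")
  stopifnot(all(domains %in% c("Bacteria", "Archaea")))
  cfg <- list(fasta = fasta, meta = meta, synthetic = synthetic,
              identity_threshold = identity_threshold,
              min_len_bacteria = min_len_bacteria,
              min_len_archaea = min_len_archaea,
              min_large = min_large, window_coverage = window_coverage,
              max_gap_frac = max_gap_frac, domains = domains,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `synthetic:` block
#' is passed to [syntheticConfig()].
#'
#' @param path YAML file.
#' @return A validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(syntheticConfig,
                                                    y$synthetic)
  do.call(pipelineConfig, y)
}

# small deterministic string checksum (djb2, kept under 2^31)
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  h
}

#' Run the full survey pipeline
#'
#' Orchestrates ingest, deduplication, length filtering, then per domain
#' track (Bacteria and Archaea are processed separately): greedy
#' clustering, aquatic-cluster retention, size partition, rank abundance,
#' per-cluster consensus, master alignment, window extraction, divergence
#' exclusion, OTU assignment, niche statistics, and a neighbor-joining
#' tree of OTU archetypes. Writes per-stage tables, window FASTA, Newick
#' trees and a JSON manifest with per-stage counts under the config's
#' output directory. Any stage error halts the run naming the stage.
#'
#' @param config A [pipelineConfig()] or path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package = "GeneSurvey",
                   version = as.character(utils::packageVersion("GeneSurvey")),
                   config = config[setdiff(names(config), "synthetic")],
                   config_hash = .config_hash(config),
                   stages = list())

  survey <- stage("ingest", {
    if (!is.null(config$synthetic)) simulateSurvey(config$synthetic)$survey
    else readSurvey(config$fasta, config$meta)
  })
  manifest$stages$ingest <- list(n_records = length(survey))
  survey <- stage("deduplicate", suppressMessages(deduplicate(survey)))
  manifest$stages$deduplicate <- list(n_records = length(survey))
  survey <- stage("length_filter", suppressMessages(
    filterByLength(survey, config$min_len_bacteria, config$min_len_archaea)))
  manifest$stages$length_filter <- list(n_records = length(survey))
  writeSurvey(survey, file.path(config$out_dir, "records.fasta"),
              file.path(config$out_dir, "records.tsv"))

  for (dom in config$domains) {
    tag <- tolower(dom)
    dsurv <- survey[surveyMeta(survey)$domain == dom]
    dman <- list(n_records = length(dsurv))
    if (length(dsurv) < 2L) {
      dman$skipped <- "fewer than 2 records"
      manifest$stages[[tag]] <- dman
      next
    }
    cl <- stage(paste0(tag, ":cluster"),
                greedyCluster(dsurv, config$identity_threshold))
    cl <- stage(paste0(tag, ":aquatic_filter"),
                suppressMessages(filterAquaticClusters(cl, dsurv)))
    part <- stage(paste0(tag, ":partition"),
                  partitionBySize(cl, config$min_large))
    ra <- rankAbundance(cl)
    utils::write.table(ra, file.path(config$out_dir,
                                     paste0(tag, "_rank_abundance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_cluster_tsv(cl, file.path(config$out_dir,
                                     paste0(tag, "_clusters.tsv")))
    dman$n_clusters <- length(cl)
    dman$n_large <- length(part$large)
    dman$n_individuals <- length(part$individuals)

    cons <- stage(paste0(tag, ":consensus"),
                  suppressMessages(clusterConsensus(dsurv, part$large)))
    seqs <- as.character(surveySeqs(dsurv))
    indiv <- seqs[part$individuals]
    rows_total <- length(cons$consensus) + length(indiv)
    if (rows_total < 2L) {
      dman$skipped <- "fewer than 2 rows for the master alignment"
      manifest$stages[[tag]] <- dman
      next
    }
    aln <- stage(paste0(tag, ":master_alignment"),
                 buildMasterAlignment(cons$consensus, indiv))
    win <- stage(paste0(tag, ":window"),
                 extractWindow(aln, config$window_coverage,
                               config$max_gap_frac))
    utils::write.table(windowReport(win),
                       file.path(config$out_dir, paste0(tag, "_window.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep <- suppressMessages(excludeDivergent(aln, win, config$max_gap_frac))
    wseqs <- windowSequences(aln, win, ids = keep$kept)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(wseqs),
      file.path(config$out_dir, paste0(tag, "_window_seqs.fasta")))
    dman$n_divergent_clusters <- length(cons$divergent)
    dman$n_window_rows <- length(wseqs)
    dman$n_excluded_rows <- length(keep$excluded)
    dman$window <- windowReport(win)

    wts <- stats::setNames(rep(1, length(wseqs)), names(wseqs))
    cs <- clusterSizes(part$large)
    wts[intersect(names(wts), names(cs))] <-
      cs[intersect(names(wts), names(cs))]
    otus <- stage(paste0(tag, ":otus"),
                  assignArchetypes(wseqs, config$identity_threshold,
                                   weights = wts))
    prof <- otuSourceProfile(otus, dsurv, part$large)
    dman$n_otus <- length(otus)
    dman$single_source_pct <- singleSourceFraction(prof)
    sp <- sourcePercentages(otus, dsurv, part$large)
    utils::write.table(sp, file.path(config$out_dir,
                                     paste0(tag, "_source_percent.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_otu_tsv(otus, prof, file.path(config$out_dir,
                                         paste0(tag, "_otus.tsv")))
    summ <- surveySummary(cl, part, otus)
    utils::write.table(summ, file.path(config$out_dir,
                                       paste0(tag, "_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dman$summary <- summ

    if (length(otus) >= 3L) {
      arch <- otuTable(otus)$archetype
      wrows <- substr(alignmentRows(aln)[arch], win@start + 1L, win@end)
      waln <- new("SurveyAlignment", rows = wrows)
      d <- stage(paste0(tag, ":distances"),
                 suppressWarnings(jcDistance(waln)))
      tree <- stage(paste0(tag, ":nj_tree"), njTree(d))
      tree$tip.label <- otuTable(otus)$otu_id[match(tree$tip.label, arch)]
      writeNewick(tree, file.path(config$out_dir, paste0(tag, "_otus.nwk")))
      ann <- leafAnnotation(otus, prof)
      ann$otu_id <- otuTable(otus)$otu_id[match(ann$otu_id, prof$otu_id)]
      utils::write.table(ann,
                         file.path(config$out_dir,
                                   paste0(tag, "_tree_annotation.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages[[tag]] <- dman
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

.write_cluster_tsv <- function(clusters, path) {
  tab <- clusterTable(clusters)
  out <- data.frame(cluster_id = tab$cluster_id,
                    representative = tab$representative,
                    size = tab$size,
                    members = vapply(tab$members, paste,
                                     character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_otu_tsv <- function(otus, profiles, path) {
  tab <- otuTable(otus)
  out <- data.frame(otu_id = tab$otu_id, archetype = tab$archetype,
                    n_members = tab$size,
                    members = vapply(tab$members, paste,
                                     character(1), collapse = ","),
                    n_seqs = profiles$n_seqs,
                    sources = vapply(profiles$sources, paste,
                                     character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
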
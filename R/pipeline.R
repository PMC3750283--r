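## Orchestration of the stages under one configuration, plus the
## worked-example table reproduction used by the acceptance script.

#' Pipeline configuration
#'
#' Collects every stage parameter (with the study's defaults: clustering at
#' divergence < 0.01, mapping identity 0.95, SNP window 40-60% at coverage
#' 20-20,000, selection models with dN/dS capped at 999) plus the scenario
#' and master seed. Serialisable to YAML for provenance.
#'
#' @param scenario simulation scenario name (see [benchmarkScenario()]).
#' @param seed master seed.
#' @param merge,cluster,map,snp,selection stage parameter lists; partial
#'   lists are filled with defaults.
#' @return validated config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(scenario = "tiny", seed = 1L, merge = list(),
                           cluster = list(), map = list(), snp = list(),
                           selection = list()) {
  cfg <- list(
    scenario = scenario, seed = as.integer(seed),
    merge = utils::modifyList(list(min_overlap = 10L, max_mismatch_rate = 0.1),
                              merge),
    cluster = utils::modifyList(list(threshold = 0.01), cluster),
    map = utils::modifyList(list(min_identity = 0.95, k = 21L), map),
    snp = utils::modifyList(list(min_pct = 40, max_pct = 60, min_cov = 20,
                                 max_cov = 20000), snp),
    selection = utils::modifyList(list(models = c("M0", "M1", "M2"),
                                       freqs = "equal", ncat = 10L,
                                       n_starts = 1L, n_taxa = 8L,
                                       branch_mode = "scale"), selection))
  stopifnot(cfg$cluster$threshold > 0, cfg$map$min_identity <= 1,
            cfg$snp$min_pct <= cfg$snp$max_pct,
            cfg$snp$min_cov <= cfg$snp$max_cov)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipelineConfig, x[intersect(names(x), names(formals(pipelineConfig)))])
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a simulated scenario
#'
#' Stages run in order simulate, merge, cluster, quant, snps, selection;
#' each stage writes a TSV under `outdir` and a joint `summary.json`
#' (read counts, toxin/nontoxin percentages, SNP counts, test results) plus
#' the echoed `config.yaml` are written at the end. Reruns with the same
#' config are bit-identical (no timestamps are embedded).
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created).
#' @return `outdir`, invisibly; side effect: stage outputs on disk.
#' @export
runPipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- benchmarkScenario(config$scenario, seed = config$seed)
  sim <- simulateTranscriptome(sim_cfg)
  records <- sim$records
  writeFasta(transcriptSeqs(records), file.path(outdir, "transcripts.fasta"))
  writeAnnotations(as.data.frame(transcriptAnno(records)),
                   file.path(outdir, "annotations.tsv"))
  reads <- simulateReads(records, stats::setNames(
    sim$truth$expression$weight, sim$truth$expression$transcript_id),
    sim_cfg, sim$alt_alleles)

  mrg <- mergeStream(reads$fastq1, reads$fastq2,
                     minOverlap = config$merge$min_overlap,
                     maxMismatchRate = config$merge$max_mismatch_rate,
                     mergedOut = file.path(outdir, "merged.fastq"))

  clusters <- clusterTranscripts(records[isToxin(records)],
                                 threshold = config$cluster$threshold)
  .writeTsv(clusters[, c("cluster_name", "member_id", "representative_id")],
            file.path(outdir, "clusters.tsv"))

  mp <- mapReads(mrg$merged, records, minIdentity = config$map$min_identity,
                 k = config$map$k, seed = config$seed)
  ab <- estimateAbundance(mp$hits, clusters, n_input_reads = mp$n_reads)
  expr_report <- makeExpressionReport(ab$cluster_table,
                                      file.path(outdir, "expression.tsv"))

  pile <- buildPileup(mp$hits, mrg$merged, records)
  calls <- callSnps(pile, records, minPct = config$snp$min_pct,
                    maxPct = config$snp$max_pct, minCov = config$snp$min_cov,
                    maxCov = config$snp$max_cov)
  cls_of <- stats::setNames(toxinClass(records), transcriptIds(records))
  calls$type <- ifelse(cls_of[calls$transcript_id] == "NONTOXIN",
                       "Nontoxin", "Toxin")
  .writeTsv(calls, file.path(outdir, "snps.tsv"))
  het_tox <- length(unique(calls$transcript_id[calls$type == "Toxin"]))
  het_non <- length(unique(calls$transcript_id[calls$type == "Nontoxin"]))
  n_tox <- sum(isToxin(records)); n_non <- sum(!isToxin(records))
  het <- if (het_tox + het_non > 0 && n_tox > 0 && n_non > 0)
    heterozygosityTest(het_tox, n_tox, het_non, n_non) else NULL
  het_report <- makeHetReport(calls, het, records)
  .writeTsv(het_report$per_class, file.path(outdir, "het_summary.tsv"))

  sel_cfg <- sim_cfg@selection
  sel_tree <- randomTree(config$selection$n_taxa, mean_branch = 0.2,
                         seed = config$seed)
  sel_sim <- simulateCodonAlignment(
    sel_tree, list(kappa = sel_cfg$kappa, classes = sel_cfg$classes),
    n_codons = min(sel_cfg$n_codons, 150L), seed = config$seed + 7L)
  fit_cfg <- list(nStarts = config$selection$n_starts, seed = config$seed,
                  freqs = config$selection$freqs,
                  ncat = config$selection$ncat,
                  branchMode = config$selection$branch_mode)
  fits <- lapply(stats::setNames(config$selection$models,
                                 config$selection$models),
                 function(m) fitCodonModel(sel_sim$alignment, sel_tree, m,
                                           fit_cfg))
  sel_report <- if (all(c("M0", "M1", "M2") %in% names(fits)))
    selectionReport(list(sim = list(M0 = fits$M0, M1 = fits$M1,
                                    M2 = fits$M2)))
  else data.frame()
  .writeTsv(sel_report, file.path(outdir, "selection.tsv"))

  summary <- list(
    n_read_pairs = mrg$summary$n_pairs,
    n_merged = mrg$summary$n_merged,
    merge_rate = mrg$summary$merge_rate,
    n_mapped = mp$n_mapped,
    pct_toxin_of_total = ab$totals$pct_toxin_of_total,
    pct_mapped_of_total = ab$totals$pct_mapped_of_total,
    n_snps = nrow(calls),
    n_snps_toxin = sum(calls$type == "Toxin"),
    n_snps_nontoxin = sum(calls$type == "Nontoxin"),
    het_test = if (!is.null(het))
      list(statistic = het$statistic, df = het$df, p_value = het$p_value)
      else NULL,
    selection = if (nrow(sel_report))
      list(lambda = sel_report$lambda[1], p_value = sel_report$p_value[1])
      else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writePipelineConfig(config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Ranked expression report
#'
#' Rows sorted by descending share of toxin reads with ranks `1..n`
#' assigned; optionally written as TSV.
#'
#' @param cluster_table cluster-level table (from [estimateAbundance()] or
#'   the bundled fixture).
#' @param path optional TSV output path.
#' @return the ranked data.frame.
#' @export
makeExpressionReport <- function(cluster_table, path = NULL) {
  if (nrow(cluster_table) == 0L) {
    out <- data.frame(rank = integer(), cluster_name = character(),
                      cluster_size = integer(),
                      pct_toxin_reads = numeric(), pct_total_reads = numeric())
  } else {
    tbl <- .normClusterTable(cluster_table)
    out <- tbl[order(-tbl$pct_toxin_reads, tbl$cluster_name), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    first <- c("rank", "cluster_name", "toxin_class", "cluster_size",
               "pct_toxin_reads", "pct_total_reads")
    out <- out[, c(first, setdiff(colnames(out), first)), drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(path)) .writeTsv(out, path)
  out
}

#' Heterozygosity report
#'
#' Per-class SNP and transcript counts, nonsynonymous fractions (nonsense
#' calls excluded from the synonymous/nonsynonymous tally), SNP densities
#' when a [TranscriptSet-class] is supplied, and the toxin-versus-nontoxin
#' test result.
#'
#' @param calls SNP calls with a `type` column (`"Toxin"`/`"Nontoxin"`), as
#'   from [runPipeline()] or the bundled SNP-table fixture.
#' @param test optional result of [heterozygosityTest()].
#' @param transcripts optional [TranscriptSet-class] for densities.
#' @return list: `per_class` data.frame and `test`.
#' @export
makeHetReport <- function(calls, test = NULL, transcripts = NULL) {
  tcol <- if ("transcript_id" %in% colnames(calls)) "transcript_id"
          else "transcript"
  per_class <- do.call(rbind, lapply(c("Toxin", "Nontoxin"), function(ty) {
    d <- calls[calls$type == ty, , drop = FALSE]
    coding <- d[d$effect %in% c("synonymous", "nonsynonymous"), , drop = FALSE]
    data.frame(
      type = ty, n_snps = nrow(d),
      n_transcripts = length(unique(d[[tcol]])),
      n_nonsynonymous = sum(coding$effect == "nonsynonymous"),
      pct_nonsynonymous = if (nrow(coding))
        100 * sum(coding$effect == "nonsynonymous") / nrow(coding)
        else NA_real_,
      snp_density = if (!is.null(transcripts) && "transcript_id" %in%
                          colnames(calls))
        snpDensity(calls, transcripts,
                   if (ty == "Toxin") "toxin" else "nontoxin")
        else NA_real_,
      stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, test = test)
}

#' Recompute the worked-example quantities from the bundled tables
#'
#' Derives, at run time and purely from the packaged fixtures, the headline
#' summary quantities of the study: per-class expression rollups and shares
#' from the cluster-expression table, the nonsynonymous fraction among toxin
#' SNPs, and chi-square tail probabilities of the heterozygosity and
#' selection tests (the latter recomputed from the tabulated model
#' log-likelihoods).
#'
#' @return named list of quantities (percentages on the 0-100 scale).
#' @export
reproduceTables <- function() {
  t1tbl <- loadFixture("table1")
  cs <- classSummary(t1tbl)
  pct <- stats::setNames(cs$pct_toxin_reads, cs$toxin_class)
  top5 <- c("PLA2", "3FTx", "LCN", "SVMP", "KUN")
  shares_3ftx <- withinClassShares(t1tbl, "3FTx")

  t3 <- loadFixture("table3")
  tox <- t3[t3$type == "Toxin", , drop = FALSE]
  pct_nonsyn_toxin <- 100 * sum(tox$effect == "nonsynonymous") / nrow(tox)

  ## heterozygosity comparison: tail probability at the study's printed
  ## statistic, plus the Pearson statistic recomputed from the counts
  het_p_printed <- chisqSf(6.383, 1)
  het <- heterozygosityTest(9, 75, 69, 1950)

  t4 <- loadFixture("table4")
  lrt <- lrtFromNegLnL(t4)
  rownames(lrt) <- lrt$toxin_class

  list(
    pct_toxin_reads_pla2 = unname(pct["PLA2"]),
    pct_toxin_reads_3ftx = unname(pct["3FTx"]),
    pct_toxin_reads_pla2_3ftx = unname(pct["PLA2"] + pct["3FTx"]),
    pct_toxin_reads_top5 = unname(sum(pct[top5])),
    pct_clusters_top5 =
      100 * sum(cs$n_clusters[cs$toxin_class %in% top5]) / sum(cs$n_clusters),
    pct_transcripts_top5 =
      100 * sum(cs$n_transcripts[cs$toxin_class %in% top5]) /
        sum(cs$n_transcripts),
    pct_class_share_3ftx2 =
      shares_3ftx$pct_of_class[shares_3ftx$cluster_name == "3FTx-2"],
    pct_total_reads_toxin = sum(t1tbl$pct_total_reads),
    pct_nonsynonymous_toxin_snps = pct_nonsyn_toxin,
    het_p_value = het_p_printed,
    het_pearson_statistic = het$statistic,
    het_pearson_p_value = het$p_value,
    lrt_p_kun = lrt["KUN", "p_value"],
    lrt_p_lcn = lrt["LCN", "p_value"],
    lrt_lambda_3ftx = lrt["3FTx", "lambda"],
    lrt_lambda = stats::setNames(lrt$lambda, lrt$toxin_class))
}
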
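## Read mapping and cluster-level expression quantification.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Map reads to transcripts (seed-and-extend)
#'
#' Exact k-mer seeds locate candidate gapless placements of each read on the
#' transcripts; identity is the matched fraction of the full read length
#' (terminal clipping is disallowed). Each read is assigned to its
#' best-identity placement provided that identity reaches `minIdentity`;
#' reads tied between several best placements are assigned uniformly at
#' random under `seed`.
#'
#' @param reads character vector or `QualityScaledDNAStringSet` of (merged)
#'   reads.
#' @param transcripts a [TranscriptSet-class] or named `DNAStringSet`.
#' @param minIdentity minimum match fraction (default 0.95).
#' @param k seed length (default 21).
#' @param seed integer seed for tie-breaking.
#' @return A list: `hits` data.frame (`read_id`, `transcript_id`, `start`
#'   0-based, `identity`), `n_reads`, `n_mapped`, `n_unmapped`.
#' @export
mapReads <- function(reads, transcripts, minIdentity = 0.95, k = 21L,
                     seed = NULL) {
  seqs <- if (methods::is(transcripts, "TranscriptSet"))
    transcriptSeqs(transcripts) else transcripts
  if (length(seqs) == 0L) stop("empty transcript reference")
  rid <- names(reads)
  rseq <- unname(as.character(reads))
  if (is.null(rid)) rid <- paste0("read", seq_along(rseq))
  res <- cpp_map_reads(unname(rseq), unname(as.character(seqs)),
                       as.integer(k), minIdentity)
  ties <- data.frame(read = res$tie_read, ref = res$tie_ref,
                     start = res$tie_start)
  pick <- .withSeed(seed, {
    if (nrow(ties)) {
      u <- stats::runif(nrow(ties))
      keep <- unlist(lapply(split(seq_len(nrow(ties)), ties$read),
                            function(ix) ix[which.max(u[ix])]), use.names = FALSE)
      ties[keep, , drop = FALSE]
    } else ties
  })
  hits <- data.frame(
    read_id = rid[pick$read],
    transcript_id = names(seqs)[pick$ref],
    start = pick$start,
    identity = res$best_identity[pick$read],
    stringsAsFactors = FALSE)
  list(hits = hits, n_reads = length(rseq), n_mapped = nrow(hits),
       n_unmapped = length(rseq) - nrow(hits))
}

#' Estimate cluster-level expression from mapping hits
#'
#' Per-transcript read counts are rolled up to toxin clusters; transcripts
#' absent from the cluster membership are treated as nontoxins. Percentages:
#' `pct_toxin_reads` is cluster reads over all toxin-mapped reads x 100 and
#' sums to 100 over toxin clusters; `pct_total_reads` is cluster reads over
#' all input reads of the quantification run x 100. Member transcripts of
#' multi-member clusters are labelled `a, b, c, ...` by descending read
#' count (ties by id).
#'
#' @param hits hits data.frame from [mapReads()].
#' @param clusters membership data.frame from [clusterTranscripts()].
#' @param n_input_reads total reads in the quantification run (mapped or not).
#' @return A list: `transcript_counts`, `cluster_table` (with `rank` by
#'   descending `pct_toxin_reads`), `member_labels`, and `totals`.
#' @export
estimateAbundance <- function(hits, clusters, n_input_reads) {
  if (n_input_reads < nrow(hits))
    stop("n_input_reads (", n_input_reads, ") < mapped reads (", nrow(hits), ")")
  counts <- table(hits$transcript_id)
  tcounts <- data.frame(transcript_id = names(counts),
                        n_reads = as.integer(counts),
                        stringsAsFactors = FALSE)
  cl_of <- stats::setNames(clusters$cluster_name, clusters$member_id)
  class_of <- stats::setNames(clusters$toxin_class, clusters$member_id)
  tcounts$cluster_name <- unname(cl_of[tcounts$transcript_id])
  tcounts$toxin_class <- unname(class_of[tcounts$transcript_id])
  tcounts$toxin_class[is.na(tcounts$cluster_name)] <- "NONTOXIN"
  is_tox <- tcounts$toxin_class != "NONTOXIN"
  n_toxin_reads <- sum(tcounts$n_reads[is_tox])

  ## cluster table covers every cluster, including ones with zero reads
  all_cl <- unique(clusters[, c("cluster_name", "toxin_class")])
  sz <- table(clusters$cluster_name)
  cl_reads <- tapply(tcounts$n_reads[is_tox], tcounts$cluster_name[is_tox], sum)
  cluster_table <- data.frame(
    cluster_name = all_cl$cluster_name,
    toxin_class = all_cl$toxin_class,
    cluster_size = as.integer(sz[all_cl$cluster_name]),
    n_reads = as.integer(ifelse(is.na(cl_reads[all_cl$cluster_name]), 0L,
                                cl_reads[all_cl$cluster_name])),
    stringsAsFactors = FALSE)
  cluster_table$pct_toxin_reads <-
    if (n_toxin_reads > 0) 100 * cluster_table$n_reads / n_toxin_reads else 0
  cluster_table$pct_total_reads <- 100 * cluster_table$n_reads / n_input_reads
  cluster_table <- cluster_table[order(-cluster_table$pct_toxin_reads,
                                       cluster_table$cluster_name), ]
  cluster_table$rank <- seq_len(nrow(cluster_table))
  rownames(cluster_table) <- NULL

  ## member letters by descending member abundance within multi-member clusters
  memb <- clusters
  cnt <- stats::setNames(tcounts$n_reads, tcounts$transcript_id)
  memb$n_reads <- ifelse(is.na(cnt[memb$member_id]), 0L, cnt[memb$member_id])
  lab <- unlist(lapply(split(memb, memb$cluster_name), function(d) {
    d <- d[order(-d$n_reads, d$member_id), ]
    lbl <- if (nrow(d) > 1L) paste0(d$cluster_name, letters[seq_len(nrow(d))])
           else d$cluster_name
    stats::setNames(lbl, d$member_id)
  }), use.names = TRUE)
  names(lab) <- sub("^.*\\.", "", names(lab))
  member_labels <- data.frame(member_id = memb$member_id,
                              label = unname(lab[memb$member_id]),
                              stringsAsFactors = FALSE)

  totals <- list(n_input_reads = n_input_reads, n_mapped = nrow(hits),
                 n_toxin_reads = n_toxin_reads,
                 n_nontoxin_reads = nrow(hits) - n_toxin_reads,
                 pct_toxin_of_total = 100 * n_toxin_reads / n_input_reads,
                 pct_mapped_of_total = 100 * nrow(hits) / n_input_reads)
  list(transcript_counts = tcounts, cluster_table = cluster_table,
       member_labels = member_labels, totals = totals)
}

.normClusterTable <- function(tbl) {
  if (!"cluster_size" %in% colnames(tbl) && "size" %in% colnames(tbl))
    tbl$cluster_size <- tbl$size
  need <- c("cluster_name", "toxin_class", "cluster_size",
            "pct_toxin_reads", "pct_total_reads")
  if (!all(need %in% colnames(tbl)))
    stop("cluster table must have columns: ", paste(need, collapse = ", "))
  tbl
}

#' Per-toxin-class expression rollup
#'
#' Class percentages are sums of member-cluster percentages; accepts either
#' an [estimateAbundance()] cluster table or the packaged cluster-expression
#' fixture.
#'
#' @param tbl a cluster-level table with columns `cluster_name`,
#'   `toxin_class`, `cluster_size` (or `size`), `pct_toxin_reads`,
#'   `pct_total_reads`.
#' @return A data.frame per class: `toxin_class`, `n_clusters`,
#'   `n_transcripts`, `pct_toxin_reads`, `pct_total_reads`, ordered by
#'   descending `pct_toxin_reads`.
#' @export
classSummary <- function(tbl) {
  tbl <- .normClusterTable(tbl)
  sp <- split(tbl, tbl$toxin_class)
  res <- do.call(rbind, lapply(sp, function(d) data.frame(
    toxin_class = d$toxin_class[1],
    n_clusters = nrow(d),
    n_transcripts = sum(d$cluster_size),
    pct_toxin_reads = sum(d$pct_toxin_reads),
    pct_total_reads = sum(d$pct_total_reads),
    stringsAsFactors = FALSE)))
  rownames(res) <- NULL
  res[order(-res$pct_toxin_reads), , drop = FALSE]
}

#' Within-class expression shares
#'
#' Share of each cluster in its class's toxin reads; shares sum to 100
#' within the class.
#'
#' @param tbl a cluster-level table (see [classSummary()]).
#' @param toxin_class a single class label present in `tbl`.
#' @return A data.frame: `cluster_name`, `pct_of_class`, descending.
#' @export
withinClassShares <- function(tbl, toxin_class) {
  tbl <- .normClusterTable(tbl)
  d <- tbl[tbl$toxin_class == toxin_class, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown toxin class: ", toxin_class)
  tot <- sum(d$pct_toxin_reads)
  if (tot <= 0) stop("class ", toxin_class, " has no toxin reads")
  out <- data.frame(cluster_name = d$cluster_name,
                    pct_of_class = 100 * d$pct_toxin_reads / tot,
                    stringsAsFactors = FALSE)
  out[order(-out$pct_of_class), , drop = FALSE]
}
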
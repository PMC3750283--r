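## Clustering of toxin transcripts at a nucleotide-divergence threshold.

#' Pairwise nucleotide divergence
#'
#' Divergence between two sequences is the mismatch fraction over the columns
#' of a global (Needleman-Wunsch) alignment, with terminal gap columns
#' excluded from the denominator and internal gap columns counted as
#' mismatches.
#'
#' @param seqA,seqB nucleotide sequences (character or `DNAString`).
#' @return Divergence fraction in `[0, 1]`.
#' @export
pairwiseDivergence <- function(seqA, seqB) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (nchar(seqA) == 0L || nchar(seqB) == 0L)
    stop("divergence undefined for empty sequences")
  if (nchar(seqA) == nchar(seqB) && seqA == seqB) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), NULL)[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), NULL)[[1]]
  gap <- a == "-" | b == "-"
  lead <- cumsum(!gap) == 0
  trail <- rev(cumsum(rev(!gap)) == 0)
  keep <- which(!(lead | trail))
  if (length(keep) == 0L) return(1)
  mism <- sum(a[keep] != b[keep])
  mism / length(keep)
}

.divergenceEdges <- function(seqs, threshold) {
  n <- length(seqs)
  if (n < 2L) return(data.frame(from = character(), to = character()))
  pairs <- utils::combn(n, 2)
  hit <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    hit[p] <- pairwiseDivergence(seqs[[i]], seqs[[j]]) < threshold
  }
  data.frame(from = names(seqs)[pairs[1, hit]],
             to = names(seqs)[pairs[2, hit]],
             stringsAsFactors = FALSE)
}

#' Cluster toxin transcripts by nucleotide divergence
#'
#' Single-linkage components of the graph whose edges join transcripts at
#' divergence strictly below `threshold` (default `< 1%`). Clusters never
#' span toxin classes, even when sequences from different classes fall under
#' the threshold. Each cluster's representative is its longest member, ties
#' broken by lexicographically smallest id. Cluster names are
#' `<class>-<number>`, numbered within class by descending cluster size
#' (ties by first-seen member order).
#'
#' @param records A [TranscriptSet-class] of toxin transcripts.
#' @param threshold strict divergence threshold (default 0.01).
#' @return A data.frame with one row per member: `cluster_name`, `member_id`,
#'   `representative_id`, `toxin_class`, `member_length`.
#' @export
clusterTranscripts <- function(records, threshold = 0.01) {
  if (any(!isToxin(records)))
    stop("clusterTranscripts expects toxin transcripts only")
  ids <- transcriptIds(records)
  if (length(ids) == 0L)
    return(data.frame(cluster_name = character(), member_id = character(),
                      representative_id = character(),
                      toxin_class = character(), member_length = integer(),
                      stringsAsFactors = FALSE))
  cls <- toxinClass(records)
  widths <- Biostrings::width(transcriptSeqs(records))
  out <- list()
  for (cl in unique(cls)) {
    sel <- which(cls == cl)
    seqs <- as.character(transcriptSeqs(records)[sel])
    names(seqs) <- ids[sel]
    edges <- .divergenceEdges(seqs, threshold)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = names(seqs))
    memb <- igraph::components(g)$membership[names(seqs)]
    comp_first <- tapply(seq_along(memb), memb, min)
    comp_size <- tapply(memb, memb, length)
    ord <- order(-comp_size, comp_first)   # descending size, then first-seen
    number <- match(memb, as.integer(names(comp_size)[ord]))
    for (ci in sort(unique(number))) {
      m_ids <- names(seqs)[number == ci]
      m_len <- widths[sel][number == ci]
      rep_id <- m_ids[order(-m_len, m_ids)][1]
      out[[length(out) + 1L]] <- data.frame(
        cluster_name = paste0(cl, "-", ci), member_id = m_ids,
        representative_id = rep_id, toxin_class = cl,
        member_length = as.integer(m_len), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarise toxin clusters
#'
#' @param clusters membership data.frame from [clusterTranscripts()].
#' @return A data.frame with one row per cluster: `cluster_name`,
#'   `toxin_class`, `size`, `representative_id`, `representative_length`.
#'   Sizes sum to the number of clustered transcripts.
#' @export
clusterSummary <- function(clusters) {
  if (nrow(clusters) == 0L)
    return(data.frame(cluster_name = character(), toxin_class = character(),
                      size = integer(), representative_id = character(),
                      representative_length = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(clusters, clusters$cluster_name)
  res <- do.call(rbind, lapply(sp, function(d) data.frame(
    cluster_name = d$cluster_name[1], toxin_class = d$toxin_class[1],
    size = nrow(d), representative_id = d$representative_id[1],
    representative_length =
      as.integer(d$member_length[d$member_id == d$representative_id[1]][1]),
    stringsAsFactors = FALSE)))
  rownames(res) <- NULL
  res[order(res$toxin_class, res$cluster_name), , drop = FALSE]
}
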
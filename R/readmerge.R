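## Merging of 3'-overlapping read pairs into longer composite reads.

.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

.phredStringToInt <- function(q) lapply(strsplit(q, NULL), function(ch)
  as.integer(vapply(ch, utf8ToInt, 0L)) - 33L)

#' Merge one read pair at its 3' overlap
#'
#' The mate is reverse-complemented internally, then every overlap of length
#' at least `minOverlap` between the 3' end of read 1 and the (reverse
#' complemented) 3' end of read 2 is scored as matches minus mismatches.
#' Overlaps whose mismatch rate exceeds `maxMismatchRate` are infeasible; the
#' best-scoring feasible overlap wins, ties going to the longer overlap. At
#' agreeing overlap positions the merged phred score is `min(q1 + q2, 93)`;
#' at disagreeing positions the higher-quality base is kept with score
#' `|q1 - q2|`.
#'
#' @param seq1,seq2 read sequences (read 2 in its original orientation).
#' @param qual1,qual2 integer phred score vectors.
#' @param minOverlap smallest overlap considered (default 10).
#' @param maxMismatchRate largest tolerated mismatch fraction in the overlap
#'   (default 0.1).
#' @return A list with `merged` (logical); if merged, `sequence` and
#'   `qualities` of the composite read, else the inputs unchanged.
#' @export
mergePair <- function(seq1, qual1, seq2, qual2, minOverlap = 10L,
                      maxMismatchRate = 0.1) {
  stopifnot(nchar(seq1) == length(qual1), nchar(seq2) == length(qual2))
  if (nchar(seq1) < minOverlap || nchar(seq2) < minOverlap)
    stop("both reads must be at least minOverlap long")
  q1 <- rawToChar(as.raw(pmin(qual1, 93L) + 33L))
  q2 <- rawToChar(as.raw(rev(pmin(qual2, 93L)) + 33L))
  res <- cpp_merge_pairs(seq1, q1, .revcomp(seq2), q2,
                         as.integer(minOverlap), maxMismatchRate)
  if (!res$merged[1])
    return(list(merged = FALSE, seq1 = seq1, qual1 = qual1, seq2 = seq2,
                qual2 = qual2))
  list(merged = TRUE, sequence = as.character(res$sequence[1]),
       qualities = .phredStringToInt(as.character(res$quality[1]))[[1]])
}

#' Merge a stream of paired reads
#'
#' Applies the [mergePair()] rule to ordered, id-paired FASTQ records and
#' reports summary statistics. Inputs may be file paths or
#' `QualityScaledDNAStringSet` objects.
#'
#' @param fastq1,fastq2 paired FASTQ files or `QualityScaledDNAStringSet`s,
#'   same order and ids (a `/1`,`/2` or ` 1:`,`2:` suffix difference is
#'   tolerated).
#' @param minOverlap,maxMismatchRate see [mergePair()].
#' @param mergedOut,unmerged1Out,unmerged2Out optional output FASTQ paths.
#' @return A list: `merged` (`QualityScaledDNAStringSet` of composite reads),
#'   `unmerged1`, `unmerged2`, and `summary` (pair count, merged count, merge
#'   rate, mean merged length, mean merged phred).
#' @export
mergeStream <- function(fastq1, fastq2, minOverlap = 10L,
                        maxMismatchRate = 0.1, mergedOut = NULL,
                        unmerged1Out = NULL, unmerged2Out = NULL) {
  r1 <- if (is.character(fastq1)) readFastq(fastq1) else fastq1
  r2 <- if (is.character(fastq2)) readFastq(fastq2) else fastq2
  if (length(r1) != length(r2))
    stop("unpaired inputs: ", length(r1), " vs ", length(r2), " records")
  strip <- function(x) sub("(/[12]| [12]:.*)$", "", x)
  id1 <- strip(names(r1)); id2 <- strip(names(r2))
  if (length(r1) && any(id1 != id2))
    stop("unpaired ids at record ", which(id1 != id2)[1], ": '",
         id1[which(id1 != id2)[1]], "' vs '", id2[which(id1 != id2)[1]], "'")
  if (length(r1) == 0L) {
    empty <- fastqRecords(character(), character(), list())
    summary <- list(n_pairs = 0L, n_merged = 0L, merge_rate = NA_real_,
                    mean_merged_length = NA_real_, mean_merged_phred = NA_real_)
    return(list(merged = empty, unmerged1 = empty, unmerged2 = empty,
                summary = summary))
  }
  s1 <- as.character(r1); s2 <- as.character(r2)
  q1 <- as.character(Biostrings::quality(r1))
  q2rev <- vapply(strsplit(as.character(Biostrings::quality(r2)), NULL),
                  function(ch) paste(rev(ch), collapse = ""), character(1))
  res <- cpp_merge_pairs(s1, q1, .revcomp(s2), q2rev,
                         as.integer(minOverlap), maxMismatchRate)
  keep <- as.logical(res$merged)
  merged <- Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(as.character(res$sequence[keep])),
                    id1[keep]),
    Biostrings::PhredQuality(as.character(res$quality[keep])))
  unmerged1 <- r1[!keep]; unmerged2 <- r2[!keep]
  phreds <- unlist(.phredStringToInt(as.character(res$quality[keep])))
  summary <- list(
    n_pairs = length(r1),
    n_merged = sum(keep),
    merge_rate = sum(keep) / length(r1),
    mean_merged_length = if (any(keep)) mean(nchar(res$sequence[keep])) else NA_real_,
    mean_merged_phred = if (any(keep)) mean(phreds) else NA_real_)
  if (!is.null(mergedOut)) writeFastq(merged, mergedOut)
  if (!is.null(unmerged1Out)) writeFastq(unmerged1, unmerged1Out)
  if (!is.null(unmerged2Out)) writeFastq(unmerged2, unmerged2Out)
  list(merged = merged, unmerged1 = unmerged1, unmerged2 = unmerged2,
       summary = summary)
}
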
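## Pileup construction, heterozygous SNP calling, coding-effect annotation,
## SNP density and the toxin-versus-nontoxin heterozygosity comparison.

#' Build per-transcript base pileups from mapping hits
#'
#' Every aligned read base is tallied at its transcript coordinate (hits are
#' gapless placements from [mapReads()]).
#'
#' @param hits hits data.frame from [mapReads()].
#' @param reads the reads that were mapped (character or
#'   `QualityScaledDNAStringSet`, same ids as `hits$read_id`).
#' @param transcripts a [TranscriptSet-class] or named `DNAStringSet`.
#' @return A named list (one entry per transcript) of 4 x L integer count
#'   matrices with rows `A`, `C`, `G`, `T`.
#' @export
buildPileup <- function(hits, reads, transcripts) {
  seqs <- if (methods::is(transcripts, "TranscriptSet"))
    transcriptSeqs(transcripts) else transcripts
  rid <- names(reads)
  rseq <- unname(as.character(reads))
  if (is.null(rid)) rid <- paste0("read", seq_along(rseq))
  ri <- match(hits$read_id, rid)
  ti <- match(hits$transcript_id, names(seqs))
  if (any(is.na(ri)) || any(is.na(ti)))
    stop("hits reference unknown read or transcript ids")
  mats <- cpp_pileup(ri, ti, hits$start, unname(rseq),
                     Biostrings::width(seqs))
  names(mats) <- names(seqs)
  mats <- lapply(mats, function(m) { rownames(m) <- c("A", "C", "G", "T"); m })
  mats
}

#' Call putative heterozygous SNPs from a pileup
#'
#' A site is called iff it lies inside the annotated CDS, its coverage lies
#' in `[minCov, maxCov]` (inclusive), and the second-most-common base's read
#' fraction x 100 lies in `[minPct, maxPct]` (inclusive). The majority base
#' is reported as `ref` and the runner-up as `alt`; `snp_pct` is the
#' minor-allele percentage. Columns where more than two bases exceed a 5%
#' noise floor are not callable and are skipped. Coding effects are
#' annotated with [classifySnp()].
#'
#' @param pileup named list of count matrices from [buildPileup()].
#' @param transcripts a [TranscriptSet-class] supplying CDS windows and codon
#'   context.
#' @param minPct,maxPct inclusive bounds on the minor-allele percentage
#'   (defaults 40, 60).
#' @param minCov,maxCov inclusive coverage bounds (defaults 20, 20000).
#' @return A data.frame of calls: `transcript_id`, `position` (1-based),
#'   `ref_base`, `alt_base`, `snp_pct`, `coverage`, `effect`
#'   (`synonymous`/`nonsynonymous`/`nonsense`), `aa_ref`, `aa_alt`.
#' @export
callSnps <- function(pileup, transcripts, minPct = 40, maxPct = 60,
                     minCov = 20, maxCov = 20000) {
  anno <- transcriptAnno(transcripts)
  out <- list()
  for (tid in names(pileup)) {
    a <- anno[anno$id == tid, , drop = FALSE]
    if (nrow(a) == 0L) next
    m <- pileup[[tid]]
    if (a$cds_end > ncol(m)) stop("CDS beyond pileup for ", tid)
    cds_cols <- seq.int(a$cds_start + 1L, a$cds_end)
    sub <- m[, cds_cols, drop = FALSE]
    cov <- colSums(sub)
    ok_cov <- cov >= minCov & cov <= maxCov
    if (!any(ok_cov)) next
    for (j in which(ok_cov)) {
      cnt <- sort(sub[, j], decreasing = TRUE)
      if (cnt[2] == 0) next
      if (sum(sub[, j] > 0.05 * cov[j]) > 2L) next  # tri-allelic: not callable
      pct <- 100 * cnt[2] / cov[j]
      if (pct < minPct || pct > maxPct) next
      pos <- cds_cols[j]
      cls <- classifySnp(
        list(position = pos, ref_base = names(cnt)[1], alt_base = names(cnt)[2]),
        transcripts[tid])
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tid, position = pos, ref_base = names(cnt)[1],
        alt_base = names(cnt)[2], snp_pct = pct, coverage = as.integer(cov[j]),
        effect = cls$effect, aa_ref = cls$aa_ref, aa_alt = cls$aa_alt,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      snp_pct = numeric(), coverage = integer(),
                      effect = character(), aa_ref = character(),
                      aa_alt = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify the coding effect of a biallelic site
#'
#' Translates the codon containing the site with the reference and the
#' alternative base under the standard genetic code. The effect is
#' `synonymous` iff both alleles encode the same amino acid, `nonsense` when
#' the alternative allele creates a stop codon (such calls are reported but
#' excluded from synonymous/nonsynonymous tallies).
#'
#' @param call list or one-row data.frame with `position` (1-based, on the
#'   transcript), `ref_base`, `alt_base`.
#' @param transcript a length-1 [TranscriptSet-class].
#' @return list with `effect`, `aa_ref`, `aa_alt`.
#' @export
classifySnp <- function(call, transcript) {
  stopifnot(length(transcript) == 1L)
  a <- transcriptAnno(transcript)
  pos0 <- call$position - 1L                 # 0-based site
  if (pos0 < a$cds_start || pos0 >= a$cds_end)
    stop("site at position ", call$position, " is outside the CDS")
  off <- pos0 - a$cds_start
  codon_i <- off %/% 3L
  within <- off %% 3L
  seq <- as.character(transcriptSeqs(transcript)[[1]])
  codon_start <- a$cds_start + 3L * codon_i + 1L   # 1-based
  codon <- substr(seq, codon_start, codon_start + 2L)
  ref_codon <- codon; substr(ref_codon, within + 1L, within + 1L) <- call$ref_base
  alt_codon <- codon; substr(alt_codon, within + 1L, within + 1L) <- call$alt_base
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[ref_codon]); aa_alt <- unname(gc[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) {
    effect <- NA_character_
  } else if (aa_alt == "*" && aa_ref != "*") {
    effect <- "nonsense"
  } else if (aa_ref == aa_alt) {
    effect <- "synonymous"
  } else {
    effect <- "nonsynonymous"
  }
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' SNP density (SNPs per kb of CDS of SNP-containing transcripts)
#'
#' Density is `1000 * n_SNPs / total CDS length`, where the denominator sums
#' the CDS lengths of only those transcripts of the class that contain at
#' least one SNP.
#'
#' @param calls SNP calls data.frame from [callSnps()].
#' @param transcripts a [TranscriptSet-class].
#' @param class `"toxin"`, `"nontoxin"`, or a specific toxin-class label.
#' @return Density in SNPs/kb, or `NA` when the class has no SNP-containing
#'   transcript.
#' @export
snpDensity <- function(calls, transcripts, class = c("toxin", "nontoxin")) {
  class <- class[1]
  anno <- transcriptAnno(transcripts)
  sel <- switch(class,
                toxin = anno$toxin_class != "NONTOXIN",
                nontoxin = anno$toxin_class == "NONTOXIN",
                anno$toxin_class == class)
  ids <- anno$id[sel]
  calls <- calls[calls$transcript_id %in% ids, , drop = FALSE]
  with_snp <- unique(calls$transcript_id)
  if (length(with_snp) == 0L) return(NA_real_)
  a <- anno[match(with_snp, anno$id), , drop = FALSE]
  denom <- sum(a$cds_end - a$cds_start)
  if (denom == 0L) return(NA_real_)
  1000 * nrow(calls) / denom
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution; for `df = 2` this is
#' `exp(-x/2)` exactly and for `df = 1` the complementary error function of
#' `sqrt(x/2)`.
#'
#' @param x nonnegative statistic.
#' @param df degrees of freedom.
#' @return Upper-tail probability.
#' @export
chisqSf <- function(x, df) {
  if (any(x < 0)) stop("chi-square statistic must be nonnegative")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Compare heterozygous-locus frequency between toxins and nontoxins
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' heterozygous versus homozygous locus counts, referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param het_toxin,tot_toxin heterozygous and total toxin loci.
#' @param het_nontoxin,tot_nontoxin heterozygous and total nontoxin loci.
#' @return list with `counts`, `statistic`, `df` (1), `p_value`.
#' @export
heterozygosityTest <- function(het_toxin, tot_toxin, het_nontoxin,
                               tot_nontoxin) {
  if (tot_toxin <= 0 || tot_nontoxin <= 0) stop("totals must be positive")
  if (het_toxin > tot_toxin || het_nontoxin > tot_nontoxin)
    stop("heterozygous counts cannot exceed totals")
  tab <- matrix(c(het_toxin, tot_toxin - het_toxin,
                  het_nontoxin, tot_nontoxin - het_nontoxin),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("toxin", "nontoxin"), c("het", "hom")))
  stat <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic))
  list(counts = tab, statistic = stat, df = 1L,
       p_value = chisqSf(stat, 1))
}
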
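#' Recognised toxin classes
#'
#' Class labels used to annotate venom-gland transcripts. All transcripts
#' that are not venom components carry the `NONTOXIN` label.
#'
#' @export
TOXIN_CLASSES <- c("3FTx", "CTL", "CREGF", "HYAL", "KUN", "LAAO", "LCN",
                   "NGF", "NP", "NUC", "PDE", "PLA2", "PLB", "SVMP", "VEGF",
                   "NONTOXIN")

#' TranscriptSet: annotated full-length transcripts
#'
#' Container pairing a [Biostrings::DNAStringSet] of full-length transcript
#' sequences with a per-transcript annotation table (stable id, class-cluster
#' name such as `"PLA2-2a"`, toxin class, and CDS window). CDS coordinates are
#' 0-based half-open internally; all user-facing reports print 1-based
#' positions.
#'
#' Validity requires: unique ids matching the sequence names; sequences over
#' `{A,C,G,T,N}`; `0 <= cds_start < cds_end <= width`; CDS length divisible by
#' 3; no internal stop codon in the CDS; the leading `<class>-` prefix of
#' `name` equal to `toxin_class` (nontoxins are named `NONTOXIN-...`).
#'
#' @slot sequences A `DNAStringSet`, names are transcript ids.
#' @slot anno A [S4Vectors::DataFrame] with columns `id`, `name`,
#'   `toxin_class`, `cds_start`, `cds_end`.
#'
#' @seealso [TranscriptSet()], [cdsSeqs()], [toxinClass()]
#' @export
setClass("TranscriptSet",
         slots = c(sequences = "DNAStringSet", anno = "DataFrame"))

.validTranscriptSet <- function(object) {
  msgs <- character()
  anno <- object@anno
  seqs <- object@sequences
  need <- c("id", "name", "toxin_class", "cds_start", "cds_end")
  if (!all(need %in% colnames(anno)))
    return(paste("annotation must have columns:", paste(need, collapse = ", ")))
  if (length(seqs) != nrow(anno))
    return("number of sequences and annotation rows differ")
  if (length(seqs) == 0L) return(TRUE)
  if (anyDuplicated(anno$id)) msgs <- c(msgs, "transcript ids must be unique")
  if (!identical(names(seqs), as.character(anno$id)))
    msgs <- c(msgs, "sequence names must equal annotation ids, in order")
  bad_alpha <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad_alpha))
    msgs <- c(msgs, paste0("sequences restricted to {A,C,G,T,N}; offending id: ",
                           anno$id[which(bad_alpha)[1]]))
  if (!all(anno$toxin_class %in% TOXIN_CLASSES))
    msgs <- c(msgs, "unknown toxin_class label")
  prefix <- sub("-.*$", "", anno$name)
  if (!all(prefix == anno$toxin_class))
    msgs <- c(msgs, "transcript name prefix must encode its toxin_class")
  w <- Biostrings::width(seqs)
  if (!all(anno$cds_start >= 0 & anno$cds_start < anno$cds_end &
           anno$cds_end <= w))
    msgs <- c(msgs, "require 0 <= cds_start < cds_end <= length(sequence)")
  if (!all((anno$cds_end - anno$cds_start) %% 3L == 0L))
    msgs <- c(msgs, "CDS length must be divisible by 3")
  if (length(msgs) == 0L) {
    # internal stop codons (standard code); terminal stop codon is allowed
    cds <- Biostrings::subseq(seqs, start = anno$cds_start + 1L, end = anno$cds_end)
    aa <- as.character(suppressWarnings(
      Biostrings::translate(cds, if.fuzzy.codon = "solve")))
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    if (any(grepl("*", internal, fixed = TRUE)))
      msgs <- c(msgs, paste0("internal stop codon in CDS of ",
                             anno$id[grepl("*", internal, fixed = TRUE)][1]))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' SimConfig: parameterisation of the synthetic-data generators
#'
#' Holds every knob of the synthetic transcriptome/read/alignment generators.
#' All randomness in the generators flows from `seed`. Defaults emulate the
#' study conditions: ~2,000 nontoxins and ~100 toxins in families, toxin
#' expression skew drawn from the bundled cluster-expression table, diploid
#' heterozygosity at a higher per-transcript rate in toxins than nontoxins,
#' and 100-nt read pairs from fragments centred near 134 nt so that pairs
#' overlap at their 3' ends.
#'
#' @slot seed integer master seed.
#' @slot n_nontoxin number of nontoxin transcripts.
#' @slot n_toxin_families number of toxin families (expression clusters).
#' @slot family_sizes integer vector of per-family duplicate counts, recycled
#'   or sampled to `n_toxin_families`.
#' @slot transcript_length_range,cds_length_range integer ranges (nt); CDS is
#'   trimmed to a multiple of 3 and placed inside the transcript.
#' @slot expression_model `"table1"` (empirical skew from the bundled
#'   expression table) or `"lognormal"`.
#' @slot lognormal_meanlog,lognormal_sdlog log-normal fallback parameters.
#' @slot toxin_fraction_of_reads fraction of read pairs drawn from toxins.
#' @slot het_fraction_toxin,het_fraction_nontoxin fraction of transcripts of
#'   each class carrying a heterozygous second allele (1-3 CDS sites).
#' @slot error_rate per-base sequencing error probability.
#' @slot read_length,fragment_mean,fragment_sd read geometry (nt).
#' @slot n_read_pairs number of simulated pairs.
#' @slot selection block for codon-alignment simulation: a list with entries
#'   `model`, `p`, `omega`, `kappa`, `n_codons`, `pi_mode`.
#'
#' @export
setClass("SimConfig",
         slots = c(seed = "integer",
                   n_nontoxin = "integer",
                   n_toxin_families = "integer",
                   family_sizes = "integer",
                   transcript_length_range = "integer",
                   cds_length_range = "integer",
                   expression_model = "character",
                   lognormal_meanlog = "numeric",
                   lognormal_sdlog = "numeric",
                   toxin_fraction_of_reads = "numeric",
                   het_fraction_toxin = "numeric",
                   het_fraction_nontoxin = "numeric",
                   error_rate = "numeric",
                   read_length = "integer",
                   fragment_mean = "numeric",
                   fragment_sd = "numeric",
                   n_read_pairs = "integer",
                   selection = "list"))

.validSimConfig <- function(object) {
  msgs <- character()
  frac <- c(object@toxin_fraction_of_reads, object@het_fraction_toxin,
            object@het_fraction_nontoxin, object@error_rate)
  if (any(frac < 0 | frac > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (object@read_length <= 0L) msgs <- c(msgs, "read_length must be positive")
  if (any(object@transcript_length_range <= 0L) ||
      any(object@cds_length_range <= 0L))
    msgs <- c(msgs, "length ranges must be positive")
  if (min(object@cds_length_range) > max(object@transcript_length_range))
    msgs <- c(msgs, "CDS length range must fit inside the transcript length range")
  if (object@fragment_mean < object@read_length)
    msgs <- c(msgs, "mean fragment length must be >= read length")
  if (length(msgs)) msgs else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' CodonModelFit: one fitted codon site model
#'
#' Result of [fitCodonModel()]: the model name, fitted parameters (kappa,
#' codon frequencies, site-class proportions and dN/dS ratios, fitted branch
#' lengths), the maximised log-likelihood, and convergence diagnostics across
#' multi-starts.
#'
#' @slot model one of "M0", "M1", "M2", "M7", "M8".
#' @slot kappa fitted transition/transversion rate ratio.
#' @slot pi stationary codon frequencies over the 61 sense codons.
#' @slot site_classes data.frame with columns `p` and `omega` (the discrete
#'   mixture actually used; for M7/M8 these are the beta categories).
#' @slot params named numeric of primitive model parameters (e.g. `p0`,
#'   `omega0`, beta `p`/`q`).
#' @slot tree the phylo tree with fitted branch lengths.
#' @slot lnl maximised log-likelihood (report `-lnl` to compare with
#'   likelihood tables).
#' @slot convergence integer optimizer code of the best start (0 = converged).
#' @slot n_starts number of optimisation starts performed.
#' @export
setClass("CodonModelFit",
         slots = c(model = "character", kappa = "numeric", pi = "numeric",
                   site_classes = "data.frame", params = "numeric",
                   tree = "ANY", lnl = "numeric", convergence = "integer",
                   n_starts = "integer"))

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object@sequences)
  ntox <- sum(object@anno$toxin_class != "NONTOXIN")
  cat("TranscriptSet with", n, "transcripts (", ntox, "toxin,",
      n - ntox, "nontoxin )\n")
  if (n > 0) {
    cls <- table(object@anno$toxin_class)
    cls <- cls[names(cls) != "NONTOXIN"]
    if (length(cls))
      cat("  toxin classes:", paste0(names(cls), "(", cls, ")", collapse = " "),
          "\n")
  }
  invisible(object)
})

setMethod("show", "CodonModelFit", function(object) {
  cat(sprintf("CodonModelFit [%s]  -lnL = %.4f  kappa = %.3f\n",
              object@model, -object@lnl, object@kappa))
  sc <- object@site_classes
  cat("  site classes: p = (", paste(sprintf("%.3f", sc$p), collapse = ", "),
      "), omega = (", paste(sprintf("%.3f", sc$omega), collapse = ", "), ")\n")
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig seed=%d: %d nontoxins, %d toxin families, ",
                     "%d read pairs (%d nt reads), error %.4g\n"),
              object@seed, object@n_nontoxin, object@n_toxin_families,
              object@n_read_pairs, object@read_length, object@error_rate))
  invisible(object)
})
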
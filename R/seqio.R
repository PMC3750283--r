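## Sequence, tree and table input/output, plus the TranscriptSet constructor.

#' Construct a TranscriptSet
#'
#' @param sequences A `DNAStringSet` (or named character vector) of transcript
#'   sequences over `{A,C,G,T,N}`.
#' @param annotations A data.frame/DataFrame with columns `id`, `name`,
#'   `toxin_class`, `cds_start`, `cds_end` (0-based half-open CDS window).
#'   Rows are matched to sequences by `id`; every id must be present among
#'   the sequence names.
#' @return A validated [TranscriptSet-class] object.
#' @export
TranscriptSet <- function(sequences, annotations) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  annotations <- S4Vectors::DataFrame(annotations)
  if (is.null(names(sequences)))
    stop("sequences must be named by transcript id")
  miss <- setdiff(as.character(annotations$id), names(sequences))
  if (length(miss))
    stop("annotation ids absent from the sequences: ",
         paste(utils::head(miss, 3), collapse = ", "))
  sequences <- sequences[as.character(annotations$id)]
  annotations$id <- as.character(annotations$id)
  annotations$name <- as.character(annotations$name)
  annotations$toxin_class <- as.character(annotations$toxin_class)
  annotations$cds_start <- as.integer(annotations$cds_start)
  annotations$cds_end <- as.integer(annotations$cds_end)
  methods::new("TranscriptSet", sequences = sequences, anno = annotations)
}

.scanFastaStructure <- function(path) {
  ## cheap structural pre-scan so parse errors can name the offending line
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("FASTA parse error: file '", path, "' is empty")
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[nonempty[1]])
    stop("FASTA parse error at line ", nonempty[1],
         ": expected '>' header before sequence data")
  hdr <- which(is_header)
  for (h in hdr) {
    if (trimws(lines[h]) == ">")
      stop("FASTA parse error at line ", h, ": empty header")
    nxt <- lines[seq.int(h + 1L, length.out = max(0L, length(lines) - h))]
    nxt_hdr <- c(startsWith(trimws(nxt), ">"), TRUE)
    body <- nzchar(trimws(nxt))[seq_len(which(nxt_hdr)[1] - 1L)]
    if (length(body) == 0L || !any(body))
      stop("FASTA parse error at line ", h, ": record '",
           sub("^>", "", trimws(lines[h])), "' has no sequence")
  }
  invisible(TRUE)
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and `U` is mapped to `T`; any residual character
#' outside `{A,C,G,T,N}` (IUPAC ambiguity codes other than N included) is
#' rejected, since downstream codon arithmetic requires an unambiguous
#' alphabet. Record order is preserved.
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .scanFastaStructure(path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", names(raw)[i],
         "': only A,C,G,T,N (and U, mapped to T) are accepted")
  }
  ## keep only the first whitespace-delimited token of each header
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Write sequences to FASTA
#'
#' @param x A `DNAStringSet` (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read / write FASTQ (phred+33)
#'
#' `readFastq()` returns a [Biostrings::QualityScaledDNAStringSet]; use
#' [phredScores()] to obtain integer phred scores. Quality strings are assumed
#' phred+33 (no autodetection). A sequence/quality length mismatch raises a
#' parse error.
#'
#' @param path FASTQ file.
#' @return A `QualityScaledDNAStringSet`.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    ## Biostrings notes that it drops its internal quality metadata column
    ## while building the QualityScaled object; that is expected here
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred")),
    error = function(e) stop("FASTQ parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(x) &&
      !all(Biostrings::width(x) == Biostrings::width(Biostrings::quality(x))))
    stop("FASTQ parse error in '", path,
         "': sequence and quality lengths differ")
  x
}

#' @rdname readFastq
#' @param x A `QualityScaledDNAStringSet` (for `writeFastq`/`phredScores`), or
#'   the result of [fastqRecords()].
#' @export
writeFastq <- function(x, path) {
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname readFastq
#' @return `phredScores()`: a list of integer phred score vectors.
#' @export
phredScores <- function(x) {
  as(Biostrings::quality(x), "IntegerList")
}

#' Assemble FASTQ records from ids, sequences and integer phred scores
#'
#' @param ids character record ids.
#' @param sequences character sequences.
#' @param qualities list of integer phred vectors (capped at 93, the largest
#'   printable phred+33 score).
#' @return A `QualityScaledDNAStringSet`.
#' @export
fastqRecords <- function(ids, sequences, qualities) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(qualities))
  qs <- vapply(qualities, function(q) {
    q <- pmax(0L, pmin(as.integer(q), 93L))
    rawToChar(as.raw(q + 33L))
  }, character(1))
  seqs <- Biostrings::DNAStringSet(sequences)
  names(seqs) <- ids
  Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(qs))
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape}. A tree without branch lengths is given
#' zero-length branches and flagged with `attr(tree, "hasBranchLengths") =
#' FALSE`. Round-trips preserve topology and branch lengths to 10 significant
#' digits.
#'
#' @param path Newick file (single tree).
#' @return An \pkg{ape} `phylo` object.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
    attr(tree, "hasBranchLengths") <- FALSE
  } else {
    attr(tree, "hasBranchLengths") <- TRUE
  }
  tree
}

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Tab-separated with header `id name toxin_class cds_start cds_end`
#' (0-based half-open CDS coordinates).
#'
#' @param path TSV file.
#' @return A data.frame.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "toxin_class", "cds_start", "cds_end")
  if (!all(need %in% colnames(df)))
    stop("annotation table must have columns: ", paste(need, collapse = " "))
  df
}

#' @rdname readAnnotations
#' @param annotations a data.frame as returned by `readAnnotations()`.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a packaged worked-example table
#'
#' The package ships, as plain TSV, the study's printed summary tables:
#' `"table1"` (expression levels of the 75 toxin clusters), `"table3"`
#' (putative heterozygous SNPs with coverage, 1-based position, minor-allele
#' percentage and amino-acid effect) and `"table4"` (codon site-model fits
#' and likelihood-ratio tests for the four diverse toxin classes).
#'
#' @param table_name one of `"table1"`, `"table3"`, `"table4"`.
#' @return A typed data.frame. For `"table3"` an `effect` column is derived:
#'   `nonsynonymous` where the replacement amino acid differs, else
#'   `synonymous`.
#' @export
loadFixture <- function(table_name) {
  files <- c(table1 = "table1_toxin_clusters.tsv",
             table3 = "table3_snps.tsv",
             table4 = "table4_codeml.tsv")
  if (!table_name %in% names(files))
    stop("unknown fixture '", table_name, "'; expected one of: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[table_name]], package = "venomtx",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character())
  if (table_name == "table3") {
    df$aa_alt[df$aa_alt == ""] <- NA_character_
    df$effect <- ifelse(is.na(df$aa_alt), "synonymous", "nonsynonymous")
  }
  df
}
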
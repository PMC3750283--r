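## Synthetic transcriptomes, diploid read sets and codon alignments with
## full ground truth, for validating every pipeline stage.

#' Construct a SimConfig
#'
#' Defaults emulate the study conditions of a small-neurotoxin elapid
#' venom-gland transcriptome: 1,950 nontoxins and 75 toxin families whose
#' duplicate counts and expression skew follow the bundled cluster-expression
#' table (116 toxin transcripts in total), toxins receiving 80.2% of the
#' on-transcriptome reads (45.8 of the 57.1 percentage points mapped in the
#' study), heterozygous second alleles in 12% of toxin and 3.5% of nontoxin
#' transcripts, 100-nt read pairs from fragments of mean length 134, and a
#' 0.1% per-base error rate.
#'
#' @param seed master seed; all generator randomness flows from it.
#' @param n_nontoxin,n_toxin_families,family_sizes transcriptome
#'   architecture. `family_sizes = NULL` takes duplicate counts from the
#'   bundled expression table when `n_toxin_families` is 75, else singletons.
#' @param transcript_length_range,cds_length_range nt ranges; the CDS is
#'   placed inside the transcript and trimmed to a codon multiple.
#' @param expression_model `"table1"` or `"lognormal"`.
#' @param lognormal_meanlog,lognormal_sdlog log-normal expression fallback.
#' @param toxin_fraction_of_reads fraction of read pairs drawn from toxins.
#' @param het_fraction_toxin,het_fraction_nontoxin per-transcript
#'   heterozygosity rates.
#' @param error_rate per-base sequencing error.
#' @param read_length,fragment_mean,fragment_sd,n_read_pairs read geometry.
#' @param selection codon-simulation block: list with `kappa`, `classes`
#'   (data.frame `p`, `omega`), `n_codons`, `pi_mode` (`"equal"`/`"random"`),
#'   optionally `class_sizes` (taxa per alignment for a multi-class suite).
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      n_nontoxin = 1950L,
                      n_toxin_families = 75L,
                      family_sizes = NULL,
                      transcript_length_range = c(350L, 2400L),
                      cds_length_range = c(240L, 1500L),
                      expression_model = "table1",
                      lognormal_meanlog = 0,
                      lognormal_sdlog = 1.5,
                      toxin_fraction_of_reads = 0.802,
                      het_fraction_toxin = 0.12,
                      het_fraction_nontoxin = 0.035,
                      error_rate = 0.001,
                      read_length = 100L,
                      fragment_mean = 134,
                      fragment_sd = 20,
                      n_read_pairs = 100000L,
                      selection = list()) {
  if (is.null(family_sizes)) {
    family_sizes <- if (n_toxin_families == 75L)
      as.integer(loadFixture("table1")$cluster_size)
    else rep(1L, n_toxin_families)
  }
  family_sizes <- as.integer(rep_len(family_sizes, n_toxin_families))
  sel <- list(kappa = 2, classes = data.frame(p = 1, omega = 0.5),
              n_codons = 500L, pi_mode = "equal", class_sizes = NULL)
  sel[names(selection)] <- selection   # shallow: classes is a data.frame
  methods::new("SimConfig", seed = as.integer(seed),
               n_nontoxin = as.integer(n_nontoxin),
               n_toxin_families = as.integer(n_toxin_families),
               family_sizes = family_sizes,
               transcript_length_range = as.integer(transcript_length_range),
               cds_length_range = as.integer(cds_length_range),
               expression_model = expression_model,
               lognormal_meanlog = lognormal_meanlog,
               lognormal_sdlog = lognormal_sdlog,
               toxin_fraction_of_reads = toxin_fraction_of_reads,
               het_fraction_toxin = het_fraction_toxin,
               het_fraction_nontoxin = het_fraction_nontoxin,
               error_rate = error_rate, read_length = as.integer(read_length),
               fragment_mean = fragment_mean, fragment_sd = fragment_sd,
               n_read_pairs = as.integer(n_read_pairs), selection = sel)
}

#' Bundled benchmark scenarios
#'
#' `paper_like` mirrors the study's architecture at one hundredth of the
#' read depth (1,950 nontoxins; 116 toxins in 75 families; 100,000 pairs).
#' `tiny` is a seconds-scale smoke configuration. `selection_suite`
#' parameterises codon-alignment simulation for four toxin classes with
#' taxa counts (26, 9, 9, 52).
#'
#' @param name one of `"paper_like"`, `"tiny"`, `"selection_suite"`.
#' @param seed master seed.
#' @return A [SimConfig-class].
#' @export
benchmarkScenario <- function(name, seed = 1L) {
  switch(name,
    paper_like = simConfig(seed = seed),
    tiny = simConfig(seed = seed, n_nontoxin = 20L, n_toxin_families = 6L,
                     family_sizes = c(3L, 2L, 1L, 1L, 2L, 1L),
                     expression_model = "lognormal",
                     transcript_length_range = c(350L, 900L),
                     cds_length_range = c(240L, 330L),
                     n_read_pairs = 2000L),
    selection_suite = simConfig(
      seed = seed, n_read_pairs = 0L,
      selection = list(class_sizes = c("3FTx" = 26L, KUN = 9L, LCN = 9L,
                                       PLA2 = 52L),
                       n_codons = 200L,
                       classes = data.frame(p = c(0.6, 0.2, 0.2),
                                            omega = c(0.1, 1, 4)))),
    stop("unknown scenario '", name,
         "'; expected paper_like, tiny or selection_suite"))
}

.randomCds <- function(n_codons) {
  tab <- .codonTables()
  nonstop <- tab$codons
  ## avoid ATG-independent quirks: just draw sense codons uniformly
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}

.randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## mutate `n` distinct CDS-safe positions of a transcript; returns the new
## sequence (never creates an internal stop codon)
.mutateTranscript <- function(seq, cds_start, cds_end, n) {
  s <- strsplit(seq, NULL)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  placed <- 0L; guard <- 0L
  used <- integer(0)
  while (placed < n && guard < 500L) {
    guard <- guard + 1L
    pos <- sample(length(s), 1L)
    if (pos %in% used) next
    old <- s[pos]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    if (pos > cds_start && pos <= cds_end) {
      off <- pos - cds_start - 1L
      ci <- off %/% 3L
      c0 <- cds_start + 3L * ci + 1L
      codon <- paste(s[c0:(c0 + 2L)], collapse = "")
      substr(codon, off %% 3L + 1L, off %% 3L + 1L) <- new
      if (codon %in% stops) next
    }
    s[pos] <- new
    used <- c(used, pos)
    placed <- placed + 1L
  }
  paste(s, collapse = "")
}

#' Simulate an annotated venom-gland transcriptome
#'
#' Toxin families are generated by duplication from a random family template
#' CDS: each duplicate carries a fixed small number of substitutions
#' (about 0.3% of its length) so that within-family divergence stays below
#' 1%, while independent templates keep between-family divergence far above
#' 5%. A configurable fraction of transcripts carries a heterozygous second
#' allele differing at 1-3 CDS sites. Everything is deterministic under the
#' config seed.
#'
#' @param config A [SimConfig-class].
#' @return list: `records` ([TranscriptSet-class] of reference alleles),
#'   `alt_alleles` (named character vector of second-allele sequences for
#'   heterozygous transcripts), `truth` (list of data.frames: `families`
#'   with expression weights, `het_sites` with allele positions,
#'   `expression` per transcript).
#' @export
simulateTranscriptome <- function(config) {
  methods::validObject(config)
  .withSeed(config@seed, {
    tab1 <- if (config@expression_model == "table1" &&
                config@n_toxin_families == 75L) loadFixture("table1") else NULL
    classes <- if (!is.null(tab1)) tab1$toxin_class
               else rep_len(setdiff(TOXIN_CLASSES, "NONTOXIN"),
                            config@n_toxin_families)
    fam_names <- if (!is.null(tab1)) tab1$cluster_name else {
      idx <- stats::ave(seq_along(classes), classes, FUN = seq_along)
      paste0(classes, "-", idx)
    }
    fam_weights <- if (!is.null(tab1)) tab1$pct_toxin_reads / 100
                   else stats::rlnorm(config@n_toxin_families,
                                      config@lognormal_meanlog,
                                      config@lognormal_sdlog)
    fam_weights <- fam_weights / sum(fam_weights)

    ids <- character(); names_ <- character(); cls <- character()
    seqs <- character(); cds_s <- integer(); cds_e <- integer()
    fam_of <- character()
    for (f in seq_len(config@n_toxin_families)) {
      tl <- sample(config@transcript_length_range[1]:
                   config@transcript_length_range[2], 1L)
      clen <- sample(config@cds_length_range[1]:config@cds_length_range[2], 1L)
      clen <- (clen %/% 3L) * 3L
      clen <- min(clen, (tl %/% 3L) * 3L)
      utr5 <- sample(0:(tl - clen), 1L)
      template <- paste0(.randomSeq(utr5), .randomCds(clen %/% 3L),
                         .randomSeq(tl - utr5 - clen))
      size <- config@family_sizes[f]
      for (m in seq_len(size)) {
        id <- sprintf("TOX%05d", length(ids) + 1L)
        sq <- if (m == 1L) template
              else .mutateTranscript(template, utr5, utr5 + clen,
                                     max(1L, round(0.003 * tl)))
        ids <- c(ids, id); cls <- c(cls, classes[f])
        names_ <- c(names_, if (size > 1L) paste0(fam_names[f], letters[m])
                            else fam_names[f])
        seqs <- c(seqs, sq); cds_s <- c(cds_s, utr5); cds_e <- c(cds_e, utr5 + clen)
        fam_of <- c(fam_of, fam_names[f])
      }
    }
    n_tox <- length(ids)
    for (i in seq_len(config@n_nontoxin)) {
      tl <- sample(config@transcript_length_range[1]:
                   config@transcript_length_range[2], 1L)
      clen <- sample(config@cds_length_range[1]:config@cds_length_range[2], 1L)
      clen <- min((clen %/% 3L) * 3L, (tl %/% 3L) * 3L)
      utr5 <- sample(0:(tl - clen), 1L)
      ids <- c(ids, sprintf("NT%05d", i))
      names_ <- c(names_, paste0("NONTOXIN-", i))
      cls <- c(cls, "NONTOXIN")
      seqs <- c(seqs, paste0(.randomSeq(utr5), .randomCds(clen %/% 3L),
                             .randomSeq(tl - utr5 - clen)))
      cds_s <- c(cds_s, utr5); cds_e <- c(cds_e, utr5 + clen)
      fam_of <- c(fam_of, NA_character_)
    }
    anno <- data.frame(id = ids, name = names_, toxin_class = cls,
                       cds_start = cds_s, cds_end = cds_e,
                       stringsAsFactors = FALSE)
    records <- TranscriptSet(stats::setNames(seqs, ids), anno)

    ## heterozygous second alleles: 1-3 CDS substitutions
    is_tox <- cls != "NONTOXIN"
    het_t <- sample(which(is_tox),
                    round(config@het_fraction_toxin * n_tox))
    het_n <- sample(which(!is_tox),
                    round(config@het_fraction_nontoxin * config@n_nontoxin))
    het <- c(het_t, het_n)
    alt_alleles <- character(0)
    het_rows <- list()
    for (i in het) {
      nsub <- sample(1:3, 1L)
      s_ref <- strsplit(seqs[i], NULL)[[1]]
      s_alt <- s_ref
      placed <- 0L; guard <- 0L
      while (placed < nsub && guard < 200L) {
        guard <- guard + 1L
        pos <- sample((cds_s[i] + 1L):cds_e[i], 1L)
        if (s_alt[pos] != s_ref[pos]) next
        cand <- sample(setdiff(c("A", "C", "G", "T"), s_ref[pos]), 1L)
        off <- pos - cds_s[i] - 1L
        c0 <- cds_s[i] + 3L * (off %/% 3L) + 1L
        codon <- s_alt[c0:(c0 + 2L)]
        codon[off %% 3L + 1L] <- cand
        if (paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA")) next
        s_alt[pos] <- cand
        placed <- placed + 1L
        het_rows[[length(het_rows) + 1L]] <- data.frame(
          transcript_id = ids[i], position = pos, ref = s_ref[pos],
          alt = cand, stringsAsFactors = FALSE)
      }
      alt_alleles[ids[i]] <- paste(s_alt, collapse = "")
    }
    het_sites <- if (length(het_rows)) do.call(rbind, het_rows)
                 else data.frame(transcript_id = character(),
                                 position = integer(), ref = character(),
                                 alt = character(), stringsAsFactors = FALSE)

    ## expression: family weight split over members, toxin share of total
    member_share <- unlist(lapply(split(seq_len(n_tox), fam_of[seq_len(n_tox)]),
      function(ix) {
        u <- stats::runif(length(ix), 0.2, 1)
        stats::setNames(u / sum(u), ids[ix])
      }), use.names = TRUE)
    names(member_share) <- sub("^.*\\.", "", names(member_share))
    fam_w <- stats::setNames(fam_weights, fam_names)
    w_tox <- member_share[ids[seq_len(n_tox)]] *
      fam_w[fam_of[seq_len(n_tox)]] * config@toxin_fraction_of_reads
    w_non <- if (config@n_nontoxin > 0) {
      u <- stats::rlnorm(config@n_nontoxin, config@lognormal_meanlog,
                         config@lognormal_sdlog)
      (1 - config@toxin_fraction_of_reads) * u / sum(u)
    } else numeric(0)
    weights <- c(unname(w_tox), w_non)
    weights <- weights / sum(weights)
    expression <- data.frame(transcript_id = ids, family = fam_of,
                             weight = weights, stringsAsFactors = FALSE)
    families <- data.frame(family = fam_names, toxin_class = classes,
                           size = config@family_sizes,
                           weight = unname(fam_w), stringsAsFactors = FALSE)
    list(records = records, alt_alleles = alt_alleles,
         truth = list(families = families, het_sites = het_sites,
                      expression = expression))
  })
}

#' Simulate paired reads from a (possibly heterozygous) transcriptome
#'
#' Fragments are drawn per transcript proportionally to its expression
#' weight, with the two alleles of heterozygous transcripts sampled 50/50.
#' Each fragment (normal length distribution, resampled when shorter than a
#' read or longer than the transcript) yields a 100-nt read from each end,
#' the second reverse-complemented, so most pairs overlap at their 3' ends.
#' Per-base errors are injected at the configured rate with phred scores
#' consistent with it.
#'
#' @param records [TranscriptSet-class] of reference alleles.
#' @param weights named per-transcript expression weights summing to 1.
#' @param config [SimConfig-class]; uses error/fragment/read fields and
#'   `seed + 1` so the read stream is independent of transcriptome
#'   generation.
#' @param alt_alleles named character vector of second-allele sequences (as
#'   from [simulateTranscriptome()]).
#' @return list: `fastq1`, `fastq2` (`QualityScaledDNAStringSet`), `truth`
#'   data.frame (`read_id`, `transcript_id`, `allele`, `frag_start`,
#'   `frag_len`).
#' @export
simulateReads <- function(records, weights, config,
                          alt_alleles = character(0)) {
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  .withSeed(config@seed + 1L, {
    n <- config@n_read_pairs
    rl <- config@read_length
    ids <- transcriptIds(records)
    seqs <- as.character(transcriptSeqs(records))
    names(seqs) <- ids
    tlen <- stats::setNames(Biostrings::width(transcriptSeqs(records)), ids)
    pick <- sample(names(weights), n, replace = TRUE, prob = weights)
    allele <- ifelse(pick %in% names(alt_alleles) &
                       stats::runif(n) < 0.5, "alt", "ref")
    flen <- round(stats::rnorm(n, config@fragment_mean, config@fragment_sd))
    bad <- which(flen < rl | flen > tlen[pick])
    guard <- 0L
    while (length(bad) && guard < 50L) {
      guard <- guard + 1L
      flen[bad] <- round(stats::rnorm(length(bad), config@fragment_mean,
                                      config@fragment_sd))
      bad <- bad[flen[bad] < rl | flen[bad] > tlen[pick[bad]]]
    }
    flen[bad] <- pmin(pmax(rl, config@fragment_mean), tlen[pick[bad]])
    fstart <- floor(stats::runif(n) * (tlen[pick] - flen + 1)) + 1L
    src <- ifelse(allele == "alt", alt_alleles[pick], seqs[pick])
    frag <- substring(src, fstart, fstart + flen - 1L)
    r1 <- substring(frag, 1L, rl)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substring(frag, flen - rl + 1L, flen))))
    inject <- function(reads) {
      k <- stats::rbinom(length(reads), rl, config@error_rate)
      for (i in which(k > 0)) {
        s <- strsplit(reads[i], NULL)[[1]]
        pos <- sample(rl, k[i])
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        reads[i] <- paste(s, collapse = "")
      }
      reads
    }
    r1 <- inject(r1); r2 <- inject(r2)
    q <- if (config@error_rate > 0)
      as.integer(round(-10 * log10(config@error_rate))) else 40L
    qual <- replicate(n, rep(q, rl), simplify = FALSE)
    rid <- sprintf("pair%06d", seq_len(n))
    truth <- data.frame(read_id = rid, transcript_id = unname(pick),
                        allele = allele, frag_start = unname(fstart),
                        frag_len = unname(flen), stringsAsFactors = FALSE)
    list(fastq1 = fastqRecords(rid, r1, qual),
         fastq2 = fastqRecords(rid, r2, qual),
         truth = truth)
  })
}

#' Simulate a codon alignment under a site-model mixture
#'
#' Root codons are drawn from the stationary frequencies; each site is
#' assigned a class with the mixture probabilities and evolved along the
#' tree with exact transition probabilities (matrix exponentials of the
#' jointly scaled class generators, the same scaling [fitCodonModel()]
#' assumes).
#'
#' @param tree `phylo` with positive branch lengths (expected substitutions
#'   per codon).
#' @param spec list: `kappa`, `classes` (data.frame `p`, `omega`), `pi`
#'   (length-61, optional; default equal frequencies).
#' @param n_codons number of codon sites.
#' @param seed integer seed.
#' @return list: `alignment` (named character vector, tips of the tree),
#'   `site_class` (integer class index per site).
#' @export
simulateCodonAlignment <- function(tree, spec, n_codons, seed = 1L) {
  tab <- .codonTables()
  pi <- spec$pi
  if (is.null(pi)) pi <- rep(1 / tab$n, tab$n)
  classes <- spec$classes
  .withSeed(seed, {
    eig <- .mixtureEigen(spec$kappa, classes, pi)
    site_class <- sample.int(nrow(classes), n_codons, replace = TRUE,
                             prob = classes$p)
    tr <- stats::reorder(tree, "postorder")
    nt <- length(tr$tip.label)
    nnode <- max(tr$edge)
    states <- matrix(NA_integer_, nnode, n_codons)
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(tab$n, n_codons, replace = TRUE, prob = pi)
    for (e in rev(seq_len(nrow(tr$edge)))) {    # preorder
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t_e <- tr$edge.length[e]
      for (k in unique(site_class)) {
        P <- .probMatrix(eig[[k]], t_e)
        P <- P / rowSums(P)
        sel <- which(site_class == k)
        ps <- states[parent, sel]
        for (s in unique(ps)) {
          ix <- sel[ps == s]
          states[child, ix] <- sample.int(tab$n, length(ix), replace = TRUE,
                                          prob = P[s, ])
        }
      }
    }
    aln <- vapply(seq_len(nt), function(i)
      paste(tab$codons[states[i, ]], collapse = ""), "")
    names(aln) <- tr$tip.label
    list(alignment = aln, site_class = site_class)
  })
}

#' Random coalescent-style tree for simulation
#'
#' Utility for tests and examples: a random topology with exponential
#' branch lengths of a given mean.
#'
#' @param n_taxa number of tips.
#' @param mean_branch mean branch length (expected substitutions per codon).
#' @param seed integer seed.
#' @return unrooted `phylo`.
#' @export
randomTree <- function(n_taxa, mean_branch = 0.2, seed = 1L) {
  .withSeed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_branch)
    tr
  })
}
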
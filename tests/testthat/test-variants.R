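## helper: a pileup list for one transcript with given per-column counts
pile_one <- function(len, cols) {
  m <- matrix(0L, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (nm in names(cols)) {
    j <- as.integer(nm)
    m[, j] <- cols[[nm]]
  }
  m
}

test_that("identical error-free reads give single-base columns", {
  s <- paste0("ATGGCC", random_dna(94))
  ts <- make_ts(c(t1 = s), 0L, 6L, "PLA2")
  reads <- setNames(rep(substr(s, 1, 50), 10), paste0("r", 1:10))
  hits <- data.frame(read_id = names(reads), transcript_id = "t1",
                     start = 0L, identity = 1)
  pile <- buildPileup(hits, reads, ts)
  cov <- colSums(pile$t1)
  expect_equal(unname(cov[1:50]), rep(10, 50))
  expect_equal(unname(cov[51:100]), rep(0, 50))
  expect_true(all(colSums(pile$t1[, 1:50] > 0) == 1))

  empty <- buildPileup(hits[0, ], reads, ts)
  expect_equal(sum(empty$t1), 0)

  hits$start <- 60L
  expect_error(buildPileup(hits, reads, ts), "bounds")
})

test_that("SNP calling honours the frequency window and coverage bounds", {
  len <- 30L
  seq <- strrep("ATG", 10)   # CDS over the whole transcript, stop-free
  ts <- make_ts(c(t1 = seq), 0L, 30L, "PLA2")
  base_cols <- function(a, g) c(A = a, C = 0L, G = g, T = 0L)
  pile <- list(t1 = pile_one(len, list(
    `4` = base_cols(55L, 45L),     # callable: 45%
    `7` = base_cols(61L, 39L),     # 39 < 40: no
    `10` = base_cols(10L, 9L),     # coverage 19 < 20: no
    `13` = base_cols(10L, 10L),    # coverage 20, 50%: callable
    `16` = c(A = 11000L, C = 0L, G = 9000L, T = 0L),  # coverage 20,000: in
    `19` = c(A = 11001L, C = 0L, G = 9000L, T = 0L),  # 20,001: beyond max
    `22` = c(A = 50L, C = 30L, G = 40L, T = 0L)       # tri-allelic: skip
  )))
  calls <- callSnps(pile, ts)
  expect_setequal(calls$position, c(4L, 13L, 16L))
  c4 <- calls[calls$position == 4L, ]
  expect_equal(c4$snp_pct, 45)
  expect_equal(c4$ref_base, "A")
  expect_equal(c4$alt_base, "G")
  ## inclusive boundary at exactly 40%
  pile40 <- list(t1 = pile_one(len, list(`4` = base_cols(60L, 40L))))
  expect_equal(nrow(callSnps(pile40, ts)), 1L)

  ## monotonicity: relaxing the window or coverage never loses calls
  n_strict <- nrow(callSnps(pile, ts, minPct = 45, maxPct = 55,
                            minCov = 30, maxCov = 15000))
  n_default <- nrow(callSnps(pile, ts))
  n_loose <- nrow(callSnps(pile, ts, minPct = 30, maxPct = 70,
                           minCov = 10, maxCov = 30000))
  expect_lte(n_strict, n_default)
  expect_lte(n_default, n_loose)
})

test_that("coding effects agree with an independent translation oracle", {
  ## third-position degeneracy and a first-position replacement
  ts <- make_ts(c(t1 = "GCTGGA"), 0L, 6L, "PLA2")
  syn <- classifySnp(list(position = 3L, ref_base = "T", alt_base = "C"), ts)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_ref, "A")
  rep1 <- classifySnp(list(position = 4L, ref_base = "G", alt_base = "A"), ts)
  expect_equal(rep1$effect, "nonsynonymous")
  expect_equal(paste0(rep1$aa_ref, rep1$aa_alt), "GR")   # Gly -> Arg
  ## alternative allele creating a stop is flagged nonsense
  ts2 <- make_ts(c(t1 = "TGGGGA"), 0L, 6L, "PLA2")
  non <- classifySnp(list(position = 3L, ref_base = "G", alt_base = "A"), ts2)
  expect_equal(non$effect, "nonsense")

  ## exhaustive 61-codon x 3-position x 3-substitution sweep vs seqinr
  tab <- venomtx:::.codonTables()
  for (codon in tab$codons) {
    tset <- make_ts(setNames(paste0(codon, "GGA"), "x"), 0L, 6L, "PLA2")
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- classifySnp(list(position = pos, ref_base = ref,
                                alt_base = alt), tset)
        altc <- codon; substr(altc, pos, pos) <- alt
        aa1 <- seqinr::translate(strsplit(codon, NULL)[[1]])
        aa2 <- seqinr::translate(strsplit(altc, NULL)[[1]])
        want <- if (aa2 == "*") "nonsense"
                else if (aa1 == aa2) "synonymous" else "nonsynonymous"
        expect_equal(got$effect, want,
                     label = paste(codon, pos, alt, got$effect))
      }
    }
  }
})

test_that("the tabulated toxin SNPs are 45.5% nonsynonymous", {
  t3 <- loadFixture("table3")
  tox <- t3[t3$type == "Toxin", ]
  expect_equal(nrow(tox), 11L)
  expect_equal(length(unique(tox$transcript)), 9L)
  expect_equal(round(100 * mean(tox$effect == "nonsynonymous"), 1), 45.5)
  non <- t3[t3$type == "Nontoxin", ]
  expect_equal(nrow(non), 87L)
  expect_equal(round(100 * mean(non$effect == "nonsynonymous"), 1), 26.4)
  ## Kunitz-type inhibitor worked example: G -> R replacement at 42.5%
  kun <- t3[t3$transcript == "Kunitz inhibitor 1a", ]
  expect_equal(paste0(kun$aa_ref, kun$aa_alt), "GR")
})

test_that("SNP density counts SNPs per kb of SNP-containing CDS", {
  s <- strrep("ATG", 400)   # 1200 nt, CDS 999 nt
  ts <- TranscriptSet(c(t1 = s, t2 = s), data.frame(
    id = c("t1", "t2"), name = c("PLA2-1", "NONTOXIN-1"),
    toxin_class = c("PLA2", "NONTOXIN"), cds_start = 0L, cds_end = 999L))
  calls <- data.frame(transcript_id = c("t1", "t1"), position = c(5L, 500L),
                      effect = "synonymous", stringsAsFactors = FALSE)
  expect_equal(snpDensity(calls, ts, "toxin"), 1000 * 2 / 999)
  expect_true(is.na(snpDensity(calls, ts, "nontoxin")))
})

test_that("heterozygosity comparison matches the Pearson 2x2 oracle", {
  res <- heterozygosityTest(9, 75, 69, 1950)
  expect_equal(res$statistic, pearson_2x2_oracle(9, 66, 69, 1881))
  expect_equal(round(res$statistic, 2), 13.96)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, chisqSf(res$statistic, 1))

  eq <- heterozygosityTest(10, 100, 100, 1000)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(heterozygosityTest(1, 0, 5, 10), "positive")
  expect_error(heterozygosityTest(5, 4, 5, 10), "exceed")
})

test_that("chi-square tails match the df=1 and df=2 closed forms", {
  expect_equal(chisqSf(0, 1), 1)
  expect_equal(chisqSf(5.84, 2), exp(-5.84 / 2), tolerance = 1e-12)
  expect_equal(signif(chisqSf(5.84, 2), 3), 0.0539)
  expect_equal(signif(chisqSf(20.02, 2), 3), 4.49e-5)
  expect_equal(signif(chisqSf(6.383, 1), 3), 0.0115)
  for (x in c(0.1, 1, 3.84, 10, 25)) {
    expect_equal(chisqSf(x, 2), exp(-x / 2), tolerance = 1e-12)
    erfc <- 2 * pnorm(sqrt(2) * sqrt(x / 2), lower.tail = FALSE)
    expect_equal(chisqSf(x, 1), erfc, tolerance = 1e-12)
  }
  expect_error(chisqSf(-1, 1), "nonnegative")
})
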
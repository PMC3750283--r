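test_that("mapping assigns substrings at identity 1 and enforces the threshold", {
  set.seed(21)
  t1 <- paste0("ATGGCC", random_dna(494))
  t2 <- paste0("ATGGCC", random_dna(494))
  ts <- make_ts(c(tx1 = t1, tx2 = t2), 0L, 6L, "PLA2")
  read <- substr(t1, 101, 200)
  mp <- mapReads(c(r1 = read), ts, seed = 1)
  expect_equal(mp$hits$transcript_id, "tx1")
  expect_equal(mp$hits$identity, 1)
  expect_equal(mp$hits$start, 100)   # 0-based

  ## 6 mismatches in a 100-nt read: identity 0.94 < 0.95, unmapped
  bad <- read
  for (p in c(30, 40, 50, 60, 70, 80))
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, p, p))[1]
  mp2 <- mapReads(c(r1 = bad), ts)
  expect_equal(mp2$n_unmapped, 1)
  ## 5 mismatches: identity 0.95, mapped
  ok5 <- read
  for (p in c(30, 40, 50, 60, 70))
    substr(ok5, p, p) <- setdiff(c("A", "C", "G", "T"), substr(ok5, p, p))[1]
  mp3 <- mapReads(c(r1 = ok5), ts)
  expect_equal(mp3$n_mapped, 1)
  expect_equal(mp3$hits$identity, 0.95)

  expect_error(mapReads(c(r1 = read), Biostrings::DNAStringSet()), "empty")
})

test_that("tied best hits break deterministically under a fixed seed", {
  set.seed(22)
  s <- paste0("ATGGCC", random_dna(294))
  ts <- make_ts(c(a = s, b = s), 0L, 6L, "PLA2")
  reads <- setNames(rep(substr(s, 51, 150), 40), paste0("r", 1:40))
  h1 <- mapReads(reads, ts, seed = 99)$hits$transcript_id
  h2 <- mapReads(reads, ts, seed = 99)$hits$transcript_id
  expect_identical(h1, h2)
  expect_setequal(unique(h1), c("a", "b"))   # both used across 40 ties
})

test_that("reads simulated at 1% error return to their true cluster", {
  cfg <- simConfig(seed = 41, n_nontoxin = 10L, n_toxin_families = 6L,
                   family_sizes = c(3L, 1L, 2L, 1L, 1L, 2L),
                   expression_model = "lognormal", lognormal_sdlog = 0.5,
                   toxin_fraction_of_reads = 0.5,
                   transcript_length_range = c(400L, 800L),
                   cds_length_range = c(300L, 390L),
                   error_rate = 0.01, n_read_pairs = 5000L)
  sim <- simulateTranscriptome(cfg)
  rd <- simulateReads(sim$records, truth_weights(sim), cfg, sim$alt_alleles)
  mrg <- mergeStream(rd$fastq1, rd$fastq2)
  mp <- mapReads(mrg$merged, sim$records, seed = 41)
  expect_equal(mp$n_mapped + mp$n_unmapped, mp$n_reads)  # conservation
  cl <- clusterTranscripts(sim$records[isToxin(sim$records)])
  cl_of <- setNames(cl$cluster_name, cl$member_id)
  truth_tx <- setNames(rd$truth$transcript_id, rd$truth$read_id)
  hit_tx <- setNames(mp$hits$transcript_id, mp$hits$read_id)
  common <- intersect(names(hit_tx), names(truth_tx))
  same_unit <- function(x, y) {
    cx <- cl_of[x]; cy <- cl_of[y]
    ifelse(is.na(cx) | is.na(cy), x == y, cx == cy)
  }
  acc <- mean(same_unit(hit_tx[common], truth_tx[common]))
  expect_gte(acc, 0.99)
  expect_gte(mp$n_mapped / mp$n_reads, 0.95)
})

test_that("abundance estimation recovers multinomial proportions", {
  set.seed(43)
  seqs <- setNames(vapply(1:3, function(i) paste0("ATGGCC", random_dna(594)),
                          ""), c("A", "B", "C"))
  ts <- make_ts(seqs, 0L, 6L, "PLA2", name = paste0("PLA2-", 1:3))
  cl <- clusterTranscripts(ts)
  prob <- c(A = 0.5, B = 0.3, C = 0.2)
  n <- 20000
  pick <- sample(names(prob), n, TRUE, prob)
  start <- sample(1:500, n, TRUE)
  reads <- setNames(substring(seqs[pick], start, start + 99),
                    paste0("r", 1:n))
  mp <- mapReads(reads, ts, seed = 2)
  ab <- estimateAbundance(mp$hits, cl, n)
  tbl <- ab$cluster_table
  est <- setNames(tbl$pct_toxin_reads / 100, tbl$cluster_name)
  truth <- setNames(prob, paste0("PLA2-", 1:3))
  for (nm in names(truth)) {
    sigma <- sqrt(truth[nm] * (1 - truth[nm]) / n)
    expect_lt(abs(est[nm] - truth[nm]), 3 * sigma + 1e-9)
  }
  expect_equal(sum(tbl$pct_toxin_reads), 100, tolerance = 1e-9)
  expect_true(all(tbl$pct_total_reads <= tbl$pct_toxin_reads + 1e-12))
  expect_error(estimateAbundance(mp$hits, cl, 10), "n_input_reads")
})

test_that("member letters follow descending member abundance", {
  set.seed(44)
  s <- paste0("ATGGCC", random_dna(394))
  s2 <- s; substr(s2, 200, 200) <- setdiff(c("A","C","G","T"),
                                           substr(s2, 200, 200))[1]
  ts <- make_ts(c(x = s, y = s2), 0L, 6L, "PLA2", name = c("PLA2-1","PLA2-1"))
  cl <- clusterTranscripts(ts)
  hits <- data.frame(read_id = paste0("r", 1:10),
                     transcript_id = c(rep("y", 7), rep("x", 3)),
                     start = 0L, identity = 1, stringsAsFactors = FALSE)
  ab <- estimateAbundance(hits, cl, 10)
  lab <- setNames(ab$member_labels$label, ab$member_labels$member_id)
  expect_match(unname(lab["y"]), "a$")
  expect_match(unname(lab["x"]), "b$")
})

test_that("class rollups and within-class shares reproduce the printed table", {
  t1 <- loadFixture("table1")
  cs <- classSummary(t1)
  pla2 <- cs[cs$toxin_class == "PLA2", ]
  expect_equal(pla2$n_clusters, 31)
  expect_equal(round(pla2$pct_toxin_reads, 1), 64.9)
  f3 <- cs[cs$toxin_class == "3FTx", ]
  expect_equal(f3$n_clusters, 15)
  expect_equal(round(f3$pct_toxin_reads, 1), 21.1)
  top5 <- c("PLA2", "3FTx", "LCN", "SVMP", "KUN")
  expect_equal(round(sum(cs$pct_toxin_reads[cs$toxin_class %in% top5]), 1),
               95.1)

  sh <- withinClassShares(t1, "3FTx")
  expect_equal(round(sh$pct_of_class[sh$cluster_name == "3FTx-2"], 1), 22.7)
  expect_gte(sum(sh$pct_of_class[1:4]), 67.0)   # top four 3FTx clusters
  expect_equal(sum(sh$pct_of_class), 100)
  expect_error(withinClassShares(t1, "NOPE"), "unknown")

  ## single-class synthetic input
  one <- data.frame(cluster_name = "KUN-1", toxin_class = "KUN",
                    cluster_size = 1L, pct_toxin_reads = 100,
                    pct_total_reads = 40)
  expect_equal(classSummary(one)$pct_toxin_reads, 100)
  u4 <- data.frame(cluster_name = paste0("KUN-", 1:4), toxin_class = "KUN",
                   cluster_size = 1L, pct_toxin_reads = 25,
                   pct_total_reads = 10)
  expect_equal(withinClassShares(u4, "KUN")$pct_of_class, rep(25, 4))
})
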
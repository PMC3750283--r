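equal_pi <- function() {
  tab <- venomtx:::.codonTables()
  setNames(rep(1 / tab$n, tab$n), tab$codons)
}

test_that("alignment preprocessing drops signal peptides, gaps and stops", {
  set.seed(51)
  core <- vapply(1:4, function(i)
    paste(sample(setdiff(venomtx:::.codonTables()$codons, NULL), 30,
                 TRUE), collapse = ""), "")
  sig <- strrep("ATG", 20)
  aln <- setNames(paste0(sig, core), paste0("s", 1:4))
  out <- preprocessAlignment(aln, signal_codons = 20L)
  expect_equal(unique(nchar(out)), 90)       # 30 codons left
  expect_equal(attr(out, "n_codons"), 30)

  ## a gap column and a mid-frame stop column are removed
  aln2 <- aln
  substr(aln2[2], 61, 63) <- "---"           # codon column 21
  substr(aln2[3], 64, 66) <- "TAA"           # codon column 22
  out2 <- preprocessAlignment(aln2, signal_codons = 20L)
  expect_equal(attr(out2, "n_codons"), 28)
  expect_false(any(c(21L, 22L) %in% attr(out2, "kept_codons")))

  short <- setNames(rep(strrep("ATG", 9), 2), c("a", "b"))
  expect_error(preprocessAlignment(short), "fewer than 10")
})

test_that("the codon rate matrix has generator structure and reversibility", {
  pi <- equal_pi()
  for (par in list(c(2, 0.5), c(5, 2), c(1, 1))) {
    Q <- buildRateMatrix(par[1], par[2], pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    D <- diag(pi)
    expect_lt(max(abs(D %*% Q - t(D %*% Q))), 1e-15)   # detailed balance
  }
  ## kappa = omega = 1, equal pi: all permitted moves share one rate
  Q1 <- buildRateMatrix(1, 1, pi)
  off <- Q1[venomtx:::.codonTables()$adj]
  expect_equal(length(unique(round(off, 14))), 1L)
  ## skewed frequencies remain reversible
  set.seed(52)
  pi2 <- runif(61); pi2 <- pi2 / sum(pi2)
  Q2 <- buildRateMatrix(3, 0.2, pi2)
  D2 <- diag(pi2)
  expect_lt(max(abs(D2 %*% Q2 - t(D2 %*% Q2))), 1e-15)
  expect_error(buildRateMatrix(2, 1, pi2[-1]), "length")
  expect_error(buildRateMatrix(2, 1, pi2 * 2), "sum to 1")
})

test_that("transition probabilities match the series-expansion oracle", {
  pi <- equal_pi()
  Q <- buildRateMatrix(2.5, 0.4, pi)
  es <- venomtx:::.eigenSystem(Q, pi)
  for (t in c(0.1, 0.7)) {
    P <- venomtx:::.probMatrix(es, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
    expect_lt(max(abs(P - expm_series_oracle(Q, t))), 1e-10)
  }
  ## scaling: doubling the generator and halving time leaves P unchanged
  es2 <- venomtx:::.eigenSystem(2 * Q, pi)
  expect_lt(max(abs(venomtx:::.probMatrix(es, 0.4) -
                    venomtx:::.probMatrix(es2, 0.2))), 1e-10)
})

test_that("pruning equals brute-force state enumeration on small instances", {
  tab <- venomtx:::.codonTables()
  pi <- equal_pi()
  set.seed(53)
  ## one sequence: log stationary frequencies, closed form
  one <- setNames(paste(sample(tab$codons, 6, TRUE), collapse = ""), "A")
  sp <- list(kappa = 2, pi = pi, classes = data.frame(p = 1, omega = 0.5))
  expect_equal(siteLogLik(one, spec = sp)$total, 6 * log(1 / 61))

  ## two taxa, one codon: direct 61-state summation
  tr2 <- ape::read.tree(text = "(A:0.13,B:0.21);")
  aln2 <- setNames(c(tab$codons[7], tab$codons[40]), c("A", "B"))
  ll <- siteLogLik(aln2, tr2, sp)$total
  expect_equal(ll, brute_force_loglik(aln2, tr2, 2,
                                      data.frame(p = 1, omega = 0.5), pi),
               tolerance = 1e-8)

  ## three taxa, five codons, two site classes
  tr3 <- ape::read.tree(text = "(A:0.2,B:0.35,C:0.1);")
  cls <- data.frame(p = c(0.7, 0.3), omega = c(0.1, 2.5))
  aln3 <- setNames(vapply(1:3, function(i)
    paste(sample(tab$codons, 5, TRUE), collapse = ""), ""), c("A", "B", "C"))
  sp3 <- list(kappa = 3, pi = pi, classes = cls)
  got <- siteLogLik(aln3, tr3, sp3)$total
  want <- brute_force_loglik(aln3, tr3, 3, cls, pi)
  expect_equal(got, want, tolerance = 1e-8 * abs(want))
})

test_that("the likelihood is invariant under re-rooting (pulley principle)", {
  pi <- equal_pi()
  sp <- list(kappa = 2, pi = pi, classes = data.frame(p = 1, omega = 0.8))
  for (seed in c(61, 62)) {
    tr <- randomTree(6, 0.3, seed = seed)
    sim <- simulateCodonAlignment(tr, list(kappa = 2,
                                           classes = sp$classes), 40,
                                  seed = seed)
    base <- siteLogLik(sim$alignment, tr, sp)$total
    for (tip in c(1, 3, 5)) {
      rr <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[tip]))
      expect_equal(siteLogLik(sim$alignment, rr, sp)$total, base,
                   tolerance = 1e-8)
    }
  }
})

test_that("fitted nested models respect likelihood ordering", {
  tr <- randomTree(5, 0.3, seed = 71)
  sim <- simulateCodonAlignment(
    tr, list(kappa = 2, classes = data.frame(p = c(0.7, 0.3),
                                             omega = c(0.2, 1))),
    80, seed = 71)
  cfg <- list(nStarts = 1, freqs = "equal", branchMode = "scale")
  f1 <- fitCodonModel(sim$alignment, tr, "M1", cfg)
  f2 <- fitCodonModel(sim$alignment, tr, "M2", cfg)
  expect_gte(f2@lnl, f1@lnl - 1e-6)
  f7 <- fitCodonModel(sim$alignment, tr, "M7", cfg)
  f8 <- fitCodonModel(sim$alignment, tr, "M8", cfg)
  expect_gte(f8@lnl, f7@lnl - 1e-6)
  lrt <- codonLrt(f1, f2)
  expect_gte(lrt$lambda, 0)
  expect_error(codonLrt(f1, f8), "nested")
})

test_that("identical sequences drive branch lengths to zero", {
  tab <- venomtx:::.codonTables()
  set.seed(72)
  s <- paste(sample(tab$codons, 30, TRUE), collapse = "")
  aln <- setNames(rep(s, 4), paste0("t", 1:4))
  tr <- randomTree(4, 0.1, seed = 72)
  fit <- fitCodonModel(aln, tr, "M0",
                       list(nStarts = 1, freqs = "equal"))
  expect_lt(max(fit@tree$edge.length), 1e-3)
  expect_equal(fit@lnl, 30 * log(1 / 61), tolerance = 1e-4)
})

test_that("likelihood-ratio arithmetic reproduces the tabulated tests", {
  expect_equal(codonLrt(list(model = "M1", lnl = -1600.40),
                        list(model = "M2", lnl = -1576.50))$lambda, 47.8)
  kun <- codonLrt(list(model = "M1", lnl = -965.08),
                  list(model = "M2", lnl = -962.16))
  expect_equal(kun$lambda, 5.84, tolerance = 1e-9)
  expect_equal(signif(kun$p_value, 3), 0.0539)
  same <- codonLrt(list(model = "M1", lnl = -100),
                   list(model = "M2", lnl = -100))
  expect_equal(same$lambda, 0)
  expect_equal(same$p_value, 1)

  t4 <- loadFixture("table4")
  lrt <- lrtFromNegLnL(t4)
  expect_equal(lrt$consistent,
               c(TRUE, TRUE, TRUE, FALSE))  # printed PLA2 lambda disagrees
  expect_equal(lrt$lambda[t4$toxin_class == "PLA2"],
               2 * (4761.33 - 4359.71))
})

test_that("NJ guide trees recover simple topologies", {
  tab <- venomtx:::.codonTables()
  ## three taxa: the unique unrooted topology
  set.seed(81)
  s <- paste(sample(tab$codons, 60, TRUE), collapse = "")
  aln3 <- setNames(c(s, s, s), c("A", "B", "C"))
  tr3 <- njGuideTree(aln3)
  expect_equal(length(tr3$tip.label), 3L)
  expect_true(all(tr3$edge.length >= 0))

  ## a clean simulated 6-taxon history is recovered
  tr <- randomTree(6, 0.15, seed = 82)
  sim <- simulateCodonAlignment(tr, list(kappa = 2,
    classes = data.frame(p = 1, omega = 0.5)), 400, seed = 82)
  est <- njGuideTree(sim$alignment)
  expect_equal(ape::dist.topo(ape::unroot(tr), est)[1], 0)

  ## identical sequences: all branch lengths zero
  same <- njGuideTree(setNames(rep(s, 4), paste0("x", 1:4)))
  expect_true(all(same$edge.length == 0))
  expect_error(njGuideTree(aln3[1:2]), "3 taxa")
})

test_that("F3x4 frequencies reflect positional composition", {
  aln <- setNames(c("AAATTTGGG", "AAATTTGGG"), c("a", "b"))
  pi <- codonFreqsF3x4(aln)
  expect_equal(sum(pi), 1)
  ## only codons with A/T/G at positions 1/2/3 respectively have mass
  heavy <- pi[pi > 1e-6]
  expect_true(all(grepl("^[ATG][ATG][ATG]$", names(heavy))))
})
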
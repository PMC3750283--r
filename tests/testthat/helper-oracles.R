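## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## Needleman-Wunsch global alignment (match 1, mismatch -1, gap -2) followed
## by the divergence rule: terminal gap columns excluded from the
## denominator, internal gap columns counted as mismatches.
nw_divergence_oracle <- function(a, b) {
  A <- strsplit(a, NULL)[[1]]; B <- strsplit(b, NULL)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  ## traceback
  i <- n; j <- m; pa <- character(); pb <- character()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], 1, -1)) {
      pa <- c(A[i], pa); pb <- c(B[j], pb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      pa <- c(A[i], pa); pb <- c("-", pb); i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j], pb); j <- j - 1
    }
  }
  gap <- pa == "-" | pb == "-"
  lead <- cumsum(!gap) == 0
  trail <- rev(cumsum(rev(!gap)) == 0)
  keep <- which(!(lead | trail))
  sum(pa[keep] != pb[keep]) / length(keep)
}

## Taylor-series matrix exponential (independent of the eigen route)
expm_series_oracle <- function(Q, t, terms = 80) {
  S <- diag(nrow(Q)); term <- diag(nrow(Q))
  for (i in seq_len(terms)) {
    term <- term %*% (Q * t) / i
    S <- S + term
  }
  S
}

## Brute-force codon-alignment likelihood: enumerate all internal-node
## states; transition probabilities from the series-expansion exponential of
## the package's (jointly scaled) class generators. Valid for small trees.
brute_force_loglik <- function(aln, tree, kappa, classes, pi) {
  tab <- venomtx:::.codonTables()
  Qs <- lapply(classes$omega, function(w)
    buildRateMatrix(kappa, w, pi, scale = FALSE))
  rho <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  c0 <- sum(classes$p * rho)
  Qs <- lapply(Qs, function(Q) Q / c0)
  tr <- stats::reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  edges <- tr$edge
  internal <- setdiff(unique(as.vector(edges)), seq_len(nt))
  codmat <- venomtx:::.codonIndexMatrix(aln)[tr$tip.label, , drop = FALSE]
  nsite <- ncol(codmat)
  total <- 0
  root <- edges[nrow(edges), 1]
  for (s in seq_len(nsite)) {
    sitelik <- 0
    for (k in seq_len(nrow(classes))) {
      Ps <- lapply(seq_len(nrow(edges)), function(e)
        expm_series_oracle(Qs[[k]], tr$edge.length[e]))
      grids <- rep(list(seq_len(tab$n)), length(internal))
      states <- as.matrix(expand.grid(grids))
      lik_k <- 0
      for (g in seq_len(nrow(states))) {
        st <- numeric(max(edges))
        st[internal] <- states[g, ]
        st[seq_len(nt)] <- codmat[, s]
        pr <- pi[st[root]]
        for (e in seq_len(nrow(edges)))
          pr <- pr * Ps[[e]][st[edges[e, 1]], st[edges[e, 2]]]
        lik_k <- lik_k + pr
      }
      sitelik <- sitelik + classes$p[k] * lik_k
    }
    total <- total + log(sitelik)
  }
  unname(total)
}

## Pearson chi-square on a 2x2 table, from the definition
pearson_2x2_oracle <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

## single-linkage components from a full divergence matrix (BFS closure)
single_linkage_oracle <- function(div, threshold) {
  n <- nrow(div)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(div[v, ] < threshold & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

## small helper: one-transcript TranscriptSet
make_ts <- function(seqs, cds_start, cds_end, class = "PLA2",
                    name = NULL) {
  ids <- names(seqs)
  class <- rep_len(class, length(seqs))
  if (is.null(name))
    name <- ifelse(class == "NONTOXIN", paste0("NONTOXIN-", seq_along(seqs)),
                   paste0(class, "-", seq_along(seqs)))
  TranscriptSet(seqs, data.frame(
    id = ids, name = name, toxin_class = class,
    cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE))
}

## expression weights named by transcript id from a simulation truth block
truth_weights <- function(sim)
  stats::setNames(sim$truth$expression$weight,
                  sim$truth$expression$transcript_id)
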
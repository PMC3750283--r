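## Codon site models (M0, M1a, M2a, M7, M8) on a fixed tree, pruning
## likelihood, likelihood-ratio tests, and the NJ guide tree.

.codonEnv <- new.env(parent = emptyenv())

## 61 sense codons of the standard code, their amino acids, and the
## single-nucleotide substitution structure (transition / synonymous masks)
.codonTables <- function() {
  if (!is.null(.codonEnv$tab)) return(.codonEnv$tab)
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  gc <- Biostrings::GENETIC_CODE[codons]
  sense <- codons[gc != "*"]
  aa <- unname(gc[gc != "*"])
  n <- length(sense)
  sp <- strsplit(sense, NULL)
  diffpos <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- which(sp[[i]] != sp[[j]])
    diffpos[i, j] <- if (length(d) == 1L) d else 0L
  }
  adj <- diffpos > 0L
  is_ts <- matrix(FALSE, n, n)
  ts_pairs <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j]) {
    d <- diffpos[i, j]
    is_ts[i, j] <- paste0(sp[[i]][d], sp[[j]][d]) %in% names(ts_pairs)
  }
  is_syn <- outer(aa, aa, "==") & adj
  .codonEnv$tab <- list(codons = sense, aa = aa, adj = adj, is_ts = is_ts,
                        is_syn = is_syn, n = n)
  .codonEnv$tab
}

#' Codon substitution rate matrix
#'
#' Goldman-Yang style 61 x 61 generator over the sense codons of the
#' standard code. Multi-nucleotide changes are forbidden; a single-nucleotide
#' change from codon i to j has rate `pi_j`, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. The diagonal makes
#' rows sum to zero and, by default, the matrix is rescaled so the expected
#' number of substitutions per codon per unit time is 1 at stationarity.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS).
#' @param pi stationary codon frequencies (length 61, summing to 1).
#' @param scale rescale to one expected substitution per codon per unit time
#'   (default TRUE).
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
buildRateMatrix <- function(kappa, omega, pi, scale = TRUE) {
  tab <- .codonTables()
  if (length(pi) != tab$n) stop("pi must have length ", tab$n)
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1 (within 1e-9)")
  if (any(pi < 0)) stop("pi must be nonnegative")
  Q <- matrix(0, tab$n, tab$n, dimnames = list(tab$codons, tab$codons))
  Q[tab$adj] <- rep(pi, each = tab$n)[tab$adj]
  Q[tab$adj & tab$is_ts] <- Q[tab$adj & tab$is_ts] * kappa
  Q[tab$adj & !tab$is_syn] <- Q[tab$adj & !tab$is_syn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rho <- -sum(pi * diag(Q))
    if (rho > 0) Q <- Q / rho
  }
  Q
}

## Eigen system of the reversible generator: with D = diag(pi),
## A = D^{1/2} Q D^{-1/2} is symmetric; P(t) = left exp(L t) right.
.eigenSystem <- function(Q, pi) {
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / sq,
       right = t(e$vectors) * rep(sq, each = length(pi)))
}

.probMatrix <- function(es, t) {
  P <- es$left %*% (exp(es$values * t) * es$right)
  P[P < 0] <- 0
  P
}

## Site classes (p_k, omega_k) for each model from primitive parameters.
## M7/M8 use ncat equal-probability beta categories represented by their
## category means.
.betaCategories <- function(p, q, ncat) {
  ## extreme shapes (near the 0.005 bound) make qbeta complain about
  ## precision; the clamped category means below remain usable
  br <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = ncat + 1), p, q))
  means <- ncat * (p / (p + q)) *
    (stats::pbeta(br[-1], p + 1, q) - stats::pbeta(br[-(ncat + 1)], p + 1, q))
  means[!is.finite(means)] <- p / (p + q)
  pmin(pmax(means, 0), 1)
}

.siteClasses <- function(model, params, ncat = 10L) {
  switch(model,
    M0 = data.frame(p = 1, omega = params[["omega"]]),
    M1 = data.frame(p = c(params[["p0"]], 1 - params[["p0"]]),
                    omega = c(params[["omega0"]], 1)),
    M2 = data.frame(p = c(params[["p0"]], params[["p1"]],
                          1 - params[["p0"]] - params[["p1"]]),
                    omega = c(params[["omega0"]], 1, params[["omega2"]])),
    M7 = data.frame(p = rep(1 / ncat, ncat),
                    omega = .betaCategories(params[["pbeta"]],
                                            params[["qbeta"]], ncat)),
    M8 = data.frame(
      p = c(rep(params[["p0"]] / ncat, ncat), 1 - params[["p0"]]),
      omega = c(.betaCategories(params[["pbeta"]], params[["qbeta"]], ncat),
                params[["omega_s"]])),
    stop("unknown model: ", model))
}

## Jointly scaled mixture: one scale factor across classes so that branch
## lengths are expected substitutions per codon averaged over site classes.
.mixtureEigen <- function(kappa, classes, pi) {
  Qs <- lapply(classes$omega, function(w)
    buildRateMatrix(kappa, w, pi, scale = FALSE))
  rho <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  c0 <- sum(classes$p * rho)
  if (c0 <= 0) c0 <- 1
  lapply(Qs, function(Q) .eigenSystem(Q / c0, pi))
}

## --- alignment handling ------------------------------------------------

#' Preprocess a codon alignment for selection analysis
#'
#' Removes the signal-peptide codon columns, every codon column containing a
#' gap in any sequence, and every codon column containing a stop codon in
#' any sequence, recording which original codon columns were kept.
#'
#' @param alignment named character vector (or `DNAStringSet`) of aligned
#'   in-frame coding sequences of equal length divisible by 3.
#' @param signal_codons codon columns occupied by the signal peptide: a
#'   single count n (columns 1..n) or an integer vector of codon indices.
#' @return named character vector of cleaned aligned sequences with
#'   attributes `kept_codons` (original codon-column indices retained) and
#'   `n_codons`.
#' @export
preprocessAlignment <- function(alignment, signal_codons = 0L) {
  seqs <- toupper(as.character(alignment))
  names(seqs) <- if (!is.null(names(alignment))) names(alignment)
  if (is.null(names(seqs))) stop("alignment sequences must be named")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences must have equal length")
  if (w %% 3L != 0L) stop("alignment length must be divisible by 3")
  ncod <- w %/% 3L
  sp <- do.call(rbind, strsplit(seqs, NULL))
  ## a single count n means "the leading n codon columns"; a vector is taken
  ## as explicit codon-column indices
  drop_sig <- if (length(signal_codons) == 1L) seq_len(signal_codons[1])
              else as.integer(signal_codons)
  drop_sig <- drop_sig[drop_sig >= 1 & drop_sig <= ncod]
  stops <- c("TAA", "TAG", "TGA")
  keep <- logical(ncod)
  for (ci in seq_len(ncod)) {
    cols <- (3L * (ci - 1L) + 1L):(3L * ci)
    cod <- apply(sp[, cols, drop = FALSE], 1, paste, collapse = "")
    keep[ci] <- !(ci %in% drop_sig) && !any(grepl("-", cod, fixed = TRUE)) &&
      !any(cod %in% stops)
  }
  if (sum(keep) < 10L)
    stop("fewer than 10 codons remain after preprocessing")
  kept <- which(keep)
  nt_keep <- as.vector(vapply(kept, function(ci)
    (3L * (ci - 1L) + 1L):(3L * ci), integer(3)))
  out <- apply(sp[, nt_keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(seqs)
  attr(out, "kept_codons") <- kept
  attr(out, "n_codons") <- length(kept)
  out
}

## codon index matrix (ntaxa x ncodons), NA for codons with N or other
## non-ACGT characters
.codonIndexMatrix <- function(seqs) {
  tab <- .codonTables()
  sp <- strsplit(toupper(as.character(seqs)), NULL)
  ncod <- length(sp[[1]]) %/% 3L
  m <- matrix(NA_integer_, length(sp), ncod)
  for (i in seq_along(sp)) {
    cods <- vapply(seq_len(ncod), function(ci)
      paste(sp[[i]][(3 * (ci - 1) + 1):(3 * ci)], collapse = ""), "")
    m[i, ] <- match(cods, tab$codons)
  }
  rownames(m) <- names(seqs)
  m
}

#' F3x4 codon frequencies
#'
#' Codon frequencies from position-specific nucleotide frequencies of the
#' alignment, renormalised over the 61 sense codons.
#'
#' @param seqs named character vector of in-frame aligned sequences.
#' @return length-61 frequency vector (codon names attached).
#' @export
codonFreqsF3x4 <- function(seqs) {
  tab <- .codonTables()
  sp <- do.call(rbind, strsplit(toupper(as.character(seqs)), NULL))
  pos <- (seq_len(ncol(sp)) - 1L) %% 3L + 1L
  f <- sapply(1:3, function(p) {
    x <- sp[, pos == p, drop = FALSE]
    x <- x[x %in% c("A", "C", "G", "T")]
    tabx <- table(factor(x, levels = c("A", "C", "G", "T")))
    n <- sum(tabx)
    if (n == 0) rep(0.25, 4) else as.numeric(tabx) / n
  })
  rownames(f) <- c("A", "C", "G", "T")
  cod <- strsplit(tab$codons, NULL)
  pi <- vapply(cod, function(b) f[b[1], 1] * f[b[2], 2] * f[b[3], 3], 0)
  pi <- pi + 1e-12           # guard against structurally absent codons
  pi <- pi / sum(pi)
  names(pi) <- tab$codons
  pi
}

## --- pruning likelihood -------------------------------------------------

## Rooted traversal structure from an (un)rooted ape phylo
.treeStructure <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(edge = tree$edge, lengths = tree$edge.length,
       ntip = length(tree$tip.label), labels = tree$tip.label,
       root = tree$edge[nrow(tree$edge), 1])
}

## per-class log-likelihood per pattern; returns matrix K x npat of log f_k
.classLogLik <- function(ts, codmat, eigens, classes, pi, lengths) {
  nst <- length(pi)
  npat <- ncol(codmat)
  K <- length(eigens)
  out <- matrix(NA_real_, K, npat)
  for (k in seq_len(K)) {
    es <- eigens[[k]]
    Ps <- lapply(lengths, function(t) .probMatrix(es, t))
    partial <- vector("list", max(ts$edge))
    logscale <- numeric(npat)
    for (e in seq_len(nrow(ts$edge))) {
      child <- ts$edge[e, 2]; parent <- ts$edge[e, 1]
      P <- Ps[[e]]
      if (child <= ts$ntip) {
        idx <- codmat[child, ]
        contrib <- matrix(1, nst, npat)
        ok <- !is.na(idx)
        contrib[, ok] <- P[, idx[ok]]
      } else {
        contrib <- P %*% partial[[child]]
      }
      partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                           else partial[[parent]] * contrib
      cs <- .colSums(partial[[parent]], nst, npat)
      if (any(cs < 1e-150)) {         # rescale only when underflow threatens
        s <- pmax(cs, 1e-300)
        partial[[parent]] <- partial[[parent]] * rep(1 / s, each = nst)
        logscale <- logscale + log(s)
      }
    }
    f <- colSums(pi * partial[[ts$root]])
    f[f <= 0] <- 1e-300
    out[k, ] <- log(f) + logscale
  }
  out
}

#' Phylogenetic log-likelihood of a codon alignment under a site model
#'
#' Felsenstein pruning over the tree for each site class, mixed over classes
#' with their probabilities. Branch lengths are expected substitutions per
#' codon (averaged over the site-class mixture). With a single sequence the
#' likelihood reduces to the product of stationary frequencies of its codons.
#'
#' @param alignment named character vector of in-frame aligned sequences
#'   (codons with N are treated as missing data).
#' @param tree `phylo` tree whose tip labels match the alignment names
#'   (ignored for a single sequence).
#' @param spec list with `kappa`, `pi` (61 frequencies) and `classes`
#'   (data.frame with columns `p`, `omega`), e.g. from [.siteClasses()]
#'   internals or [fitCodonModel()].
#' @return list: `total` log-likelihood and `site` per-codon log-likelihoods.
#' @export
siteLogLik <- function(alignment, tree = NULL, spec) {
  seqs <- as.character(alignment)
  if (is.null(names(seqs))) names(seqs) <- names(alignment)
  codmat_full <- .codonIndexMatrix(seqs)
  classes <- spec$classes
  pi <- spec$pi
  if (nrow(codmat_full) == 1L) {
    lw <- log(pi)
    site <- vapply(codmat_full[1, ], function(i)
      if (is.na(i)) 0 else {
        ## mixture over classes is irrelevant at stationarity
        lw[i]
      }, 0)
    return(list(total = sum(site), site = site))
  }
  if (is.null(tree)) stop("a tree is required for >= 2 sequences")
  if (!setequal(tree$tip.label, rownames(codmat_full)))
    stop("tree tip labels must match alignment names")
  ts <- .treeStructure(tree)
  codmat_full <- codmat_full[ts$labels, , drop = FALSE]
  key <- apply(codmat_full, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  codmat <- codmat_full[, upat, drop = FALSE]
  map <- match(key, key[upat])
  eigens <- .mixtureEigen(spec$kappa, classes, pi)
  ll <- .classLogLik(ts, codmat, eigens, classes, pi, ts$lengths)
  site_pat <- .mixLogLik(ll, classes$p)
  site <- site_pat[map]
  list(total = sum(site), site = site)
}

## log of the class mixture from a K x npat matrix of per-class log-likelihoods
.mixLogLik <- function(ll, p) {
  K <- nrow(ll)
  if (K == 1L) return(ll[1, ] + log(p[1]))
  m <- ll[1, ]
  for (k in 2:K) m <- pmax(m, ll[k, ])
  m + log(.colSums(p * exp(ll - rep(m, each = K)), K, ncol(ll)))
}

## --- model fitting ------------------------------------------------------

.modelParamInfo <- function(model) {
  switch(model,
    M0 = list(names = "lomega", lower = log(1e-4), upper = log(999),
              init = log(0.3)),
    M1 = list(names = c("lp0", "lomega0"), lower = c(-15, -15),
              upper = c(15, 15), init = c(0, qlogis(0.2))),
    M2 = list(names = c("lp0", "lp1", "lomega0", "lomega2"),
              lower = c(-15, -15, -15, log(1e-6)),
              upper = c(15, 15, 15, log(998)),
              init = c(0, 0, qlogis(0.2), log(1))),
    M7 = list(names = c("lpbeta", "lqbeta"), lower = rep(log(0.005), 2),
              upper = rep(log(99), 2), init = c(log(0.5), log(1.5))),
    M8 = list(names = c("lpbeta", "lqbeta", "lp0", "lomega_s"),
              lower = c(log(0.005), log(0.005), -15, log(1e-6)),
              upper = c(log(99), log(99), 15, log(998)),
              init = c(log(0.5), log(1.5), qlogis(0.9), log(1))),
    stop("unknown model: ", model))
}

.rawToPrimitive <- function(model, raw) {
  switch(model,
    M0 = c(omega = unname(exp(raw[["lomega"]]))),
    M1 = c(p0 = unname(stats::plogis(raw[["lp0"]])),
           omega0 = unname(stats::plogis(raw[["lomega0"]]))),
    M2 = {
      p0 <- stats::plogis(raw[["lp0"]])
      p1 <- (1 - p0) * stats::plogis(raw[["lp1"]])
      c(p0 = unname(p0), p1 = unname(p1),
        omega0 = unname(stats::plogis(raw[["lomega0"]])),
        omega2 = unname(1 + exp(raw[["lomega2"]])))
    },
    M7 = c(pbeta = unname(exp(raw[["lpbeta"]])),
           qbeta = unname(exp(raw[["lqbeta"]]))),
    M8 = c(pbeta = unname(exp(raw[["lpbeta"]])),
           qbeta = unname(exp(raw[["lqbeta"]])),
           p0 = unname(stats::plogis(raw[["lp0"]])),
           omega_s = unname(1 + exp(raw[["lomega_s"]]))))
}

#' Fit a codon site model on a fixed tree topology
#'
#' Maximises the pruning likelihood over branch lengths, kappa and the
#' model's site-class parameters by bounded quasi-Newton (L-BFGS-B) search
#' from several seeded starts, keeping the best. Supported models: `M0`
#' (one ratio), `M1` (nearly neutral, omega0 estimated), `M2` (positive
#' selection), `M7` (beta), `M8` (beta plus a selected class). The dN/dS
#' ratio is bounded above at 999; beta shape parameters lie in
#' `[0.005, 99]`; M7/M8 use `ncat` equal-probability beta categories.
#'
#' @param alignment named character vector of in-frame aligned sequences
#'   (ideally from [preprocessAlignment()]).
#' @param tree `phylo` guide tree (topology fixed; lengths used as starting
#'   values), e.g. from [njGuideTree()].
#' @param model one of `"M0"`, `"M1"`, `"M2"`, `"M7"`, `"M8"`.
#' @param config list of options: `nStarts` (default 5), `seed` (default 1),
#'   `freqs` (`"f3x4"` default, or `"equal"`), `ncat` (default 10),
#'   `branchMode` (`"joint"` optimises every branch length, `"scale"` a
#'   single scale factor on the input lengths, `"fixed"` holds them),
#'   `maxit` (default 200), `factr`/`pgtol` (L-BFGS-B convergence controls;
#'   the default `factr = 1e5` keeps nested-model likelihood orderings
#'   within about 1e-7).
#' @return A [CodonModelFit-class].
#' @export
fitCodonModel <- function(alignment, tree, model = "M0", config = list()) {
  cfg <- utils::modifyList(list(nStarts = 5L, seed = 1L, freqs = "f3x4",
                                ncat = 10L, branchMode = "joint",
                                maxit = 200L, factr = 1e5, pgtol = 0),
                           config)
  seqs <- as.character(alignment)
  if (is.null(names(seqs))) names(seqs) <- names(alignment)
  pi <- if (identical(cfg$freqs, "equal"))
    stats::setNames(rep(1 / 61, 61), .codonTables()$codons)
  else codonFreqsF3x4(seqs)
  tree <- stats::reorder(tree, "postorder")
  nedge <- nrow(tree$edge)
  t0 <- tree$edge.length
  if (is.null(t0)) t0 <- rep(0.1, nedge)
  t0 <- pmax(t0, 1e-4)
  info <- .modelParamInfo(model)

  bl_par <- switch(cfg$branchMode,
    joint = list(names = paste0("lt", seq_len(nedge)),
                 lower = rep(log(1e-6), nedge), upper = rep(log(20), nedge),
                 init = log(t0)),
    scale = list(names = "lscale", lower = log(1e-4), upper = log(1e3),
                 init = 0),
    fixed = list(names = character(), lower = numeric(), upper = numeric(),
                 init = numeric()),
    stop("branchMode must be joint, scale or fixed"))
  par_names <- c(bl_par$names, "lkappa", info$names)
  lower <- c(bl_par$lower, log(0.05), info$lower)
  upper <- c(bl_par$upper, log(50), info$upper)
  init <- c(bl_par$init, log(2), info$init)
  names(init) <- par_names

  codmat_full <- .codonIndexMatrix(seqs)
  ts <- .treeStructure(tree)
  codmat_full <- codmat_full[ts$labels, , drop = FALSE]
  key <- apply(codmat_full, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  codmat <- codmat_full[, upat, drop = FALSE]
  wpat <- as.numeric(table(match(key, key[upat]))[
    as.character(seq_len(sum(upat)))])

  negll <- function(par) {
    names(par) <- par_names
    lengths <- switch(cfg$branchMode,
      joint = exp(par[seq_len(nedge)]),
      scale = t0 * exp(par[["lscale"]]),
      fixed = t0)
    kappa <- exp(par[["lkappa"]])
    prim <- .rawToPrimitive(model, par)
    classes <- .siteClasses(model, as.list(prim), cfg$ncat)
    if (any(classes$p < 0) || any(!is.finite(classes$omega))) return(1e10)
    eig <- .mixtureEigen(kappa, classes, pi)
    ll <- .classLogLik(ts, codmat, eig, classes, pi, lengths)
    tot <- sum(wpat * .mixLogLik(ll, classes$p))
    if (!is.finite(tot)) return(1e10)
    -tot
  }

  best <- NULL
  .withSeed(cfg$seed, {
    for (s in seq_len(cfg$nStarts)) {
      p0v <- if (s == 1L) init else {
        jit <- init + stats::rnorm(length(init), sd = 0.5)
        pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
      }
      fit <- tryCatch(
        stats::optim(p0v, negll, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = cfg$maxit, factr = cfg$factr,
                                    pgtol = cfg$pgtol)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("all optimisation starts failed for model ", model)
  par <- best$par
  names(par) <- par_names
  lengths <- switch(cfg$branchMode,
    joint = exp(par[seq_len(nedge)]),
    scale = t0 * exp(par[["lscale"]]),
    fixed = t0)
  fitted_tree <- tree
  fitted_tree$edge.length <- unname(lengths)
  prim <- .rawToPrimitive(model, par)
  classes <- .siteClasses(model, as.list(prim), cfg$ncat)
  methods::new("CodonModelFit", model = model,
               kappa = unname(exp(par[["lkappa"]])), pi = pi,
               site_classes = classes, params = prim, tree = fitted_tree,
               lnl = -best$value, convergence = as.integer(best$convergence),
               n_starts = as.integer(cfg$nStarts))
}

#' Likelihood-ratio test between nested codon site models
#'
#' `lambda = 2 (lnL_alt - lnL_null)` compared to a chi-square distribution
#' with two degrees of freedom. Only the nested pairs M1-vs-M2 and M7-vs-M8
#' are accepted. Slightly negative statistics (optimizer slack above
#' `-1e-6`) are clamped to zero; larger negatives are flagged as a
#' convergence failure.
#'
#' @param null_fit,alt_fit [CodonModelFit-class] objects (or lists with
#'   `model` and `lnl` entries).
#' @return list: `lambda`, `df` (2), `p_value`, `flagged`.
#' @export
codonLrt <- function(null_fit, alt_fit) {
  getf <- function(x, f) if (methods::is(x, "CodonModelFit"))
    methods::slot(x, f) else x[[f]]
  nm <- getf(null_fit, "model"); am <- getf(alt_fit, "model")
  if (!(identical(c(nm, am), c("M1", "M2")) ||
        identical(c(nm, am), c("M7", "M8"))))
    stop("not a supported nested pair: ", nm, " vs ", am)
  lambda <- 2 * (getf(alt_fit, "lnl") - getf(null_fit, "lnl"))
  flagged <- FALSE
  if (lambda < 0) {
    if (lambda > -1e-6) lambda <- 0
    else { flagged <- TRUE; warning("negative LRT statistic (", lambda,
                                    "): convergence failure") }
  }
  list(lambda = lambda, df = 2L, p_value = chisqSf(max(lambda, 0), 2),
       flagged = flagged)
}

#' Neighbor-joining guide tree
#'
#' Neighbor joining on Jukes-Cantor-corrected pairwise nucleotide distances;
#' saturated pairs (where the JC logarithm is undefined) fall back to the
#' uncorrected distance. Negative NJ branch lengths are clamped to zero.
#'
#' @param alignment named character vector of aligned sequences (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
njGuideTree <- function(alignment) {
  seqs <- toupper(as.character(alignment))
  if (is.null(names(seqs))) names(seqs) <- names(alignment)
  if (length(seqs) < 3L) stop("neighbor joining needs at least 3 taxa")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), NULL)))
  d_jc <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  d_raw <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  d <- as.matrix(d_jc)
  draw <- as.matrix(d_raw)
  bad <- !is.finite(d)
  if (any(bad)) d[bad] <- draw[bad]
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Selection-test summary table
#'
#' One row per alignment/class: taxa count, M1 and M2 proportions and
#' ratios with their -lnL, the one-ratio M0 omega, and the M1-vs-M2 LRT.
#'
#' @param fits named list (per class) of lists with entries `M0`, `M1`, `M2`
#'   ([CodonModelFit-class] objects) and optionally `n`.
#' @return data.frame mirroring a codeml summary: `class`, `n`, `m1_p`,
#'   `m1_omega`, `m1_neg_lnl`, `m2_p`, `m2_omega`, `m2_neg_lnl`, `m0_omega`,
#'   `lambda`, `p_value`.
#' @export
selectionReport <- function(fits) {
  fmt <- function(x) paste(sprintf("%.2f", x), collapse = " ")
  rows <- lapply(names(fits), function(cl) {
    f <- fits[[cl]]
    lrt <- codonLrt(f$M1, f$M2)
    data.frame(
      class = cl,
      n = if (!is.null(f$n)) f$n else length(f$M1@tree$tip.label),
      m1_p = fmt(f$M1@site_classes$p), m1_omega = fmt(f$M1@site_classes$omega),
      m1_neg_lnl = -f$M1@lnl,
      m2_p = fmt(f$M2@site_classes$p), m2_omega = fmt(f$M2@site_classes$omega),
      m2_neg_lnl = -f$M2@lnl,
      m0_omega = unname(f$M0@params[["omega"]]),
      lambda = lrt$lambda, p_value = lrt$p_value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio statistics from a table of -lnL values
#'
#' Recomputes `lambda = 2 (neg_lnl_null - neg_lnl_alt)` and its chi-square
#' (df 2) tail probability from tabulated per-class nearly-neutral and
#' selection-model likelihoods, flagging rows where a tabulated `lambda`
#' disagrees with the likelihoods it was printed beside.
#'
#' @param tbl data.frame with columns `toxin_class`, `m1_neg_lnl`,
#'   `m2_neg_lnl`, and optionally `lambda` (tabulated).
#' @return data.frame: `toxin_class`, `lambda`, `p_value`,
#'   `lambda_tabulated`, `consistent`.
#' @export
lrtFromNegLnL <- function(tbl) {
  lambda <- 2 * (tbl$m1_neg_lnl - tbl$m2_neg_lnl)
  out <- data.frame(toxin_class = tbl$toxin_class, lambda = lambda,
                    p_value = chisqSf(pmax(lambda, 0), 2),
                    stringsAsFactors = FALSE)
  if ("lambda" %in% colnames(tbl)) {
    out$lambda_tabulated <- tbl$lambda
    out$consistent <- abs(out$lambda - tbl$lambda) <= 0.05
  }
  out
}
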
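---
title: "Models and methods behind venomtx"
author: "venomtx maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind venomtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

venomtx analyses venom-gland transcriptomes of the kind produced for small
neurotoxic elapids: a reference set of annotated full-length transcripts
(nontoxins plus toxin transcripts in classes such as PLA2, 3FTx, LCN, SVMP
and KUN), short paired-end reads whose fragments are barely longer than a
single read, and codon alignments of the diverse toxin families. This
vignette records the models, the tunable parameters with their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Data model

`TranscriptSet` pairs a `DNAStringSet` with a per-transcript annotation
(id, class-cluster-letter name such as `PLA2-2a`, toxin class, CDS window).
CDS coordinates are 0-based half-open internally; every user-facing report
prints 1-based positions, which removes off-by-one ambiguity while matching
how positions are conventionally tabulated. Sequences are restricted to
`{A,C,G,T,N}` at parse time: IUPAC ambiguity codes other than N are
rejected because the SNP and codon machinery downstream needs an
unambiguous alphabet. FASTQ input is assumed phred+33 (HiSeq-era data);
there is no autodetection.

## Read merging

Most fragments in this library design are shorter than twice the read
length, so mates overlap at their 3' ends. `mergePair()` scores every
candidate overlap of length at least `minOverlap` (default 10) as
matches − mismatches, discards candidates whose mismatch rate exceeds
`maxMismatchRate` (default 0.1), and keeps the best score, breaking ties
toward the longer overlap. Merged qualities follow a standard consensus
heuristic: agreeing positions get `min(q1 + q2, 93)` (93 is the largest
printable phred+33 score), disagreeing positions keep the higher-quality
base with quality `|q1 − q2|`. The merging criteria of the original
software are not published, so both knobs are configuration; the defaults
are permissive enough that essentially every error-free pair whose true
overlap reaches `minOverlap` merges exactly, which is also the property the
tests assert.

## Toxin clustering

Toxin transcripts are grouped at nucleotide divergence strictly below 1%,
the unit at which expression and allelic variation are reported (a cluster
can contain alleles, recent duplicates, or residual assembly errors).
Divergence is computed on a global Needleman–Wunsch alignment
(`Biostrings::pairwiseAlignment`): terminal gap columns are excluded from
the denominator — so a clean length difference does not look like
divergence — and internal gap columns count as mismatches. Neither the
linkage rule nor the denominator convention is forced by the problem;
single linkage was chosen because the clusters exist precisely to absorb
near-identical variants so that each read maps to a unique unit, and
chaining is the behaviour that achieves this. Complete linkage can be
obtained by swapping the component step. Clusters never span toxin classes
even if two sequences from different classes fall under the threshold,
because cluster names are class-scoped. The representative is the longest
member (ties to the lexicographically smallest id); member letters
`a, b, c, …` are assigned later, by descending member read count, since
abundance is what the letters encode.

## Mapping and abundance

`mapReads()` is a seed-and-extend mapper: exact 21-mer seeds propose
(transcript, diagonal) candidates and a gapless extension over the full
read computes identity = matches / read length, with terminal clipping
disallowed; a read is assigned to its best-identity transcript when that
identity reaches `minIdentity` (default 0.95). Multireads are resolved by
best-hit with a seeded uniform tie-break rather than fractional weighting —
clustering already collapsed the near-identical targets, and a reproducible
hard assignment keeps the pileups simple. Any mapper meeting the identity
contract would do; the gapless design is adequate because the reference is
the transcriptome the reads came from (no splicing, no indel model in the
simulator). Percentages: `pct_toxin_reads` divides by all toxin-mapped
reads and sums to 100 across toxin clusters; `pct_total_reads` divides by
all input reads of the quantification run, mapped or not.

## Heterozygosity

`callSnps()` scans annotated CDS columns of the pileup and calls a site
when coverage lies in `[20, 20000]` and the second-most-common base's read
fraction lies in `[40%, 60%]`, both inclusive ("ranging from 40–60%" is
read as a closed interval). The majority base is reported as ref, the
runner-up as alt, and `snp_pct` is the minor-allele percentage, which keeps
every reported value at or below 60 as in the tabulated data; columns where
more than two bases exceed a 5% noise floor are not callable. With a
diploid 50/50 site at 100x coverage, the binomial count falls inside the
40–60 window about 96% of the time, which is why the caller-recovery test
asks for 95% of planted loci. Effects are classified by translating the
codon with ref and alt base under the standard code; an alt allele creating
a stop is flagged `nonsense` and excluded from the synonymous /
nonsynonymous tallies. SNP density divides SNP count by the summed CDS
length of *SNP-containing* transcripts of the class (per kb). The
toxin-versus-nontoxin comparison is a Pearson chi-square on the 2x2
heterozygous/homozygous table without continuity correction, df = 1. On
the published counts (9/75 versus 69/1950) this statistic is 13.96, not
the 6.383 printed alongside them; `reproduceTables()` reports both the
tail probability at the published statistic and the recomputed Pearson
value, and the discrepancy is deliberately left visible.

## Codon site models

The substitution model is the Goldman–Yang codon model on the 61 sense
codons: single-nucleotide changes only, rate `pi_j` times `kappa` for
transitions and times `omega` for nonsynonymous changes, reversible with
stationary distribution `pi` (default F3x4 from the alignment, equal
frequencies as an option for controlled tests). Site models: M0 (one
ratio), M1a (proportion `p0` with estimated `omega0 < 1`, rest neutral),
M2a (adds a selected class with `omega2 >= 1`), M7 (beta-distributed omega
in K = 10 equal-probability categories represented by their means), M8
(beta plus a selected class). The M1/M2 parameterisation with an
*estimated* omega0 follows the tabulated fits, which show omega0 well
above zero. `omega` is bounded in `[1e-4, 999]` — 999 mirrors the boundary
estimates that occur when a class has no synonymous variation — and beta
shapes in `[0.005, 99]`.

Likelihoods use Felsenstein pruning over unique codon-column patterns, one
pass per site class, mixed with the class probabilities; transition
matrices come from the symmetrized eigendecomposition of the generator.
Site classes share one scale factor (the mixture-averaged rate), so branch
lengths are expected substitutions per codon. Columns are rescaled during
pruning only when their partial likelihoods threaten underflow, so valid
inputs never produce `-Inf`. `fitCodonModel()` maximises over branch
lengths (log-transformed), `kappa` and the class parameters with L-BFGS-B
from `nStarts` seeded starts (default 5), convergence governed by
`factr = 1e5`; `branchMode` can hold relative branch lengths fixed and fit
a single scale, a cheaper regime the replicated power studies use. LRTs
compare M1-vs-M2 or M7-vs-M8 with df = 2; statistics in `(-1e-6, 0)` are
clamped to zero as optimizer slack, anything more negative is flagged as a
convergence failure. Boundary-corrected null mixtures are out of scope;
with df = 2 the test is conservative under the null, which the type-I
study confirms empirically.

Guide trees: neighbor joining on Jukes–Cantor distances (uncorrected
fallback where JC is undefined, negative branch lengths clamped to zero)
provides the fixed topology; branch lengths are refit under the codon
model. This replaces a full ML/Bayesian tree search, which is outside the
package's scope, so likelihood values on real alignments are comparable
only up to the guide-tree approximation. Alignment preprocessing removes
the signal-peptide codon columns (a count of leading columns or explicit
indices — spans are interpreted on alignment columns, the natural unit
after amino-acid-guided alignment), every codon column containing a gap,
and every column containing a stop, recording the kept-column mask; fewer
than 10 remaining codons is an error.

## The synthetic-data generator

`simConfig()` defaults are the study conditions: 1,950 nontoxins; 75 toxin
families whose duplicate counts and expression skew come from the bundled
75-cluster expression table (116 toxin transcripts; top cluster ~5% of
toxin reads, floor ~0.01%); toxins receiving 80.2% of on-transcriptome
reads (45.8 of 57.1 mapped percentage points); heterozygous second alleles
in 12% of toxin and 3.5% of nontoxin transcripts (1–3 CDS substitutions,
sampled 50/50 with no allelic imbalance); 100-nt pairs from fragments of
mean 134 nt (sd 20); 0.1% per-base error with phred-consistent constant
qualities. `paper_like` runs this architecture at 100,000 read pairs —
one hundredth of the study's quantification depth — because full depth
adds nothing to correctness checks. Toxin families are independent random
templates (between-family divergence far above the 1% threshold) whose
duplicates carry a fixed ~0.3% substitution load, guaranteeing
within-family divergence below 1%. The generator does **not** emulate
indels, RNA degradation, positional coverage bias, quality-score decay
along the read, or UTR/CDS compositional differences; passing tests
therefore demonstrate correctness of the algorithms under the stated
error model, not robustness to every artefact of real libraries.

All generator randomness flows from the config seed (reads use seed + 1 so
the read stream does not perturb transcriptome generation), and every
planted truth — family membership, expression weight, allele position,
per-site selection class — is returned in truth tables, enabling exact
recall/precision accounting downstream.

## Problem sizes in the validation suite

The replicated studies in the test suite use sizes chosen to make the
statistics meaningful while keeping a full run of the suite in the minutes
range on one core: dN/dS recovery fits M0 to 20 alignments of 8 taxa x 500
codons simulated at omega = 0.5 (joint branch-length optimisation,
single start); the LRT power and type-I studies use 20 replicates each of
8 taxa x 300 codons (scale-mode branch lengths, single start) under a
strong selection truth (`p2 = 0.2, omega2 = 4`) and a nearly neutral truth
respectively; caller recovery uses a 50-transcript panel (~25 kb of CDS)
at ~100x coverage with 0.1% error. Single-start fits make these checks
conservative: a restart budget could only improve the optima.

## Known limitations

* The mapper is gapless and forward-strand (merged cDNA reads against
  their own transcriptome); it is not a general-purpose aligner.
* M7/M8 category means degrade in precision at extreme beta shapes near
  the 0.005 bound; the clamped means remain valid mixture components.
* The NJ guide tree is an approximation to a full tree search; selection
  tests inherit its topology.
* SNP calling has no genotype-likelihood model, no indels and no phasing;
  it implements exactly the frequency/coverage filter of the reported
  analysis.
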
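---
title: "Entropy- and stationarity-based alignment trimming: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy- and stationarity-based alignment trimming: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocktrim)
```

## The problem

Multiple sequence alignments assembled by automatic pipelines contain columns
that hurt phylogenetic inference: ambiguously aligned or mutationally
saturated regions, and columns whose character-state composition differs
systematically between lineages. blocktrim removes both kinds before tree
inference. The first trimmer scores columns by a similarity-weighted entropy
and keeps conserved blocks; the second removes columns until every pair of
sequences passes a matched-pairs test of compositional homogeneity.

## The entropy-like column score

For column $c$ of an alignment over $r$ canonical states ($r = 4$ for DNA,
$20$ for amino acids), let $\Pi^{(c)}$ be the diagonal matrix of relative
state frequencies among the canonical residues of the column, and let $S$ be
a symmetric non-negative similarity matrix. With
$\mu = 1/\mathrm{trace}(\Pi^{(c)} S)$, the score is the von-Neumann-type
entropy

$$h(c) \;=\; -\mathrm{trace}\!\left[\mu \Pi^{(c)} S \,
  \log_r\!\left(\mu \Pi^{(c)} S\right)\right]
  \;=\; -\sum_s \lambda_s \log_r \lambda_s ,$$

where $\lambda_s$ are the eigenvalues of $\mu\,\Pi^{(c)} S$; the
normalization $\mu$ makes them sum to 1. A constant column scores 0. With
$S = I_r$ the score reduces to the Shannon entropy of the column frequencies
(base $r$), which treats every substitution as equally surprising. Weighting
by a substitution-derived $S$ is the point of the method: a column of the
chemically similar residues I/L/M/V scores much lower than a column of
C/Q/W/Y at the same frequencies, because the former variability is
biologically expected. With our reconstructed BLOSUM50 table (below) the two
scores are about 0.27 and 0.45.

Numerics: the eigenvalues are taken from the symmetric similar matrix
$\mu\,\Pi^{1/2} S\,\Pi^{1/2}$ restricted to the states present in the
column — same spectrum, guaranteed real; eigenvalues below 0 by rounding are
clamped at 0, and $0\log 0 := 0$. Columns with no canonical residue score 0
and are never selected.

## Similarity matrices

* **BLOSUM target frequencies** (`blosum_target(eta)`, eta in 30–95 by 5,
  plus 62, default 62 for amino acids). These are the joint substitution
  probabilities $q_{ij}$ of the BLOSUM series, not the integer log-odds
  scores. The score is invariant to a global rescaling of $S$, so only the
  relative structure of $q$ matters. Stringent levels (95) suit closely
  related sequences; relaxed levels (30) suit distant ones.
* **DNA PAM** (`pam_dna(kappa, eta)`, defaults kappa = 2, eta = 100). PAM-1
  has diagonal 0.99, transitions $0.01\kappa/(2+\kappa)$ and transversions
  $0.01/(2+\kappa)$; PAM-$\eta$ is the $\eta$-th matrix power, computed by
  repeated squaring so rows remain stochastic to machine precision.
* **Identity** (`identity_matrix(r)`), giving plain Shannon entropy.

### Provenance and accuracy of the embedded BLOSUM tables

The real-valued $q_{ij}$ tables are not redistributed with standard toolkits,
which ship only integer log-odds matrices rounded to 1/2–1/5 bit units. The
tables under `inst/extdata/` are therefore *reconstructions*: for each entry
the unrounded log-ratio is estimated by an empirical-Bayes rule whose prior
is the entry's smooth trend across the BLOSUM family (a local-quadratic fit
over the clustering level) and whose posterior is truncated to the entry's
own rounding interval, so every reconstructed entry is exactly consistent
with the published integer matrix. Marginals are then made self-consistent
and the matrix normalized (see `data-raw/make_blosum_targets.R`).

The quantization floor limits accuracy: on worked column-score examples the
reconstruction carries an uncertainty of a few times $10^{-2}$ at coarse
scales. For the I/L/M/V column under BLOSUM50 the package computes
$h \approx 0.268$, whereas computations with the original full-precision
table report $\approx 0.300$ — a discrepancy we attribute to rounding of the
distributed integer matrix, at whose consistency boundary the original value
sits. The C/Q/W/Y value ($\approx 0.451$ here) is insensitive to this.
No integer BLOSUM95 matrix is distributed at all (the public series jumps
from 90 to 100); the BLOSUM95 file is synthesized from the family trend and
carries `synthetic` in its name. Trimming behaviour is robust to these
table-level perturbations because selection depends on a 0.5 threshold, not
on the third decimal of $h$.

## From scores to blocks

1. **Smoothing.** $\tilde h(c)$ averages $h$ over a window of half-width $w$
   (default 1), weighting each column by $1 - g$, its non-gap fraction, with
   the window truncated at the alignment ends. Gaps, missing characters and
   ambiguity codes all count towards $g$; a window with zero weight falls
   back to the raw score.
2. **Classification.** Columns with $\tilde h < 0.5$ (strict) are conserved;
   maximal runs form conserved (C) and variable (V) regions.
3. **Merging.** A variable region flanked by two conserved ones is absorbed
   when the gap-weighted mean of $h$ over the whole span C∪V∪C is below the
   threshold and the span contains less than 30% gaps; passes repeat left to
   right until no merge fires (each merge reduces the region count, so the
   fixpoint is reached in finitely many passes).
4. **Post-filters.** Columns with no canonical residue are dropped; optional
   filters drop columns gappier than `max_col_gap` (off by default) and
   conserved blocks shorter than `min_block` (default 5), the latter
   mirroring the behaviour of the distributed trimming tools.

Codon alignments are translated (universal code) and scored as amino acids;
a kept amino-acid column keeps its three nucleotide columns.

A note on small alignments: with $n$ sequences a column shows at most $n$
states, and with $n = 4$ even a completely scrambled amino-acid column stays
below the 0.5 default threshold (the I/L/M/V example above peaks at
$\log_{20} 4 \approx 0.46$ under the identity). The defaults are tuned for
the tool's intended regime — tens of sequences or more; for very few
sequences, lower the threshold.

## Stationarity-based trimming

For sequences $i, j$ the divergence matrix $F$ counts aligned state pairs
over columns where both residues are canonical. Marginal symmetry of $F$
(equal row and column sums) is the null hypothesis that the two sequences
are compositionally homogeneous; it is tested with Stuart's matched-pairs
statistic $d^{\top} V^{-} d$, $d$ the first $r-1$ marginal differences, $V$
their covariance, with a spectral pseudo-inverse and df = rank$(V)$ when $V$
is singular. The chi-squared approximation is unreliable below roughly 1000
columns (and the exported test warns then), which is why this trimmer is
meant for long concatenates.

The trimmer makes every pair satisfy $p_{ij} > 0.1$ (strictly):

1. **Crude phase.** While any pair fails, remove columns one at a time in
   decreasing $h$ order (ties by column index), re-estimating the affected
   $p_{ij}$ after every removal. This yields a homogeneous core $C$.
2. **Add-and-remove phase.** Rebuild from the full alignment: columns outside
   $C$ are removed one at a time according to their sigma score — the summed
   log-change their removal causes in the pairwise p-values — until all pairs
   pass again. Only columns outside $C$ are eligible, so the selection can
   only grow; passes repeat until it stops growing (normally one pass).

A design point we settled empirically: the sigma ranking must *track the
current set* (we refresh the per-pair removal tables after each small batch
of removals and re-estimate every p-value after every single removal). If
the ranking is instead frozen at the start of a pass, the phase converges to
a degenerate solution on strongly biased data: it retains pairs of biased
columns whose compositional excesses cancel — marginally symmetric, hence
invisible to the test — yet still convergent in their character states, so
downstream tree inference remains biased. With the tracking score, whichever
bias direction is currently in excess is removed next and such balanced
retention cannot persist; on the GC-biased quartet fixtures this is the
difference between rescuing the true topology in essentially all replicates
and failing in most, and it matches the behaviour of removing only a small
fraction of characters on mildly biased real data.

The `sigma_scores()` function exposes the complementary add-one form
$\sigma(c) = \sum_{i<j} \log(p_{ij}^{(c)}/p_{ij})$ used to reason about
candidate columns; a constant column has $\sigma = 0$ exactly (it adds only
diagonal mass to every $F$, leaving $d$ and $V$ unchanged).

Power, not impossibility, ends the crude phase on pathological input: a
two-sequence alignment of pure A↔C mismatches can never be made symmetric,
but once two mismatch columns remain the statistic (= the count) drops below
the 10% critical value and the loop stops with that remnant. An error is
raised only if removal truly empties the alignment.

### Choosing a BLOSUM level from the data

`suggest_blosum_eta()` implements the min–max pairwise-identity rule
($\eta$ = the smallest over sequences of each sequence's best percent
identity) and clamps the recommendation to the supported 30–95 range. It is
advisory: on simulated benchmarks this rule systematically underestimates
the level that trims best, so it should be read as a lower bound, with prior
knowledge of sequence divergence taking precedence.

## The synthetic-data generators

All fixtures are generated in code, seeded, and pure functions of their
parameters.

* `simulate_alignment()` evolves independent columns along an `ape` tree
  under an equal-rate model: F81 for DNA, its 20-state uniform analogue
  ("Poisson") for amino acids. On a branch of length $t$ (expected
  substitutions per site) a site keeps its state with probability
  $e^{-\beta t}$, $\beta = 1/(1 - \sum_k f_k^2)$, else redraws from the
  branch's stationary frequencies $f$ — which may differ per branch, giving
  non-stationary regimes. A JTT-like empirical amino-acid model is
  deliberately not used: the trimmers never consume the generator's rate
  structure, only its column-state patterns, and the uniform model keeps the
  fixture assumptions explicit.
* `make_informative_noise_mix()` emulates the classic benchmark
  construction: ten blocks of 30–70 columns, half simulated on one resolved
  40-taxon model tree (random topology, branch lengths uniform on
  0.02–0.25 — moderately divergent, mostly conserved columns), half on a
  40-taxon star tree with branches of 1.0 (saturated, effectively random
  columns; a star tree of any length carries no topology signal, and long
  branches make the noise visible to an entropy score). Ground-truth column
  labels are returned.
* `make_gc_quartet()` builds the compositional-attraction scenario on the
  quartet ((u,v),(x,y)): a homogeneous fraction of columns evolves with
  uniform frequencies everywhere; the remainder uses 80% GC stationary
  frequencies on the external branches of u and x and 20% GC on those of v
  and y, root composition uniform. Branch lengths are a package choice (no
  published values exist for this construction): external 0.8 for u and x,
  0.05 for v and y, internal 0.05. The long biased branches are necessary
  for the compositional pull to dominate: with short ones (0.2–0.5 tried
  systematically) distance-based inference is simply never fooled, and there
  is no artefact to remove. At 0.8, a biased fraction of 0.4 flips the
  inferred quartet in essentially all seeds while a fully homogeneous
  alignment is still recovered correctly.
* `quartet_topology()` is the minimal estimator used to judge the fixtures:
  F81 pairwise distances (`ape::dist.dna`) and the four-point condition,
  ties broken lexicographically, saturated distances capped with a warning.

What these fixtures do *not* emulate: insertions/deletions (alignments are
gap-free unless constructed otherwise), rate variation across sites,
realistic amino-acid exchangeabilities, alignment error from real aligners.
Passing the regression tests therefore demonstrates the selection logic
under controlled signal/noise structure, not performance on real data.

## Problem sizes used by the test suite

The shipped tests run the quartet experiment on 50 seeded replicates of
length 10,000 at a biased fraction of 0.4 (the stationarity trimmer takes
roughly 2 s per replicate), and the entropy regression on 8 seeded 40-taxon
mixes of ~500 columns. Unit tests use alignments of 2–60 columns with
hand-computable expectations, brute-force oracles for the Stuart statistic
and the sigma scores, and quadrature checks for the chi-squared tail.

## Limitations and scope

* The published benchmark comparisons around this method family — ROC
  studies against other trimmers (Gblocks, trimAl, Noisy), bootstrap/aLRT
  confidence-value distributions, and the mitochondrial and yeast
  supermatrix re-analyses — depend on external aligners, tree programs and
  external data accessions and are not reproduced here; this package
  implements the trimming method itself, the recodings, and self-contained
  simulation evidence that the two trimmers do what they claim.
* The embedded BLOSUM tables are reconstructions with the accuracy limits
  described above; applications needing the historical tables to full
  precision should obtain them independently.
* Stuart's test needs long alignments; with short ones the stationarity
  trimmer stops early for lack of power rather than because composition is
  truly homogeneous.
* Row (sequence) trimming, non-universal genetic codes, frame detection and
  Dayhoff-class recoding are out of scope.
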
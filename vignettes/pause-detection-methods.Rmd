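---
title: "Detecting ribosome pausing with expression-stratified isolation forests"
author: "ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ribosome pausing with expression-stratified isolation forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

## The problem and the model

Ribosome profiling measures, for every codon of every translated ORF, how
many ribosome-protected footprints cover it. A codon where the ribosome
dwells longer accumulates more footprints; these local "pausing peaks"
carry information about decoding speed, cotranslational folding and
collisions. Two properties of the data make peak calling hard: counting
noise grows sharply as expression falls, and coverage is systematically
elevated at both ORF ends (initiation/termination ramps).

`ribopause` treats peak detection as a two-dimensional anomaly-detection
problem. Each codon becomes a point

* `u` — its count divided by the mean count of its ORF (so ORFs of
  different expression are comparable), and
* `x` — its normalized position `(i + 1) / L` for 0-based codon `i` in an
  ORF of `L` sense codons (so ramp-affected termini line up across ORFs of
  any length).

ORFs are first ranked by TPM (computed from the codon counts themselves)
and split into five quantile bins — (0–20%), [20–40%), [40–60%), [60–80%),
[80–100%] — because an outlier in a weakly expressed ORF would be ordinary
coverage in a strongly expressed one. Within each bin all codon points are
stacked and an **Extended Isolation Forest** (EIF) is trained: 200 trees,
each grown on a uniform subsample of ψ points, where ψ is the rounded mean
ORF length of the bin; tree depth is capped at `ceiling(log2(ψ))`. Every
internal node cuts the data with a random hyperplane (normal uniform on the
unit circle, intercept uniform in the node's bounding box) — the fully
extended variant, not axis-parallel cuts. A codon's anomaly score is
`s = 2^(-E[path]/c(ψ))`, where the expected isolation path averages, over
trees, the edges to the codon's leaf plus the standard normalizer
`c(n) = 2(ln(n-1) + γ) - 2(n-1)/n` for the leaf's size. Codons whose score
is at or above the 0.95 quantile of their bin's scores are called pausing
peaks; the flagged codon is interpreted as the P-site codon of the paused
ribosome (A site = +1, E site = −1).

`c(n)` is the asymptotic isolation-forest form of the expected unsuccessful
binary-search-tree path length; the exact expectation is `2·H(n+1) − 2`,
which `c(n)` approaches within 1% by `n ≈ 64`. We use the standard
asymptotic form so scores match the reference construction (`c(2) = 2γ − 1
≈ 0.154`); the two differ only in a monotone rescaling of scores.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nBins` | 5 | TPM quantile bins; ties at an edge go to the lower bin |
| `nTrees` | 200 | forest size; AUC is flat from ~50 trees upward |
| `psi` | mean ORF length per bin | subsample per tree (codons) |
| `thresholdQuantile` | 0.95 | score quantile above which a codon is a peak |
| `seed` | — | expands to independent per-tree streams; runs are bit-reproducible |

The flag rate per bin is `1 − thresholdQuantile` by construction (up to
quantile interpolation and ties, which are all flagged). A consequence
worth stating explicitly: any evaluation of the *flagged set* against rare
ground-truth positives has a false positive rate bounded above by the flag
budget (≈5% at the default threshold), whatever the data look like.

The package also implements the conventional baseline the forest is
compared against: position-specific z-scores, where the mean and SD for
position `i` are taken over the normalized counts at position `i` of all
ORFs in the same TPM bin, excluding the last 10 codons of every ORF.
SD here — and in the injection procedure below — is the sample standard
deviation (`sd()`, denominator n−1); where SD is zero the z-score is
reported as undefined rather than forced to 0.

## What the synthetic translatome emulates

`generateTranslatome()` draws, per ORF: a log-normal codon length (median
400 codons, sdlog 0.45, clamped to [50, 2500]); a log-normal per-codon
expression level (median 2 reads/codon, sdlog 1.6, spanning roughly three
orders of magnitude); and per-codon counts from a negative binomial with
size 10, i.e. variance ≈ 2× mean at mean 10 — overdispersed like RiboSeq
coverage without fitting any real library. Coverage is multiplied by a
linear 5′ ramp (2× at the start codon decaying over 50 codons) and a 3′
ramp (1.5× over the last 20 codons). Sequences are ATG + uniform sense
codons + TAA; a codon-usage table can be supplied. Codon-specific dwell
multipliers act through the codon in the **A site** of the elongating
ribosome (i.e. the count at P-site position `i` is scaled by the dwell of
codon `i+1`), matching the view that tRNA accommodation at the A site is
the rate-limiting step; `dwellSite = "P"` switches the convention.

What it does **not** emulate: ligation/PCR sequence bias, nucleotide-level
periodicity artifacts, multimapping, isoforms, or 5′UTR translation. A
green benchmark therefore demonstrates that the detector recovers planted
coverage anomalies under realistic noise, length and expression
heterogeneity — not that every biological pause in real libraries is found.

The validation benchmark (`injectPauses()`) follows a two-step
construction: every position whose normalized count exceeds **2× the ORF's
SD** of normalized counts is first flattened to the ORF mean, harshly
removing natural extremes; then `Uniform(2.5, 3) × SD` (the same
pre-flattening SD) is added at one random position per ORF — the ground
truth. ORFs whose SD is zero are not flattened and use the translatome
mean SD for the spike, a documented fallback for a degenerate case.
Recovery is scored by rank (Mann–Whitney) AUC, and TPR/FPR of the
0.95-quantile flag set. At the study scale (2,000 ORFs, 5 seeds) the
pipeline reaches AUC ≈ 0.997 and TPR ≈ 0.99; FPR sits just under the 5%
flag budget for the reason given above. Performance is flat across
trees ∈ {50…400} and ψ ∈ 0.5–2× the mean ORF length (spread < 0.02 AUC),
and the forest beats the z-score baseline on ramp-containing data — the 3′
ramp sits at a *fixed relative* but *variable absolute* position, which the
normalized-position feature absorbs and pooled positional statistics do
not.

## Downstream statistics

* **Enrichment** at the E/P/A sites (amino acids, O/N optimality triplets,
  bicodon pairs) uses Fisher's exact test; the reported odds ratio is the
  sample OR `(ad)/(bc)` with the Haldane–Anscombe 0.5 correction applied
  only when a cell is zero (the conditional-MLE estimate is available via
  `estimator = "cmle"`). Multiplicity is handled by Benjamini–Hochberg;
  "significant" means q < 0.05. The background universe is all non-pause
  codon positions of the analyzed ORFs, read at the same site offset — the
  default we adopted since no background definition is forced by the
  statistic itself.
* **Theil–Sen comparison** of per-codon pause fractions between conditions:
  slope = median of pairwise slopes, intercept = median residual; codons
  with |residual| > 3 × MAD are outliers. When the robust fit is exact
  (MAD = 0) any nonzero deviation is flagged, so constructed toys behave
  sensibly.
* **Logo matrices** use `H(l,i) = q(l,i) log2(q(l,i)/p_i)` with
  `0·log 0 = 0`; negative entries mark depletion, and columns are *not*
  forced non-negative. Background `p` defaults to the analyzed proteome's
  residue frequencies.
* **Tripeptide clustering** measures motif similarity with the restricted
  Damerau–Levenshtein (optimal string alignment) distance and groups with
  average-linkage (UPGMA) hierarchical clustering; the linkage and the cut
  (default k = 5) are conventions we chose and expose, since only the
  distance is canonical.
* **tAI** follows the dos Reis construction: absolute adaptiveness
  `W = Σ (1 − s_pairing) · tGCN(anticodon)` over recognizing anticodons
  with the standard eukaryotic wobble rules generated from the genetic code
  (G34:U3, I34:C3, I34:A3, U34:G3; AUG restricted to its Watson–Crick
  anticodon), `w = W/max(W)`, zero-W codons imputed with the geometric mean
  of nonzero `w`, and gene tAI the geometric mean over codons.
* **Metagene traces** average a signal at codon offsets around anchors;
  backgrounds come from seeded random anchor sets of equal size (default
  1000 draws; 2.5/97.5 percentile band). Window sizes are analysis choices
  and therefore explicit parameters.

## Disome geometry

Disome-seq footprints come in two length populations about 3 nt apart; the
package splits them at the antimode of the read-length histogram (ties
toward the lower length) and runs the unchanged pause pipeline per
population. A disome call is the P site of the 3′ **trailing** ribosome;
the **leading** ribosome's P site sits `displacement` codons downstream —
default 10 codons (≈ one 30-nt monosome footprint), a documented geometric
assumption exposed as a parameter. Long-population calls are shifted by one
codon before framing, mirroring the one-codon read-length difference.
`monosomeOverlapTrace()` then asks where monosome pauses fall relative to
disome sites; a peak at `+displacement` only is the signature of a
collision onto a single paused leading ribosome.

## Numerical and degenerate-input choices

* Quantiles (TPM edges, score thresholds) use R's default linear
  interpolation (type 7); ties at a score threshold are all flagged.
* P-site offsets: modal distance from 5′ end to the start codon over
  initiation-proximal reads, ties broken toward the smaller offset;
  "clear periodicity" is quantified as modal-frame fraction ≥ 0.6
  (configurable — the criterion is qualitative in origin).
* Forests: subsampling is without replacement; ψ > n is clamped with a
  warning; nodes stop at depth `ceiling(log2 ψ)`, single points, or
  duplicated points; a cut that fails to separate the points is redrawn a
  bounded number of times before the node becomes a leaf.
* All randomness (trees, backgrounds, simulations) flows from explicit
  integer seeds through counter-based per-stream expansion, so results do
  not depend on call order or threading.
* Problem sizes used in the shipped tests and the benchmark script —
  2,000-ORF translatomes with 5 replicate seeds for recovery, 1,000 ORFs
  for replicate concordance, 800 for hyperparameter sweeps — were chosen as
  the smallest scales at which the quantities stabilize.

## Known limitations

* The flagged-set FPR cannot exceed the flag budget (see above); compare
  flag-set TPR/FPR across tools only at matched flag rates.
* A single anomalous codon in an otherwise exactly uniform bin can be
  missed when ψ is much smaller than the bin, because most subsamples never
  see it; realistic data (anomalies in every ORF) do not have this
  pathology, and ψ can be raised to the bin size for such corner cases.
* The EIF scores are comparable within a bin, not across bins; downstream
  analyses treat bins symmetrically and never rank codons across bins.
* One CDS per ORF id; no isoform handling, no UTRs, codon resolution only.
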
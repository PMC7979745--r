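---
title: "Methods: tiling CRISPRi screen analysis for risk cis-regulatory elements"
author: "crescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling CRISPRi screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescreen)
```

## The problem

Genome-wide association studies place most disease-risk SNPs in
noncoding DNA, often inside cis-regulatory elements (CREs) such as
enhancers marked by DNase hypersensitivity and H3K27ac. Whether a
risk-SNP-containing CRE (rCRE) actually matters for cell growth cannot
be read off chromatin marks; it can be asked directly with CRISPR
interference (CRISPRi): dCas9–KRAB is tiled across each element with
many sgRNAs, a pooled library is grown for ~16 days, and elements whose
guides drop out of the population are called essential. `crescreen`
implements the computational arm of such a screen end to end — guide
design, counting, window-level scoring, cross-cell-line comparison,
epigenomic/genetic association, and a methylation-stratified eQTL
analysis that asks whether a risk genotype's effect on a nearby
oncogene is masked by CTCF insulation — together with seeded synthetic
data generators that plant known effects so every stage can be
validated by parameter recovery.

## Guide design

Candidate discovery enumerates every 20-nt protospacer adjacent to an
NGG PAM on both strands. The cut/repression reference point is placed
between protospacer positions 17 and 18 (3 bp 5' of the PAM), and
guides are assigned to windows by that coordinate, since CRISPRi
silencing centers there. Efficiency filtering is deliberately
rule-based: GC fraction in [0.20, 0.80], no `TTTT` (a Pol III
terminator for U6-driven guides), no homopolymer longer than 5, and
protospacer length 20 (19 allowed). Published design tools layer
learned efficiency scores on top of these rules; we keep only the hard
consensus filters, because they are reproducible without training data
and the screen's statistics do not depend on soft efficiency ranking.
Specificity is exact-match occurrence counting of protospacer+NGG
genome-wide on both strands (a 0-mismatch contract, the same one used
when counting screen reads); a guide passes only with exactly one
occurrence. Mismatch-tolerant off-target scores are out of scope.

Declustering lays an ideal anchor grid at `spacing` (default 20 bp,
i.e. 5 guides per 100 bp, the library density the design targets) and
matches anchors to passing cut sites. A per-anchor greedy "nearest
unused candidate" rule can strand a middle anchor when candidates
cluster, so the implementation solves the matching globally: first the
bottleneck (minimax) deviation between sorted anchors and sorted cut
sites is found by binary search with greedy interval matching, then a
non-crossing dynamic program minimizes total deviation among
bottleneck-optimal assignments, with deterministic tie-breaking. This
construction guarantees that whenever any assignment keeps every guide
within half a spacing of its anchor, the selected set has no adjacent
gap wider than twice the spacing.

Intervals wider than 400 bp are split into consecutive 400-bp regions
sharing a parent id (so that adjacent splits can be merged after
scoring). A trailing remainder shorter than 200 bp is absorbed by the
last window; 200 bp or more becomes its own short region — the
split-point choice is ours, logged per region, since any fixed rule is
equally defensible. Promoter controls are 400-bp windows centered on
TSSs. Duplicate protospacers selected in two regions are emitted once,
flagged ambiguous, and excluded from window statistics. Synthesis
oligos are the exact concatenation of the vector's fixed arms around
the protospacer.

## Screen scoring

**Normalization.** Median-of-ratios size factors (the DESeq
construction): each sample's factor is the median over guides of the
count divided by the guide's geometric mean across samples, with
guides containing a zero excluded from the reference set.

**Guide-level test.** Counts are modeled as negative binomial with
variance `mu + alpha * mu^2`. A single pooled `alpha` is estimated from
the moment identity `E[s^2 - kappa*m] = alpha * mu^2` (with `kappa` the
Poisson part of a normalized count), accumulated over all guides and
timepoints. We solve it as a ratio of sums rather than a per-guide
regression of `s^2 - m` on `m^2`: with two replicates the squared
sample mean is a noisy, upward-biased estimate of `mu^2`, and using it
as a regressor attenuates `alpha` by roughly 40%, which in turn
inflates the one-sided type-I error from ~0.05 to ~0.11. The
ratio-of-sums form sums numerator and denominator before dividing and
iteratively corrects `E[m^2]` by `(kappa*m + alpha*m^2)/r`; it recovers
the generator's dispersion to within a few percent and calibrates the
test (per-seed type-I in [0.04, 0.06] at nominal 0.05 in the
acceptance checks). The test itself is a Wald test on the log2 fold
change of normalized means (pseudocount 0.5, symmetric, avoids log(0)),
with the delta-method standard error under the NB; the one-sided
depletion p is half the two-sided p for negative fold changes.

**Windows.** Each region is split into 100-bp windows at a 50-bp
offset, windows wholly inside the region, requiring at least two
guides. Guides are ranked library-wide by one-sided depletion p (the
ranking statistic is our choice; the alternative — ranking by a fold
change — is less stable at screen depth), and a window is scored by
alpha-RRA: among its members' rank percentiles, the minimum Beta
order-statistic probability over members passing a significance gate
(one-sided p < 0.25, configurable; gating keeps clearly null guides
from diluting the order statistic). Window p-values come from permuting
the guide-to-window assignment over the whole library, with the null
shared across windows of equal size; all member subsets are enumerated
exactly when `choose(n, m)` is at most `exact_limit` (default 2e4 — a
pure-R enumeration bound chosen for routine runtimes; raise it for
exact p-values on larger designs) and sampled (default 10,000
permutations, seeded) otherwise. A region is summarized by its
lowest-p window; sibling regions from one split parent merge to their
single most essential window. The region's depletion score is the
representative window's RRA score — smaller is more essential — and
`-log10` of it is reported alongside for ranking and plotting.

## Comparative essentiality

Two screens are compared by OLS of one score vector on the other, with
differential regions flagged by the mean-shift outlier test: externally
studentized residuals against a t distribution with n − 3 degrees of
freedom, Bonferroni-adjusted by the number of regions, flagged below
0.1. Removal-and-refit is performed once, not iterated. Dependent
evidence across screens is combined by the empirical Brown's method:
Fisher's statistic referred to a scaled chi-square whose degrees of
freedom and scale are calibrated from the empirical covariance of
`-2 log` right-tail ECDF transforms of the underlying score vectors,
capped at Fisher's values when the empirical variance undershoots
independence. With independent inputs this reproduces Fisher; with a
duplicated input it returns the single p. Locus enrichment of essential
regions uses a 1-df Pearson chi-square without continuity correction on
the in/out-locus × essential/not table; "essential" is an explicit
threshold rule recorded in the output (default region p < 0.05), and
sparse tables (any expected cell < 1) are flagged with a Fisher exact
fallback.

## Epigenome and SNP association

Per-region signal is the maximum track value over any base (bedGraph
semantics; uncovered bases contribute 0, matching coverage-track
conventions, and fully uncovered regions are counted). Skewed signal
distributions are rank-inverse-normalized, `qnorm((rank - 0.5)/n)` with
average ranks for ties, before regression; Spearman and Pearson
correlations are reported per mark with significance tiers at
0.05/0.01/0.005. Each rCRE is represented by the highest odds ratio
among risk SNPs within its 600-bp window, interpreted as the 400-bp
core ±100 bp (the window's anchoring is not fixed by convention, so the
flank is a logged, configurable parameter); the top quartile of regions
by depletion score — per screen and their intersection, both emitted —
is compared with the rest by a rank-sum test. PWM scanning scores every
window on both strands and calls hits at min-max normalized similarity
`(S - S_min)/(S_max - S_min)` of at least 0.75. The
methylation–binding correlation uses Spearman's rho with the exact
small-sample null distribution (exact for n ≤ 9 via the standard
algorithm, Edgeworth-corrected just above; verified against brute-force
permutation at n = 8).

## Methylation-stratified eQTL

Expression is Box-Cox transformed with a fixed lambda of −0.1 (an
input, never re-estimated; non-positive values are an error rather than
silently offset). The cohort is dichotomized at the median methylation
of the insulator CpG — ties go to the low stratum, a deterministic
policy we fixed since the convention is not standard — and transformed
expression is regressed on additive risk-allele dosage (0/1/2; additive
coding is the field default when the original coding is unstated)
separately per stratum, with a pooled genotype × stratum interaction
model reported alongside. No covariates enter by default; a hook
exists. Stratum-specific co-expression is the Pearson correlation of
Box-Cox-transformed expression between the focal gene and each
neighbor, per stratum.

## The synthetic-data generators

All generators are pure functions of a configuration and a master seed;
each derives an independent sub-stream, so adding one generator never
shifts another's draws, and identical inputs give byte-identical output
files.

- **Genome**: one chromosome of uniform ACGT with non-overlapping
  400-bp target regions. PAM-rich regions are built on a period-3
  scaffold (`x G G` repeated) guaranteeing a forward-strand GG at least
  every 3 bp; the free base is drawn AT-leaning with occasional G
  (which adds offset PAMs) and rare C, so protospacers stay inside the
  GC filter and are essentially unique genome-wide.
- **Screen counts**: day-0 counts are NB(depth × a_g, alpha) with
  log-normal guide abundances a_g (sigma 0.5, mimicking library skew;
  the real library's skew and dispersion are not published, so these
  defaults are explicit placeholders), mean depth 500 reads per guide
  and dispersion 0.15; day-16 expectations are scaled by 2^effect for
  guides in planted regions. Two replicates per timepoint. Ground truth
  is emitted as a sidecar table, never encoded in names.
- **Signal track**: four piecewise-constant segments per region whose
  maximum is a linear blend `rho * z + sqrt(1 - rho^2) * noise` of the
  supplied essentiality z, shifted by a constant to be strictly
  positive — a linear shift leaves the Pearson correlation untouched
  and keeps `|rho| = 1` exact.
- **Cohort**: genotype ~ Binomial(2, maf = 0.3); methylation a
  balanced Beta(2,8)/Beta(8,2) mixture (bimodal on [0,1], echoing a
  "highly variable" insulator CpG without claiming its exact shape);
  latent expression Gaussian on the Box-Cox(−0.1) scale with total
  residual sd 0.5, the genotype effect (default 0.4) acting only above
  the methylation threshold (0.5, near the mixture median so the
  analysis median split recovers the true strata). A fraction r = 0.7
  of the residual variance is a factor shared with one neighbor gene in
  the high stratum only, so the in-stratum co-expression targets r. The
  residual sd is set so a 0.4 dosage effect in a 64-sample stratum is a
  ~4-sigma signal — a strong cis-eQTL, which is what the analysis is
  meant to detect. Latent values are mapped through the inverse Box-Cox
  to strictly positive expression.

What the generators do *not* emulate: sequencing error and read-level
artifacts (counts are emitted directly), PCR jackpotting, copy-number
and chromatin context effects on guide efficacy, linkage structure
among SNPs, cell-type mixtures in the cohort, and any dependence
between the screen and cohort worlds. Passing recovery tests therefore
demonstrates that the estimators are correct and calibrated under their
stated models — not that real screens meet those models.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally and on disk;
  1-based only in prose.
- Dispersion clamped at 0; a sample of all zeros is an error, not a
  silent drop. Guides with a zero in any sample are excluded from the
  normalization reference only.
- Windows with fewer than two guides are dropped; a region with no
  qualifying window gets p 1 and a flag.
- Permutation p-values use the add-one convention
  `(1 + #{null <= obs}) / (N + 1)`.
- Tie-breaks: candidate selection prefers smaller coordinate then
  lexicographically smaller protospacer; the best window prefers
  smaller p, then smaller score, then smaller start; median ties in the
  cohort go to the low stratum.
- Constant inputs short-circuit with NA and a recorded reason
  (correlations) or zeros with a warning (rank-inverse normal).
- Test problem sizes: calibration suites use 20 seeds × 2,000 guides,
  500-seed null batteries for level checks, 100 seeds for eQTL
  recovery and 50 for co-expression; oracle-equivalence suites use
  1,000 random sequences for PAM scanning and exhaustive enumeration
  elsewhere. These sizes give Monte-Carlo error comfortably inside the
  asserted bands.

## Known limitations

Off-target assessment is exact-match only; no learned guide-efficiency
scores; no copy-number or MOI correction; single-chromosome synthetic
genomes; the Brown combination is exposed per region pair and globally,
but which construction a given published figure used is ambiguous and
not claimed; cohort regressions carry no population-structure
correction. Published effect sizes from real screens and cohorts of
this kind depend on deposited or controlled-access data and are
deliberately not asserted anywhere in this package; every quantitative
claim here is recomputed from the synthetic generators by the test
suite and the acceptance script.
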
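---
title: "Methods: integrative transcriptome–volatilome correlation analysis"
author: "volnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative transcriptome-volatilome correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical methods: the
models and rules it implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The design and data model

The intended experiment profiles the same fruit samples on two platforms:
relative volatile abundances (52 compounds) and two-channel microarray
expression (~4348 unigenes), across 2 genotypes × 5 conditions (maturity
stages S1–S4 plus a post-harvest shelf-life condition S4+SL) × 3 biological
replicates = 30 samples. Both platforms are reduced to a features × samples
matrix of log2(sample / common reference) values (`omics_matrix`). The
shelf-life condition is a distinct treatment, not a sixth numbered stage;
the sample design is always supplied as an explicit table and never parsed
out of sample-id strings. All analyses downstream of preprocessing operate
at replicate level (n = 30): correlations "across the different samples"
use every replicate, not stage means (a `group_mean` aggregation exists for
users who prefer condition-level profiles, but it is not the default).

## Two-channel preprocessing

1. **Spot filter.** A spot is kept iff its background-subtracted intensity
   strictly exceeds 2× the mean background in at least one channel. The
   mean background is computed per hybridization and per channel, matching
   per-slide scanning practice; a global mean would let one bright slide
   mask dim ones.
2. **MA-lowess.** M = log2 ratio of background-subtracted intensities,
   A = their mean log2 intensity; the lowess fit of M on A (span 0.3,
   3 robustness iterations — the common two-channel defaults, since only
   the method is prescribed) is subtracted per hybridization. Spots with a
   non-positive background-subtracted intensity are marked invalid rather
   than clipped: clipping fabricates ratios.
3. **Replicate validity.** A feature is retained for a (genotype, stage)
   condition iff it has valid ratios in at least 2 of the 3 replicate
   hybridizations; otherwise the whole condition is masked for that
   feature. Output stays at replicate level, so the "holes" this rule
   leaves are handled downstream by pairwise-complete correlation.
4. **Reference centering.** Each feature is shifted by the median log2
   value of the reference pool.

Two numerical caveats are worth stating plainly. First, subtracting a
lowess fit is only an identity up to the fit's own sampling noise, which
scales as sd(M)/√(span · n<sub>spots</sub>): the "no dye bias ⇒ no change"
property holds to ~0.01–0.02 log2 units at full array scale (thousands of
spots per hybridization) and is meaningless on toy inputs with dozens of
spots. The exact round-trip guarantee (reconstruction of the generating
matrix to 1e-10) therefore applies to the ratio path
(`normalize = "none"`); the lowess path is held to a 0.1 RMS bound on
biased data instead. Second, the two-channel *emulator* splits a lognormal
spot brightness T symmetrically across channels (Cy3 = T·2^(−v/2),
Cy5 = T·2^(+v/2)). Putting the whole ratio on the sample channel — the
superficially obvious construction — makes A = log2(ref) + M/2, so E[M|A]
≠ 0 even with zero dye bias, and lowess would systematically "normalize
away" real biology. The symmetric split keeps A independent of M while
preserving exact invertibility.

## Correlation and ranking

Pearson correlations are computed for every gene–volatile pair over
pairwise-complete samples, with the per-pair sample count recorded and
pairs below 3 shared samples masked. Zero-variance profiles are masked
with a warning, never reported as r = 0. No p-values are attached: the
method thresholds on correlation magnitude. Per-volatile top-k lists
(default k = 10) rank by signed r — "highest direct correlation" — with
|r| ranking behind a flag; ties break lexicographically on gene id so
output is reproducible across platforms.

## Joint hierarchical clustering

Distance is d = 1 − r; linkage is complete, so merge heights are
nondecreasing (asserted on every run) and every pair inside a subtree cut
at height h has correlation ≥ 1 − h. "Gene correlates with a volatile
cluster" is operationalized through that guarantee: cut the joint
gene+volatile tree at similarity 0.6 and report, per volatile-containing
cluster, the genes sharing the subtree — equivalently, genes whose
cophenetic similarity with the volatiles is at least the cut. Clustering
needs complete distances, so features with missing samples are mean-imputed
(logged; `drop` is available). The clustering engine is `stats::hclust`;
tie-breaking among exactly equal merge candidates follows hclust's internal
order rather than a lexicographic rule — ties have measure zero on
continuous correlation distances, and equivalence against an independent
naive agglomerative implementation is part of the acceptance suite.

## SAM-style differential expression

For the S4 vs S4+SL two-class contrast, the moderated statistic is
d<sub>i</sub> = (x̄₂ − x̄₁)/(s<sub>i</sub> + s₀) with s<sub>i</sub> the
pooled standard error. s₀ is selected on the percentile grid {0, 5, …,
100}% of the s<sub>i</sub> distribution by minimizing the coefficient of
variation of the median absolute deviation of d across windows of s. The
null distribution comes from label permutations — exhaustive when the
number of distinct assignments is small (all 20 for 3v3), sampled
otherwise. Candidate thresholds δ are the values |d(i) − d̄(i)| of the
sorted statistics against the permutation-averaged order statistics; the
call set only changes at those values and nearly all of the action is in
the tails, so the tails are kept exactly and only the body of the grid is
thinned. Cutoffs scan origin-outward within their own tails (the upper
cutoff from nonnegative order statistics, the lower from nonpositive
ones); the naive two-sided rule can "call down" a gene with positive d at
tiny δ, which breaks the monotonicity of q in |d|. The estimated FDR at a
threshold is the median permutation count beyond the cutoffs divided by
the observed call count (90th-percentile variant behind a flag; π₀ is
fixed at 1, conservatively); q<sub>i</sub> is the minimum estimated FDR
over thresholds at which gene i is called. A gene is *called* when it is
beyond the cutoffs at the smallest δ whose estimated FDR meets the target
*and* q < target — the two published criteria ("FDR of 5%" and
"q < 0.05") applied conjunctively.

A structural caveat at this design size: with 3 vs 3 there are only 20
label assignments. The observed top null gene exceeds the median of the 20
permutation maxima with probability about one half, in which case it earns
an estimated FDR of zero — a known instability of median-FDR SAM with few
permutations (the implementation warns below 10 distinct permutations).
Consequently the false-discovery behaviour is only meaningfully measured
in simulations that contain true effects: the acceptance suite uses a
block of ten 4σ responders among 500 genes for the FDR clause (the real
contrast this models had hundreds of shelf-life-responsive genes, so ten
is conservative) and a single 4σ gene in a 100-gene panel for the power
clause; the global-null simulation (2000 genes × 100 runs) checks that the
median number of q < 0.05 calls is zero.

Volatile differential abundance uses the classical equal-variance Student
t-test (Welch behind a flag) with raw p-values — no multiplicity
correction by default, matching the reporting convention it mirrors; a
Benjamini–Hochberg option exists. Fold changes are reported on the linear
scale, 2^|Δmean| with a direction, and the fold-change filter is strict
(exactly 2.0 is excluded). The Venn partition counts genes called in both
genotypes *with the same trend* as shared; genes called in both with
opposite directions are reported separately as discordant.

## PCA

Samples are scored by SVD of the feature-centered matrix; variance
fractions are squared singular values over total variance. No unit-variance
scaling by default — log2 ratios already share a scale (autoscaling behind
a flag). Each loading vector is flipped to nonnegative coordinate sum so
orientations are deterministic across platforms.

## Correlation networks

The VOC-only network connects every volatile pair with |r| at or above the
retention floor (0.5), with strength classes strong ≥ 0.95 and moderate
≥ 0.70 taken from the text they encode. Genes enter the merged network by
preselection: max over volatiles of |r| strictly above 0.85 (a secondary
pass at 0.80 is rerun, restricted to the volatiles left without any gene
edge by the primary pass — the "C4–C13" situation). Gene–VOC and gene–gene
edges share the preselection cutoff; that rule is the most parsimonious
reading of the merged-network construction and is configurable. Topology
metrics are degree, local clustering coefficient (0 for degree < 2, the
NetworkAnalyzer convention), and connected components; hubs are the top 5%
by degree. Gene sub-clusters are connected components of the gene–gene
subgraph at |r| ≥ 0.95 — deterministic and faithful to the visual
"strongly intercorrelated group" reading, unlike modularity optimization.
Exports are SIF and GraphML (Cytoscape-compatible).

## Candidate genes and exclusion

Per volatile cluster, the candidate table is the union of HCA evidence
(joint-tree co-clustering at 0.6), PC evidence (membership in a member
volatile's top-10 list) and CNA evidence (network adjacency to a member
volatile), each flagged so "Identified by" strings can be emitted
verbatim. The exclusion step is deliberately annotation-driven and
user-supplied: the published exclusions were expert judgment, so the
package encodes them as a tag set (default: ethylene biosynthesis,
ethylene signaling, cell wall softening; case-insensitive exact set
membership) and marks rows excluded with the matching reason rather than
deleting them, keeping the subjective step explicit and auditable.

## qPCR validation

ΔΔCt with technical replicates averaged on the Ct scale and amplification
efficiency fixed at 2 (efficiency-corrected quantification is out of
scope). The calibrator sample has RQ = 1 exactly, and RQ is invariant to
per-sample constant Ct shifts. Microarray concordance is the Pearson
correlation between the microarray log2 ratios and **log2(RQ)** — the
source rule does not state the scale, and correlating two log-scale
quantities is the defensible choice — validated iff strictly above 0.7.

## The synthetic world

The generator emulates the stated design: 30 samples; 52 volatiles
assigned to six trend archetypes (two increasing lactone/ester-like
families, a late-rising family, a stage-peaked family, a decreasing
lipid-derived family anti-correlated with the increasing ones, and a flat
family) with genotype-specific stage means and a larger shelf-life shift
in GenotypeB; genes planted at a controlled correlation to an archetype;
and background genes with smooth random stage profiles. One global seed
drives every draw, so datasets are bit-reproducible.

Planted genes are a·signal + N(0, σ) with
a = σ·r/(sd(signal)·√(1 − r²)), which makes the population correlation to
the archetype signal exactly the target r; infeasible targets (|r| = 1
with σ > 0, or any nonzero r against a flat archetype) raise an error
stating the attainable bound. With σ = 0 the gene is an exact (sign-flipped
if requested) copy of the signal.

Free parameters were fixed once, before the acceptance suite was written,
and not revisited: replicate noise 0.4 log2 (biological replicates of
field-grown fruit are noisy), volatile within-cluster scatter 0.25 log2,
background stage effects of sd 0.5 smoothed by a one-step moving average
and 70% shared between genotypes, shelf-life shifts of 0.3/1.5 log2 for
genotypes A/B applied to 15% of background genes, and 12 planted genes at
r = 0.95. One calibration deserves emphasis: a cumulative random-walk
background produces almost exclusively monotone profiles and therefore
co-correlates with the ripening archetypes an order of magnitude more
often than real transcriptomes do — the study design this emulates had
only ~2.5% of genes pass the |r| > 0.85 preselection *including* the true
biology. The moving-average background with 0.4 replicate noise was chosen
against that anchor (~1–1.5% of synthetic genes pass, mostly planted ones).
The generator does **not** emulate: chromatograms or spectra, volatile
quantification upstream of the abundance matrix, print-tip or PMT scanner
effects, spatial slide artifacts, or annotation structure beyond a small
tagged fraction used by the exclusion filter. A green recovery test
therefore establishes that the pipeline finds what the model plants under
realistic noise — not that it would find every true aroma gene in a real
experiment.

The two-channel emulator adds lognormal spot brightness, additive
per-channel background (mean 50 a.u.), a smooth monotone dye-bias curve
(amplitude 0.6 log2 across the intensity range) so lowess has real work to
do, and an optional forced sub-background spot fraction for testing the
spot filter.

## Determinism and the manifest

`run_all()` writes every analysis output deterministically: fixed row and
column orders, fixed number formatting, one seed for all randomness. The
manifest (`manifest.json`) records the config snapshot, seed, package
version, per-output MD5 checksums and stage wall-clock timings; because of
the timings, the determinism contract — identical seed ⇒ byte-identical
outputs — covers every file *except* the manifest itself.

## Known limitations

- SAM q-values at 3v3 rest on 20 permutations; estimated FDR is unstable
  and the top-gene q = 0 artifact described above is intrinsic at this
  design size.
- The 0.6 co-clustering rule inherits complete linkage's sensitivity to
  outlier profiles; imputation before joint clustering slightly shrinks
  correlations for features with masked samples.
- Network sub-clusters depend on a hard |r| threshold; groups straddling
  the 0.95 boundary split.
- Efficiency-corrected qPCR quantification and print-tip lowess are out of
  scope.
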
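---
title: "Methods: ligand-receptor crosstalk inference and IF proximity scoring"
author: "LRcrosstalk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor crosstalk inference and IF proximity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LRcrosstalk)
```

## The problem

Bulk tumor transcriptomes mix malignant, stromal and immune cells, so a
ligand-receptor (LR) database lookup alone says nothing about whether an
interaction is *active* in a cohort: both genes may be expressed by cells
that never meet, or the receptor may sit unengaged. This package implements
a two-evidence strategy for calling an LR pair "confident" from a gene-level
expression matrix of a modest cohort (tens of samples), plus the downstream
analyses that make the result interpretable for immunotherapy target
discovery: per-sample co-occurrence scores, association with immune
cell-type signatures, two-group immune-phenotype stratification, enrichment
statistics, and an image-based proximity score that validates predicted
checkpoint interactions on multiplexed immunofluorescence (IF) sections.

## Confident LR inference

For each candidate pair present in the matrix, the ligand-receptor Spearman
correlation is computed across samples (mean ranks for ties; two-sided
p-values). A pair passes the first stage when r > 0.5 and the
Benjamini-Hochberg adjusted p < 0.01, with BH applied once over *all*
evaluated pairs. Joint correction is the conservative reading when the
correction family is otherwise unspecified, and it makes the result
invariant to how the database is partitioned; per-source correction is
recovered by simply running the function per source table.

The second stage asks whether the receptor shows signs of downstream
activity. Every pathway topology containing the receptor contributes a set
of downstream target or otherwise-controlled genes; targets absent from the
matrix are excluded from the count (the criterion applies to what was
measured), and the receptor never counts as its own target. A pathway
supports the receptor iff at least 4 available targets have Spearman
r > 0.5 with it, or — when only 2 or 3 targets are available — all of them
do. Pathways with fewer than 2 available targets can never support. The
confident set is the union over the two topology kinds (Reactome pathways
and GO biological-process terms as ad-hoc pathways); a pair supported by
both kinds appears once with both kinds recorded. Where a receptor occurs
in several topologies with conflicting target sets, each entry is evaluated
independently and one sufficing entry makes the pair confident (union
semantics; the alternative — intersecting target sets per receptor — would
make support depend on how a database release splits pathways).

Two numerical decisions matter here. First, all printed thresholds
(r > 0.5, adjusted p < 0.01, r > 0.6 below) are strict inequalities, and
strictness is enforced with a 1e-9 guard so that a correlation whose exact
value *is* the threshold can never slip through floating-point noise in the
rank algebra. Second, p-values are exact for n ≤ 9 (full enumeration of the
n! rank permutations, which handles ties correctly by permuting the
observed mean ranks) and use the t approximation
t = r√((n−2)/(1−r²)) otherwise; at the benchmark cohort size of 24 the
t path is always taken, and the exact path exists so that small-n behavior
is verifiable against brute-force enumeration rather than asserted.

## LR-score and immune association

The per-sample co-occurrence score is the regularized geometric mean

$$\mathrm{LRscore}_s = \frac{\sqrt{l_s r_s}}{\mu + \sqrt{l_s r_s}}$$

with $l_s, r_s$ non-negative log-scale expressions and $\mu$ the matrix
mean. The geometric mean makes the score zero when either partner is
silent and symmetric in the partners; the regularization bounds it in
[0, 1), makes it monotone in each argument, and centers it so that
expression at the cohort-typical level ($\sqrt{lr} = \mu$) scores exactly
0.5. A plain geometric mean is available behind a switch for sensitivity
analysis. The regularizer $\mu$ is deliberately cohort-level, not
per-pair: scores are then comparable across pairs.

Cell-type abundance is summarized per population as the arithmetic mean of
log-scale marker expression, z-scored within the cohort. Cohort-internal
standardization replaces normalization against an external reference
cohort, which would require a download and fixes the score scale to
someone else's data; the cost is that scores are only comparable within
the analyzed cohort, which is all the downstream steps need. A pair is
immune-associated when its LR-score vector has Spearman r > 0.6 with at
least one immune population's signature scores. The any-population rule is
used because the biological question — "does this interaction track the
infiltrate?" — does not privilege one lineage; the emitted table still
records every (pair, population) combination that passed, so a stricter
per-population analysis needs no recomputation.

## Immune phenotype

Samples are clustered by Ward linkage (`ward.D2`, the variance-minimizing
form consistent with squared Euclidean distances) on Euclidean distances
between z-scored signature profiles, and the tree is cut at two groups —
the phenotype dichotomy of interest (infiltrated vs poor); the full
dendrogram is retained in the returned object for inspection. Labels are
oriented by the mean immune signature score, so `immune_infiltrated`
always names the hotter cluster. Non-immune populations (fibroblasts,
endothelium) can be scored but excluded from the distance via
`excludePopulations`, mirroring a display convention of showing stromal
scores without letting them shape the immune dendrogram. Heat-map display
values are winsorized at the 2.5% tails (type-7 empirical quantiles) so a
handful of extreme values cannot consume the color scale.

## Enrichment statistics

The differential-expression post-filters consume, never recompute, the
p/FDR/fold-change columns of an upstream edgeR/limma-style fit: genes need
p < 0.01, FDR < 0.01, fold-change ≥ 2 (expressed as max/min ≥ 1 with a
direction flag) and ≥ 20 normalized counts; proteins need p < 0.05,
fold-change ≥ 1.25 and mean log₁₀ signal ≥ 3. Printed "minimum" thresholds
are inclusive; printed "<" thresholds are strict.

Gene-set enrichment is the upper-tail hypergeometric probability
P(X ≥ k), summed in log space so overlap p-values far below 1e-20 — routine
in gene/protein overlap tests — remain accurate. Sets are intersected with
the universe first; only sets with ≥ 5 query genes are testable, and the
rule is applied *before* BH so that untestable sets never dilute or inflate
the correction family. The universe is a required argument with no default:
enrichment p-values are sensitive to it, and pretending otherwise by
defaulting to "all annotated genes" would bake an invisible choice into
every result.

One testing subtlety: a discrete tail p-value is super-uniform, not
uniform, so the calibration test asserts the exact discrete properties —
the continuity-randomized p-value $p - V\,P(X{=}k)$, $V \sim U(0,1)$, is
exactly uniform, and the raw p-value satisfies $P(p \le t) \le t$ — rather
than a literal KS uniformity check that discreteness alone would fail.

## IF proximity quantification

Channels are preprocessed Fiji-style: intensities below a lower threshold
become 0, the remainder are mapped linearly so the upper threshold reaches
255, clipped, and rounded to 8-bit. Both thresholds are required explicit
parameters because they are staining-specific and were set manually per
experiment in the motivating workflow; an automatic default would hide the
most consequential knob in the pipeline.

Receptor-positive cells are 8-connected components of the binarized
receptor channel. Area is the member-pixel count; the perimeter is measured
on the traced outer contour with Vossepoel-Smeulders chain-code weights
(0.948 per straight step, 1.340 per diagonal step), an asymptotically
unbiased estimator of smooth-boundary length — plain unit/√2 weights
overestimate digital-circle perimeters by ~5% and bias the circularity
4πA/P² of large disks to ≈ 0.90, violating the expectation that disk
circularity approaches 1 with radius (measured here: 1.06 at r = 6 falling
to 1.001 at r = 80). Circularity is capped at 1.1 before filtering because
digitization lets tiny blobs exceed 1. Particles must have area > 50 px²
and circularity > 0.3, both strict; centroids are member-pixel means in
0-based (row, col) coordinates with pixel centers at integers, and no
physical-unit conversion is applied.

The reference cell diameter D is the per-image *median* of retained
equivalent diameters (2√(area/π)); the median resists inflation by
accidentally merged cells, and the mean is available by configuration. Per
cell, the receptor is averaged over pixels within D/2 of the centroid and
the ligand over the crown D/2 < d ≤ c·D/2 with crown scale c = 2 — a
one-cell-radius-wide annulus, the zone where an extracellular ligand must
sit to engage a membrane receptor. Crowns partially off-image are averaged
over their in-image pixels and flagged; fully off-image crowns are errors.
The per-cell score is $\sqrt{F_R F_L}/255$, the normalized geometric mean
of the two fluorescence means, in [0, 1] for 8-bit inputs; a regularized
variant mirroring the transcriptome LR-score is available. A cell is called
positive when its score reaches the threshold (inclusive), and the summary
statistic is the percentage of receptor-positive cells called positive.
The default threshold of 0.3 was calibrated once on the synthetic benchmark
below, where positive cells score ≈ 0.6 and negative ones ≈ 0.05; with real
stainings it should be re-determined per experiment.

The IHC-derived summary metrics follow the printed grading verbatim:
stromal-reaction grade 0 for α-SMA density < 5%, 1 for 5–15%, 2 for
15–50%, 3 above 50% (left-closed bins, so a boundary density takes the
higher grade); and the M2/M macrophage ratio CD163/CD68, flagged high when
strictly above 0.5, undefined when CD68 is zero.

## Synthetic benchmarks

The cohort generator draws a latent Gaussian layer and maps every gene
through negative-binomial quantiles (`qnbinom(pnorm(z), mu, 1/dispersion)`),
a Gaussian copula: the map is monotone, so planted *rank* correlations
survive into count space, matching the Spearman machinery of the pipeline.
A target Spearman ρ is planted as latent Pearson 2·sin(πρ/6). Defaults are
the benchmark conditions used throughout the tests: 24 samples, 10 planted
pairs at ρ = 0.85 with 5 downstream targets each at 0.8, 50 null pairs
whose receptors get 5 *uncorrelated* targets and a topology entry (so the
evidence stage faces real nulls rather than pairs that fail by absence of
a topology), 200 unstructured background genes, NB means log-uniform on
[20, 500] with dispersion 0.4 (moderate bulk RNA-seq overdispersion), and
a latent infiltration factor splitting the cohort in half.

Immune structure: each of 3 populations has 10 marker genes (population
signatures of ~10+ genes match real marker panels); marker noise is one
part shared immune-activity fluctuation (0.25 sd) and the rest independent
per-marker noise, so the configured shift is in units of the total
within-group marker sd; the shift plus the shared fluctuation form the
factor that checkpoint pairs load on (default loading 0.8). Two numerical
details were forced by early validation failures and are worth recording.
Marker latents are standardized before the quantile map — an uncentered
shifted latent saturates `pnorm()` and compresses the shifted group into
the top count quantiles. And background genes are not mere decoration: with
too few of them the shifted markers dominate the library size and CPM
normalization divides the planted shift away (a compositional artifact that
real transcriptomes, where immune markers are a small library fraction,
do not suffer at this magnitude).

The image generator places non-overlapping disk cells (radius 9 ± 1.5 px,
clipped to [5, 14]) by rejection sampling with centroid separation of twice
the crown outer radius, so one cell's ligand halo can never contaminate a
neighbour's crown; positive cells get a ligand annulus covering the default
crown, negative cells none. Clutter — specks below the area filter and
3-px-wide streaks below the circularity filter — is placed clear of the
cells using the objects' true box footprints. Gaussian read noise (sd 8) is
added before 8-bit clipping, and intensities (receptor 180, ligand 160)
are chosen so the default preprocessing window (lower 20, upper 250) is
meaningful. Ground truth (per-cell centroids, radii, positivity; cohort
pair labels, infiltration flags, factor values) accompanies every draw, and
identical specs with identical seeds reproduce outputs bit-for-bit.

What the generators deliberately do not emulate: whole-transcriptome
covariance structure, batch effects, compositional shifts beyond the
library-size effect above, tissue morphology, uneven illumination, or
overlapping cells. Passing the recovery benchmarks therefore demonstrates
correctness of the algorithms under their stated statistical assumptions,
not robustness to every pathology of real data.

## Benchmark problem sizes

The test suite and the acceptance script run at sizes chosen to make the
Monte-Carlo assertions sharp while keeping a full run in minutes:
confident-pair recovery over 20 cohorts (and an independent brute-force
reimplementation must match pair-for-pair on the same draws),
immune-association recovery over 50–100 cohorts, phenotype clustering over
~30 cohorts, IF recovery over 50 images (10 per planted fraction in tests,
5 in the script) of 384×384 px with 20 cells each, exhaustive enumeration
oracles for the Spearman permutation p (n ≤ 7), the hypergeometric tail
(all tuples with N ≤ 25) and the evidence rule (all target combinations
with n ≤ 8).

## Known limitations

The headline counts of the motivating study (3,270 → 277 → 151/144 →
179 → 72) require its cohort, LR database snapshot and topology versions
and are not reproducible from synthetic data; the package reproduces the
*procedure* and verifies it by planted-truth recovery. The exact LR-score
and ifLR-score formulas of that study are supplementary-only; the forms
here are documented package choices with the same qualitative behavior,
and no numeric equivalence is claimed. Receptor complexes with multiple
subunits, directionality beyond ligand→receptor, probe-level data and
missing values are out of scope; expression matrices must be complete.
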
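---
title: "Methods: hypergraph gene clusters and growth-trajectory phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypergraph gene clusters and growth-trajectory phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypergrowth)
```

# Overview

`hypergrowth` implements a discovery-and-prediction chain for studies that
relate early growth trajectories (suboptimal fetal growth followed by
postnatal catch-up) to a prehypertensive cardiometabolic phenotype, via a
coordinated gene-expression cluster found by hypernetwork analysis. This
vignette records the statistical model behind each module, the design of
the synthetic cohort generator, and the numerical conventions the
implementation commits to.

# Growth trajectories

Birth size is classified from the birthweight percentile with **strict**
inequalities: SGA below the 10th, LGA above the 90th, AGA otherwise; the
boundary values 10 and 90 are AGA. Postnatal catch-up (CU-SGA) requires an
SGA birth and an age-7 height percentile strictly above 10; catch-down
(LGA-CD) mirrors it below the 90th. An SGA/LGA child with a missing height
percentile is labeled `unclassifiable`, never silently AGA.

Two trajectory statistics follow the stated formulas exactly:

* Δfetal wt `= (birthweight percentile − 23-week EFW percentile) / days`,
  in percentile points per day (`deltaFetalWt()`);
* Δchild wt `= (child weight SDS − birthweight SDS) / years`, in SDS per
  year (`deltaChildWt()`).

Estimated fetal weight uses the Hadlock log10 polynomials (the 4-parameter
head/abdomen/femur form and the 3-parameter form); percentiles against
gestational age come from a pluggable reference chart
(`efwReference()`; a clearly labeled synthetic chart ships in
`inst/extdata/`).

Quartiles of a trajectory statistic (`assignQuartiles()`) use minimum-rank
ties (`rank(ties.method = "min")`) cut at n/4 boundaries, so tied values
fall into the lower quartile and a constant vector is all Q1. Q1-vs-Q4
contrasts (`quartileContrast()`) then reuse the group-contrast machinery.

# Phenotyping

`callPrehypertension()` applies an NHLBI-style **any-criterion** rule:
SBP ≥ 120 mmHg (or ≥ 90th percentile for age/sex/height), HDL < 1.03
mmol/L, LDL ≥ 3.36 mmol/L, DBP ≥ 80 mmHg (or ≥ 90th percentile). A subject
is flagged if any available criterion fires; missing markers evaluate
false, and a subject with all markers missing is uncallable (`NA`). The
evaluation order (default SBP, HDL, LDL, DBP) determines only which
criterion is reported as the *primary driver*, never the flag itself.
Blood-pressure percentiles interpolate a pluggable age/sex/height
reference table and are clamped to its percentile range with a warning.
`groupPrevalence()` reports per-class prevalence, the relative-frequency
ratio of the focus class against the others, and a chi-square test without
continuity correction.

# Differential omics

Methylation beta-values are tested on the logit (M-value) scale and
expression counts on `log2(cpm + 1)` (cpm via `edgeR::cpm`, zero-total
samples are an error naming the sample). Testing uses limma's moderated
t-statistics with Benjamini-Hochberg control; methylation effects are
reported back on the beta scale as the group difference of mean betas
(delta-beta). Because the planted shift is applied on the logit scale,
subject-level noise attenuates the mean delta-beta slightly below the
nominal shift (Jensen's inequality) — the tests allow for this. A Welch
per-feature mode is provided for exact agreement with `t.test`.

DMRs are significant DMPs grouped by genomic proximity
(`GenomicRanges::reduce` with `min.gapwidth = maxGap + 1`), kept only when
a region holds at least 7 DMPs; an explicit region map can override the
gap rule. CpG–gene edges are Pearson correlations between M-values and
log2 cpm over shared samples, retained at a BH-adjusted threshold.

As a separation gate, `plsdaGate()` runs a hand-written NIPALS PLS-DA
against one-hot class labels; significance comes from label permutations
(p = (1 + #{permuted R² ≥ observed}) / (1 + n permutations)). The NIPALS
first component is verified against the dominant singular pair of X'Y.

# Hypernetwork

For each candidate gene, correlations to all non-candidate genes are
binarized: the default rule keeps entries with `|r| > mean(|r|) + 1 SD`
(computed over the full candidate-by-partner correlation block); an
absolute-threshold rule is available. The incidence matrix M (genes ×
partners) yields the shared-partner adjacency `A = M Mᵀ` with a zeroed
diagonal — entry (i, j) counts partners shared by genes i and j. Rows of A
are clustered with Ward.D2 on Euclidean distance; k is chosen from 2–6 by
average silhouette width. The **central cluster** is the cluster with the
largest median within-cluster adjacency; ties break toward the larger
cluster, then toward the lexicographically first member. A single node is
its own central cluster; an all-zero adjacency is flagged `noStructure`
with a warning.

# Prediction

`trainRFOOB()` wraps `randomForest` and evaluates strictly out-of-bag:
scores are the OOB vote fractions for the positive class, the confusion
matrix thresholds votes at 0.5, and the ROC/AUC come from the trapezoidal
rule over vote thresholds — algebraically the normalized Mann-Whitney U
with half-credit for ties. Relabeling the two classes leaves the AUC
invariant (votes follow the new positive class); the test suite checks
this rather than the naive `1 − AUC` flip.

`borutaSelect()` re-implements the Boruta loop: each iteration appends a
freshly permuted shadow copy of every feature, refits the forest, and
scores a *hit* when a feature's importance exceeds the best shadow
importance. After `nIterations` (≥ 10), a two-sided binomial test against
p = 0.5 at α/2 per tail confirms (upper tail) or rejects (lower tail)
features; the rest stay tentative. `predictExternal()` re-fits on the
genes present in a validation cohort, reporting the intersection ("k of m
trained genes present").

# Validation statistics

`contrastGroups()` picks Student's t when both groups pass Shapiro-Wilk at
0.05 and Mann-Whitney otherwise (a forced-test mode exists); groups
smaller than 2 are skipped with a warning. `kendallTau()` computes tau-b
with tie correction (p via the normal approximation, exact enumeration for
n ≤ 10); `partialKendallTau()` uses the closed form
τ~xy·z~ = (τ~xy~ − τ~xz~τ~yz~)/√((1−τ~xz~²)(1−τ~yz~²)). Note that this
rank-based partial does not vanish exactly under Gaussian full mediation;
it attenuates the association, and the tests assert attenuation rather
than a zero. `kmeansClusters()` is Lloyd's algorithm, best of `nInit`
seeded starts by within-cluster sum of squares, on per-gene z-scored
expression by default.

# The synthetic cohort generator

`simulateCohort()` draws, in order: birth strata (SGA/AGA/LGA at 10/80/10%
by default), within-stratum birthweight percentiles, catch-up status
(P(CU | SGA) = 0.85), an *unhealthy* subgroup among CU-SGA children
(fraction 0.25), growth and phenotype tables, and two omics matrices with
planted signal. Methylation is logit-normal (per-CpG baseline, subject
noise SD 0.35 on the logit scale, betas clipped to [0.01, 0.99]);
expression is negative-binomial (dispersion 0.1) with log-normal library
sizes (sdlog 0.3).

**What it emulates:** 450K-style beta matrices, RNA-seq count matrices
with realistic library variation, a CpG–gene coupling for planted DMP/DEG
pairs, a coordinated gene cluster sharing correlation partners (the
hypergraph target), and a phenotype layer in which the unhealthy subgroup
has elevated SBP. **What it does not emulate:** genomic covariance beyond
the planted structure (background features are independent), probe-level
artifacts, batch effects, cell-type composition, longitudinal visit
structure, or realistic minor-allele/ancestry structure.

## Parametrization by target correlations

The driving design choice: correlation strengths are specified as *target
correlations* (`cpgGeneCorr`, `clusterCorr`, `partnerCorr`) rather than raw
loadings, implemented as variance fractions of the latent Gaussian signal.
A fixed loading only yields a defined correlation after fixing the noise
scale, and the count-sampling noise is dictated by the dispersion; solving
for the variance fraction makes the realized correlation match the request
across expression levels. The gene-side noise fraction is never allowed
below 10% (the pair-factor fraction is capped at `0.90 −` the cluster
fraction): with less residual noise the latent variances explode and
contaminate library-size estimates.

Cluster and partner loadings carry alternating **signs** (± pattern). An
all-positive latent factor shifts whole libraries up and down together, so
cpm normalization absorbs most of it and the realized within-cluster
correlation falls well short of the target; a signed pattern is
library-neutral. Planted differential-expression directions follow the
loading signs so the group effect reinforces, rather than fights, the
cluster factor. Planted genes sit at modest baseline expression
(log2 cpm ~5–6.5, below the background mean of the log-normal baseline
distribution) so that planted fold changes move well under ~2% of library
mass — otherwise the fold change itself shifts library sizes and
normalization manufactures spurious background "DEGs" (composition bias).

## Calibration of effect sizes

The study conditions do not pin down effect sizes, so the generator's
defaults were calibrated once — by power arithmetic and pilot simulations,
before the test suite was frozen — so that planted-signal recovery is
non-trivial but reliable at the test scale (n = 600, 42-gene planted
cluster among 54 candidates): delta-beta 0.35, expression log2 fold change
2.2, CpG–gene target correlation 0.45, within-cluster 0.4, partner 0.25,
SBP shift 30 mmHg for the unhealthy subgroup. The binding constraint is
the group size: with ~10–20 unhealthy CU-SGA subjects out of 600, a
Jaccard ≥ 0.9 recovery criterion arithmetically requires near-certain
per-feature detection, and phenotype noise that mislabels even a few
subjects caps the achievable out-of-bag AUC. These defaults are package
design, fixed in code; the acceptance checks use them as-is. With all
effect sizes set to zero the same machinery yields chance-level AUC —
averaged over six replicate cohorts, since a single null AUC at ~10
positives has a standard deviation near 0.09.

# Numerical conventions

* Percentile classification: strict inequalities; boundaries are AGA.
* Quartiles: minimum-rank ties, lower-quartile assignment, constant → Q1.
* Binarization: default `mean(|r|) + 1 SD` rule on the candidate-partner
  block; constant features correlate as 0 with a warning.
* Silhouette k: 2–6, ties toward smaller k.
* Central-cluster ties: larger cluster, then lexicographically first node.
* AUC: trapezoidal over vote thresholds; ties get half credit.
* Boruta: two-sided binomial at α/2 per tail; minimum 10 iterations.
* Delta-beta effects reported on the beta scale; testing on M-values.
* Blood-pressure percentile interpolation clamps to table coverage with a
  warning; age outside coverage is an error.

# Problem sizes

The shipped tests and the acceptance script run at n = 600 subjects, 5,000
CpGs and 2,000 genes (about one minute end to end including the Boruta
loop and six null cohorts on one CPU). The generator and pipeline scale
linearly in features; the hypergraph step is quadratic in candidate genes
but candidates number in the dozens.

# Limitations

Reference charts for estimated fetal weight and blood pressure are
synthetic placeholders behind pluggable interfaces; substitute published
tables for real analyses. Background omics features are independent, so
null calibration here is the best case; correlated backgrounds will widen
empirical null distributions. The partial Kendall statistic is the
closed-form approximation, not a conditional tau.
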
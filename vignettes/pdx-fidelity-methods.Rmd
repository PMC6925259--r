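---
title: "Methods: fidelity statistics and response calling for paired PDX cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fidelity statistics and response calling for paired PDX cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxfidelity)
```

This vignette documents the statistical machinery in `pdxfidelity`: the
models and conventions behind each analysis, the tunable parameters and
their defaults, what the synthetic-cohort generator does and does not
emulate, and the numerical decisions taken where the underlying methods
left room.

## Methylation retention

A methylation array reports, per CpG probe, a β value in [0, 1] — the
methylated fraction of signal. `classify_state()` discretizes β into
*unmethylated* (β < 1/3), *hemimethylated* (1/3 ≤ β < 2/3), and
*methylated* (β ≥ 2/3). The strict published cutoffs (β < 1/3, 1/3 < β <
2/3, β > 2/3) leave the two boundary points unassigned; we close the bins
half-open — [0, 1/3), [1/3, 2/3), [2/3, 1] — so classification is a total
function. The effect is measure-zero for continuous β.

`retention_rate()` is the fraction of probes, shared and non-missing in
both samples of a pair, whose state is identical. It is symmetric,
probe-order invariant, lies in [0, 1], and equals 1 exactly when all
shared probes agree. Missing β values are removed pairwise, because
retention is defined per shared probe. Two useful calibration points: for
identical profiles the rate is 1; for two independent uniform β vectors
the analytic rate is 3 × (1/3)² = 1/3, which the implementation reproduces
to ± 0.01 at 10⁵ probes.

`pair_adjacency_count()` clusters all samples by average-linkage
hierarchical clustering on a 1 − Pearson correlation distance over the
top-k most-variable probes (default k = 20,000, ties broken by probe id),
and counts models whose two samples are immediate neighbours in the leaf
order. The distance and linkage are a package decision — standard practice
for methylation arrays — since discretionary choices of this kind are
rarely printed; they are recorded in the run log. Adjacency is evaluated
on the realized leaf order and is invariant to dendrogram reflections.

## Copy number from array total signal

Total (methylated + unmethylated) hybridization intensity tracks DNA copy
number once probe-composition effects are removed. `adjust_signal()`
performs a depth-limited regression-tree adjustment realized as a
piecewise-constant fit over GC-content deciles crossed with Infinium probe
type: the group mean is subtracted, leaving residuals with mean ~0. A
fixed decile × type grid is reproducible and parameter-light; with
constant covariates the adjustment degrades to mean-centering with a
warning.

`segment_cbs()` implements circular binary segmentation. For a segment of
n probes, every arc (i, j] with both arc and complement at least
`min_width` (default 2) probes is scored with the two-sample pooled-t
statistic of arc versus complement (the complement's two ends are joined,
hence "circular"); the maximizing arc is tested by permutation (default
`n_perm` = 1000, `alpha` = 0.01) and, if accepted, contributes up to two
breakpoints and recursion continues on the children. The scan is O(n²) per
segment and runs in compiled code; the permutation loop stops early as
soon as the exceedance count guarantees p > α. Degenerate arcs (zero
pooled variance with a non-zero mean difference) score +∞ so that
noiseless steps are always found; permutation replicates almost surely
score finite, giving p ≈ 0. Segmentation never crosses a chromosome
boundary and is deterministic given `seed`. On instances of ≤ 30 probes
the breakpoints match an exhaustive recursive max-t search; planted shifts
of ≥ 0.4 over ≥ 20 probes at noise sd 0.1 are recovered with ≤ 2-probe
boundary error in ≥ 90% of seeds; the false-split rate on pure noise at
α = 0.01 stays at or below 5%.

`recenter()` subtracts the probe-weighted median of segment means — the
weighted (not per-segment) median implements recentering at the probe-set
level, so a small aberrant fraction of the genome cannot drag the
baseline; the operation is idempotent. `call_states()` applies the ±0.2
rule with strict inequalities (a mean of exactly ±0.2 is neutral), and
`shared_cn_fraction()` compares per-probe states between paired profiles,
reporting the probe-weighted shared fraction and a differential map whose
loss/gain labels flip when arguments are swapped.

Because the permutation count, α, and minimum width are not universal
constants, all three are arguments with the defaults above.

## Clonal dynamics

`classify_dynamics()` takes per-variant MAF pairs. A variant is *detected*
on a side when MAF ≥ `detect_maf` (default 0.02, a typical deep-capture
noise floor) and is supported by ≥ 3 reads when depths are available.
Detection on exactly one side yields the corresponding private class;
detection on both sides is split by the MAF ratio with a strict 2× fold
boundary (ratio exactly 2 is *shared*); detection on neither side is
uninformative and returned as `NA` with a warning. The classes partition
informative variants, are invariant to common rescaling above the
detection floor, and map onto each other exactly under sample swap.

`cluster_clones()` groups variants in (MAF-primary, MAF-xenograft) space
with k-medoids (PAM), choosing k over 2..`k_max` by maximum average
silhouette and falling back to a single clone when the best silhouette is
below 0.5 (one diffuse cloud). PAM is deterministic, so clone calls
reproduce exactly. Clone cellular frequencies are 2 × the per-coordinate
median MAF, capped at 1 — the heterozygous-diploid convention under which
a fully clonal heterozygous variant sits at MAF 0.5. At depth 500 with
≥ 50 variants per clone, planted frequencies are recovered within 0.05 in
well over 90% of seeds. The package does not attempt phylogenetic ordering
or purity/copy-number-corrected cancer-cell fractions.

## Preclinical response

Volumes come from caliper diameters via V = (π/6)d³. The event for
event-free survival is the first crossing of RTV ≥ 4 (relative tumor
volume, V/V₀) or the absolute 2.5 cm³ cap, with the crossing day linearly
interpolated between bracketing measurements; curves that never cross are
censored at the 84-day evaluation period. The RTV ≥ 4 event and the
growth-delay interpretation of EFS T/C follow the established preclinical
testing-program conventions; both are arguments (`event_rtv`,
`evaluation_period`) rather than constants, since variants of the rule
exist.

Kaplan–Meier medians use `survival::survfit`; a median that is never
reached within the evaluation period is reported as ">EP", and the
corresponding EFS T/C as a "> x" lower bound with the evaluation period in
the numerator. The exact log-rank test enumerates all group relabelings
when the study has ≤ 16 mice (the 8 + 8 design gives 12,870) and otherwise
uses ≥ 10,000 seeded permutations; the statistic is the Mantel–Haenszel
chi-square, computed in-package and cross-checked against
`survival::survdiff` in the tests. Under the null the enumerated p-value
is conservative (type-I error at or below nominal), which the tests verify
by simulation. Tumor volume T/C is the ratio of arm means at the last day
on which every control mouse remains on study (the published tables do not
state their comparison day; this choice maximizes the evaluable n), with
an exact two-sided Wilcoxon rank-sum p.

Objective response calls apply, with precedence MCR > CR > PR > PD:
MCR — final volume < 0.10 cm³; CR — volume < 0.10 cm³ at ≥ 1 time point;
PR — ≥ 50% regression with measurable (≥ 0.10 cm³) tumor; otherwise
progression, split into PD1/PD2 by growth-delay value ≤ 1.5 / > 1.5. A
curve that neither regresses 50% nor shows the > 25% increase of textbook
progression is still assigned to the PD branch (stable disease is not a
category in this scheme); under exponential growth dynamics this case is
rare. The arm-level call is the lower median of per-mouse calls under the
ordering PD1 < PD2 < PR < CR < MCR, resolving even-split ties to the lower
class. Median final RTVs above 10 are printed as ">10" for comparability
with the published table dialect.

## Transcriptome similarity

Expression enters as FPKM; `transform_filter()` applies log2(FPKM + 0.01)
and removes genes with maximum transformed value < 1. Negative input is
rejected, which doubles as a double-transformation guard since transformed
matrices contain negative values. Pairwise similarity uses Spearman rank
correlation over all filtered genes (the filtered gene set, rather than a
variable subset, is the default because nothing suggests otherwise);
`spearman_pair_analysis()` flags pairs below the 25th percentile of pair
correlations. The quartile threshold is always recomputed from the data —
a published threshold of this kind is that cohort's realized quartile, not
a constant. PCA is gene-centered and unscaled (log-scale expression is
already comparable across genes); per-component variance shares sum to
100% over the full rank. Gene-set scores are mean per-gene z-scores across
samples, with zero-variance genes contributing 0, making the score
zero-mean across the cohort and invariant to non-member genes.
`paired_de()` runs per-gene paired two-tailed t-tests with
Benjamini–Hochberg adjustment; genes with zero-variance differences get
p = 1 and a degeneracy flag.

## Cohort annotations and 11p15 status

The packaged annotation table (`inst/extdata/wtpdx_annotations_synthetic.csv`)
is a reconstruction of a 45-model Wilms tumor PDX cohort: every model-level
fact available from the cohort description (anaplastic models, discordant
pairs and their reasons, specific 11p15 assignments, the model with
combined 1p+16q LOH) is preserved, and per-model assignments that were
only published in aggregate are synthetic fills chosen once so that the
aggregate counts match (38/45 concordant; 11p15 categories 17/2/18/3/5;
13 models with 1q gain). The file is labelled synthetic accordingly;
`concordance_stats()` recomputes all percentages from counts rather than
storing them. One published aggregate (an 87% 11p15 aberration rate) is
inconsistent with the published category counts (40/45 = 88.9%); the
package reports what the counts imply.

`classify_11p15()` applies a fixed-order cascade: copy ratio below the
loss threshold → hemizygous loss; above the gain threshold → paternal
gain; copy-neutral with all informative microsatellites homozygous → UPD
(copy-neutral LOH, following the convention that LOH requires a
homozygous pattern at all markers); copy-neutral with retained
heterozygosity and IC1 methylation above the biallelic threshold → LOI;
otherwise normal. Copy-neutral evidence with no informative marker returns
an explicit *indeterminate*. The thresholds (loss < 0.8, gain > 1.2,
IC1 biallelic > 0.75) are package defaults because the underlying
definitions are qualitative; all are arguments. The cascade order makes
the categories mutually exclusive by construction.

`str_match()` treats a locus as identical when allele sets are equal and
as *loss-tolerated* when the xenograft's alleles are a strict subset of
the primary's — allele dropout in a xenograft is biologically plausible,
the reverse direction (alleles appearing) is not, so the tolerance is
directional and loss-tolerated loci are counted separately in the report.

## The synthetic cohort generator

`cohort_spec()` fixes the ground truth of a simulated cohort; its defaults
are the package's reference study conditions: planted retention 0.85
(within the 0.72–0.92 range typical of paired methylation cohorts), 20,000
probes (the clustering probe budget), sequencing depth 500 (deep target
capture), a three-clone structure containing a stable clone, a 4×
expanding subclone and a vanishing clone, enrollment volumes uniform in
0.2–0.5 cm³, weekly measurements to day 84 with a 6-day baseline doubling
time and 8 mice per arm, and per-day kill rates spanning no effect to
strong combination effects. Tumor growth is exponential with a
multiplicative treatment kill term — the simplest model that produces all
five response classes — plus lognormal measurement noise (sd 0.05);
volumes below 0.005 cm³ are recorded as 0, mirroring the resolution floor
that produces the "0" RTV entries of real study tables. Retained
xenograft β values are re-drawn by a truncated normal inside the primary
probe's bin (sd 0.05), non-retained probes uniformly inside a different
bin, which keeps the planted retention rate exactly interpretable as the
expected measured rate.

What the generator deliberately does **not** emulate: raw IDATs or reads,
probe-level array artifacts beyond a smooth GC wave, murine stromal
contamination, purity/ploidy effects on MAFs and copy ratios, inter-model
heterogeneity of treatment response, and histology images. Passing
parameter-recovery tests on these simulations therefore demonstrates the
correctness of the estimators under their stated model, not robustness to
every artifact of real data; the real-data quantities (e.g. a cohort's
actual retention range) require the corresponding array and sequencing
archives.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
retention recovery uses 20 replicate single-model cohorts of 20,000
probes; CBS calibration uses 100-probe noise tracks over 100 seeds with
1,000 permutations; clone recovery uses 50 seeds of 100 variants at depth
500; log-rank calibration enumerates 1,000 replicate 4 + 4 studies; the
transcriptome check uses 37 pairs × 400 genes. Every stochastic component
takes an explicit seed, and fixed seeds reproduce results bit-identically;
the pipeline writes the seed and stage configuration to its run log.

The command-line entry point (`inst/cli/pdxfidelity.R`) is a thin wrapper
over `run_config()`/`run_all()`; the R functions are the primary
interface.
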
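---
title: "Methods: dual-control hit calling for region-targeted spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-control hit calling for region-targeted spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spothits)
```

# Overview

`spothits` analyses spot-based spatial transcriptomics from a three-arm
chemogenetic design: a perturbed group (`GqCNO`: excitatory DREADD receptor
plus agonist), a receptor-only control (`GqVeh`) and an agonist-only
specificity control (`CNOalone`). The pipeline runs selection →
normalization → dual-control differential expression → hit ranking → PCA /
activity / cross-species congruence. Every stage is exercised on synthetic
data with known ground truth; this vignette documents the models, the
tunable parameters, the numerical conventions, and what the synthetic
results do and do not establish about real data.

# The synthetic-data generator

## Count model

Counts are negative binomial, the standard overdispersed model for spot
data. Gene-level baseline means are drawn log-normally with median
`nb_mean` (default 5 counts/spot) and log-sd `nb_meanlog_sd` (default 0.4),
and a common size parameter `nb_dispersion` (default 20, i.e. mildly
overdispersed relative to Poisson). Spot-level dispersion of real Visium
data is not publicly characterized per gene; these defaults were fixed once
for testability — tight enough that planted two-fold effects are detectable
at the design's disc counts — and are not revisited. Real tissue is more
dispersed and spatially autocorrelated than this model; consequences are
discussed under *Limitations*.

## Geometry and regions

Each section is a staggered hexagonal lattice (default 40×40 spots) in
Visium array coordinates: `array_col` steps by 2 within a row and adjacent
rows are offset by one column, so the six neighbors of `(r, c)` are
`(r, c±2)` and `(r±1, c±1)`, all at equal planar distance. Regions are
disjoint rectangular blocks sized to match published per-section capture
area counts for this kind of targeted dissection: SN 6 discs (printed range
1–7), VTA 30 (2–49), thalamus 20 (0–39), CP 400 (357–560), LSX 40 (6–93),
white matter 48 (21–72). Region markers (`default_marker_panel()`) are
up-weighted by `marker_boost` (default 20×) in their home region.

## Contamination, probes, planted truth

A fraction `glial_spot_fraction` (default 0.05) of spots — placed uniformly,
therefore also *inside* DA regions, so the exclusion rule is genuinely
exercised — receive astrocyte/microglia markers at mean `glial_boost`
(default 40). Glial markers have zero baseline elsewhere: they are modelled
as cell-type-specific with no ambient background, which makes the
selection-versus-truth comparison exact rather than probabilistic. Negative
probes are drawn at mean `negative_probe_mean` (default 0.5) identically
across groups. Planted effects multiply the NB mean of a (gene, region,
group) triple by `2^log2fc`. The soma criterion of the real selection rule
is image-derived; the generator represents it as a boolean spot flag, true
for DA-region spots.

## Activity scores and the human panel

Per-spot activity scores (emulating a published deep-learning activity
predictor, which is an *input* to this pipeline, not reimplemented) are
Gaussian with mean 0.5 and SD 0.1, truncated to (0, 1]. `GqCNO` spots
within the DA regions *and their hexagonal outer ring* — exactly the
neighborhood the analysis scores — are shifted by `activity_effect`
(default 0.3·SD). The shift is neighborhood-local deliberately: a
section-wide shift would be removed exactly by the section-mean
normalization the analysis itself prescribes, i.e. it would fail to emulate
the phenomenon (locally elevated predicted activity) at all.

The human ortholog panel contains each planted gene with probability
`human_mapping_rate` (default 51/59, the mapping fraction typical of such
panels), with a direction that agrees with the planted mouse sign with
probability `human_sign_agreement` (default 0.8). No human counts are
simulated; the congruence statistic needs signs only.

Reproducibility: one design seed; per-section and per-table sub-stream
seeds are derived from it deterministically, so datasets are bit-identical
across runs and machines.

# Disc selection

A DA-region (SN/VTA) spot is selected iff

1. at least `min_markers_detected` (default 2) of the DA markers *Th*,
   *Slc6a3*, *Slc18a2* reach `marker_threshold` counts (default ≥ 1 — the
   weakest defensible reading of a "pre-set threshold", configurable);
2. no exclusion marker (*Gfap*, *Aldh1l1*, *Aif1*, *P2ry12*) strictly
   exceeds its per-section, per-gene `exclusion_quantile` (default 0.90).
   "High levels" of glial markers is not defined absolutely anywhere we
   know of; a per-section quantile is scale-free and robust to section-wide
   depth differences;
3. the spot's soma flag is true (when `require_soma_flag`).

Spots of other labelled regions are kept when any of that region's markers
is detected. Region labels are an *input* (anatomical assignment is done
upstream, by a human in practice); the rule filters within labels rather
than discovering regions. Selection is deterministic and invariant to gene
and spot order.

# Normalization suite and diagnostics

Five methods (`normalize_counts()`), samples in columns:

* **quantile** — each sample's sorted values are replaced by the
  across-sample mean of order statistics. Ties are assigned adjacent
  reference values in stable row order, which keeps the defining invariant
  — *every column has the identical sorted vector* — exact even on tied
  counts (averaging tied positions would break it).
* **q3** — scale so the 75th percentile of detected (nonzero) genes equals
  the geometric mean of per-sample 75th percentiles.
* **background** — divide each sample by its mean negative-probe count.
* **libsize** — scale each sample to the mean total.
* **median** — scale so the per-sample median over globally-detected genes
  equals the cross-sample median of those medians. Median normalization is
  under-specified in common usage; this definition (reference = median of
  medians) is the package's choice and is flagged here for users.

Degenerate inputs error early and name the offending sample (all-zero
sample for q3/median/libsize, zero negative-probe mean for background).

`normalization_diagnostic()` scores each method by (a) the mean absolute
per-sample Pearson correlation between M = log2((x+1)/ref) and
A = (log2(x+1) + log2 ref)/2, with the pseudo-reference ref the gene-wise
geometric mean of the +1-pseudocounted values (so identical samples give
M ≡ 0; correlations of numerically constant M are reported as 0 by
convention), and (b) the fraction of samples whose normalized distribution
differs from the pooled distribution by a two-sided KS test at p < 0.05.
The chosen method is the lexicographic minimum of (mean |r|, fraction
significant), tie-broken by mean KS statistic. GeoMx-style segment QC
(`qc_filter_segments()`) applies the conventional cutoffs (1000 reads, 80 %
trimmed/stitched, 75 % aligned, 50 % saturation, ≥ 1 negative count,
≤ 10 000 NTC, ≥ 20 nuclei, ≥ 1000 area), all inclusive at the printed value
— the simplest boundary reading and the platform convention — and reports
*every* violated rule per removed segment. The gene detection-rate filter
(default 1 %) is likewise inclusive. SCTransform-style variance
stabilization is outside this package's scope; the diagnostic accepts any
subset of the implemented methods.

# Differential expression and hit calling

Per gene and region, `compare_groups()` computes group means and sample
(n−1) standard deviations over the selected discs, a two-sided t-test, and
the ranking scores

* FCS = log2((μ_case+ε)/(μ_ctrl+ε)) · (−log10 max(P, p_floor))
* SNS = (μ_case−μ_ctrl)/(σ_case+σ_ctrl+ε_σ) · (−log10 max(P, p_floor))

Numerical conventions: Welch's test by default (a pooled-variance option
exists) since equal group variances cannot be assumed across treatment
arms; pseudocount ε = 0.5 on the normalized scale guards log2 of zero
means; ε_σ = 10⁻⁸ guards the SNS denominator; p_floor = 10⁻³⁰⁰ guards
−log10 underflow; a gene with zero variance in both groups and equal means
gets P = 1 and zero scores (no evidence), with unequal means P = 0
(infinite t). Both scores are zero at P = 1 and the SNS sign equals the
direction of change.

The replication unit defaults to the disc, pooled within group, matching
how per-region disc counts are reported as n in this kind of study; discs
within an animal are not independent, so this overstates the effective n
(pseudoreplication). A `unit = "animal"` option averages discs within
animal first (n = 3/3/2 here), which is statistically cleaner but very low
powered; the default keeps the disc convention and leaves the choice to the
user.

`call_hits()` intersects the two comparisons: a hit requires raw P < α
(default 0.05) against *both* controls. No multiple-testing correction is
applied to hit calling, matching the raw-p convention this design uses; a
Benjamini–Hochberg column is emitted for transparency only. Ranks are by
descending |FCS| and |SNS| from the case-versus-vehicle comparison with a
stable tie-break on the gene symbol.

A property worth knowing: the two comparisons share the case group, so
their test statistics are correlated (ρ ≈ 0.5 at equal n). Under the null
the dual-control rejection rate is therefore ≈ 0.008 at α = 0.05 — about
3× the α² = 0.0025 that independence would give, but still 6× below the
single-comparison rate. With 100 true effects among 2000 genes this puts
the empirical FDR among hits near 0.14 even at perfect recall; the second
control arm shrinks, but does not abolish, false hits, and users wanting a
guaranteed FDR should use the emitted BH column.

# Downstream analyses

**PCA** (`pca_embed()`): per-animal, per-region mean profiles of
median-normalized expression (per-disc embedding available); genes must be
expressed (> 0) in every included region; mean-centered, unscaled, top two
components with explained-variance fractions. Deterministic up to component
sign.

**Activity scores** (`normalize_activity()`, `compare_activity()`): scores
are divided by their section's mean (per-section mean of the output is
exactly 1; the operation is idempotent), then the case and pooled-control
distributions over the expanded DA neighborhood are compared with a
two-sided two-sample KS test using the asymptotic p-value — sample sizes in
this design are in the hundreds, where the exact computation is both
unavailable in the presence of ties and unnecessary.

**Congruence** (`congruence_test()`): mouse symbols map to the human panel
case-insensitively (*Th* ↔ *TH*; an explicit mapping table can override),
unmapped and zero-direction genes are dropped and reported via `n_mapped`,
and the 2×2 sign table (mouse up/down × human up/down) is tested for
independence with Pearson's chi-square, continuity correction off by
default. This is the simplest operationalization of "congruent directional
changes"; with fewer than 2 mapped genes or a zero margin the result is
flagged untestable rather than erroring, since small panels are expected.

# Pipeline, formats, determinism

`run_pipeline()` composes the stages from a declarative YAML config
(`pipeline_config()`, `write_default_config()`); each stage logs to stderr
with a stage-scoped prefix and halts with the stage name on error. Outputs:
per-region DE TSVs, ranked hit lists (one symbol per line, ready for
pathway webtools), QC and normalization reports, PCA coordinates,
activity and congruence JSONs, and a manifest with the config checksum and
per-file MD5s. Re-running an identical config reproduces every file
byte-identically. On-disk interchange uses the 10x triplet convention
(`matrix.mtx` in 1-based integer MatrixMarket coordinates, `barcodes.tsv`,
`features.tsv` with negative probes flagged by feature type) plus positions
and metadata CSVs; readers and writers are exact inverses on integer
counts, and malformed triplets are reported with file and line.

# Problem sizes used by the tests and acceptance script

The DE benchmarks use a single-DA-region design (20 discs/section, so the
smallest group — the two agonist-only animals — contributes exactly 40
discs) with 2000 genes; selection/activity/PCA checks use the full
midbrain layout (SN 6 / VTA 30 / thalamus 20 discs per 40×40 section, 8
animals) with 12–200 genes, since those properties do not depend on gene
count; power estimates use 200 seeded replicates. These sizes are the
package's chosen study conditions, stated here so results are
interpretable, and they complete in tens of seconds on one core.

# What the synthetic results do and do not show

Passing tests establish that the implementation computes what it claims:
exact score formulas, exact selection logic against a generator whose truth
is unambiguous, calibrated null behavior of the testing chain, and the
qualitative phenomena the design targets (dual-control shrinkage,
recovery of two-fold planted effects at the design's disc counts, PCA
separation under strong coordinated effects, congruence power at 80 % sign
agreement). They do *not* show that real Visium sections meet the
generator's assumptions: real data have gene-specific dispersion, spatial
autocorrelation beyond region blocks, ambient glial background (so the
quantile exclusion rule will reject a tail of clean spots), imperfect
anatomical labels, and section-level batch effects, none of which are
modelled. Two quantitative notes from our own acceptance runs: the
dual-control FDR floor described above (≈ 0.14 under 100/2000 planted
effects) is intrinsic to intersecting raw-p tests that share a case group;
and the KS comparison of activity scores at a 0.3·SD local shift with
~200/~350 spots has true power ≈ 0.78 — adequate, but borderline for a 0.8
target, so small activity effects should not be considered reliably
detectable at this design size.

# Known limitations

* Anatomical labels, soma flags and activity scores are inputs; the package
  neither segments images nor predicts activity.
* Hit calling uses raw p-values by design convention; use `p_adj` for
  FDR-controlled lists.
* Disc-level replication overstates effective n; the per-animal option is
  provided but low-powered at n = 3/3/2.
* The congruence test treats genes as independent draws; co-regulated gene
  sets will inflate its apparent power.
* Batch/slide correction (e.g. mixed models or empirical-Bayes approaches)
  is out of scope; the normalization diagnostic helps choose a scale, not
  remove batch structure.
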
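---
title: "Local coupling of dendritic spine volume and PSD size: methods and design"
author: "spinecorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local coupling of dendritic spine volume and PSD size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecorr)
```

## Overview

`spinecorr` analyses the coupling between dendritic spine volume *V*
(μm³) and the size of the postsynaptic density — its surface area *A*
(μm²) and the volume of its electron-dense core *V*ₚ (μm³) — in
serial-section EM reconstructions of control and chemically potentiated
(cLTP) tissue.  Three stages feed each other: contour-based morphometry
produces per-spine measurements; an unbiased-brick census produces
per-sample densities; and a sliding-window rank-correlation procedure
maps where, along the spine-volume axis, the *V*–PSD coupling holds and
where it fails.

This vignette documents the model and every design decision that was
genuinely open, so a reader can judge what the implementation does
without reading the code.

## Morphometry

**Volumes** are Cavalieri estimates: on each section the areas of all
closed traces carrying the object's label are summed and multiplied by
the section thickness *t*; sections are not interpolated.  This matches
the behaviour of the standard serial-section reconstruction tools, which
report contour area × thickness sums.  Polygon areas come from the
shoelace formula after a self-intersection check; areas are invariant
under vertex orientation and starting point, volumes scale as *k*³ under
a joint rescaling of coordinates and thickness, and splitting a contour
into adjacent parts leaves the volume unchanged (all property-tested).

**PSD area** follows the dual annotation rule: where the PSD-core runs
perpendicular to the cutting plane it is annotated as an open polyline
and contributes length × *t*; where it lies parallel to the plane it is
outlined as a closed trace and contributes its planar area.  Both kinds
may coexist in one stack and are summed.

**Section thickness** is estimated by the cylindrical-diameters method.
The literature for this method does not fix a formula, so the package
adopts the simplest consistent estimator: for an approximately
cylindrical organelle of in-plane diameter *d* crossing *s* consecutive
sections, *t* ≈ *d*/*s*, averaged arithmetically over observations, with
per-observation values returned for quality control.  The forward
simulation used to test it assumes that a section showing less than half
a section's worth of the organelle is not recognised as part of the
span; under that visibility convention *d*/*s* is essentially unbiased
(the all-overlap convention would inflate *s* by about one section and
bias the estimate low by *t*/(*d*+*t*)).

**Multisynaptic spines** carry one record per synapse; merging sums PSD
area and PSD-core volume, OR-combines the annotation flags, and requires
the per-synapse spine volumes to agree — a volume conflict indicates an
upstream bookkeeping error and is rejected rather than averaged.

The spine–dendrite cut-off (terminating the spine at the reconstructed
dendritic surface) is assumed already applied in the input traces; the
package does not re-cut.

## Unbiased brick census

Each spine is reduced to one reference point (in practice the PSD
centroid).  A counting brick of dimensions *w* × *h* × *d* at origin
**o** counts the points with **o** ≤ **p** < **o** + (*w*,*h*,*d*)
component-wise: the three minimum faces are inclusion planes, the three
opposite faces exclusion planes.  For point references this half-open
rule is exactly the unbiased-brick rule — a tiling of abutting bricks
counts every point once (tested), and the extended exclusion planes of
the full rule are unnecessary.  Densities are per brick volume, averaged
within a sample; the sample (slice), not the spine, is the statistical
unit for density comparisons, giving the *t*(6) comparison at 4 slices
per condition.  The default brick is 10 × 10 × 1.5 μm = 150 μm³.

## The local Spearman procedure

The data are first sorted by spine volume and reduced to ranks (average
ranks on ties; ties in volume keep stable input order for window
construction).  For each spine *i*:

1. for every window size *w* ∈ {14, …, 24}, a window of *w* consecutive
   spines is centred on *i*'s volume rank;
2. each window is resampled `n_boot` = 2500 times *without replacement*
   to subsets of *w* − 4 pairs (i.e. 10–20 pairs);
3. Spearman's ρ and its two-sided p (t approximation on the subset size)
   are computed for every subset;
4. ρ and p are averaged over all subsets of all window sizes — the
   spine's local coefficient and local p.

A spine is locally significant when its mean p < 0.05 (strict
inequality).  Maximal contiguous runs of non-significant spines, in
volume order, are the *decoupling bands*; the package reports their
volume ranges, the decoupled count, and its fraction of the population.
Between-condition differences in decoupled counts are tested with
Pearson's χ² (no continuity correction) on the 2 × 2 table.

Design decisions where the procedure is underdetermined:

* **Edge handling.**  A centred window does not fit within the first or
  last ⌊*w*/2⌋ spines, so the window is shifted inward (truncated
  centring).  Every spine therefore receives all 11 window sizes, at the
  cost of edge windows being less symmetric around their centre.
* **Averaging.**  The local p is the arithmetic mean of subset p-values
  (not a Fisher combination), and ρ and p are averaged jointly across
  windows and resamples.  Both the mean ρ and the mean p are computed
  and exported, since either may be plotted.
* **Degenerate resamples.**  A subset with constant values has no
  defined rank correlation.  By default it contributes ρ = 0, p = 1 and
  is counted (`n_degenerate`); a `"skip"` policy that drops such
  resamples from the averages is available.  With continuous input data
  degenerate subsets essentially never occur.
* **p-value approximation.**  Subset sizes are 10–20 by default, where
  the t approximation to Spearman's null is adequate; perfectly monotone
  subsets are clamped so p stays positive.
* **Conservativeness under the null.**  Averaging thousands of
  correlated p-values concentrates the local p towards 0.5, so under a
  global permutation of the PSD values the fraction of spines flagged
  significant is well *below* the nominal α — the procedure is
  conservative, not anti-conservative.  The test suite asserts the
  false-positive bound (fraction ≤ α + Monte-Carlo margin over 20
  permutation replicates) rather than a two-sided match to α, which
  p-averaging cannot attain.

The bootstrap kernel is implemented in C++ (Rcpp) because a default
profile evaluates about 27,500 resamples per spine; a 250-spine profile
takes tens of seconds on one CPU.  All resampling uses R's RNG stream,
so a seed fixed in `local_corr_params()` reproduces profiles exactly.

## Group statistics

Morphometric variables (volumes, areas, ratios) are not normally
distributed, so between-condition comparisons use Mann–Whitney tests:
exact p for min(*n*) ≤ 8 without ties, otherwise the tie-corrected
normal approximation without continuity correction.  Both *U* and
*U*′ = *n*₁*n*₂ − *U* are reported because either convention appears in
published legends.  Densities (per-sample, approximately normal) use the
pooled-variance t-test.

Allometric comparisons fit ordinary least squares on log₁₀–log₁₀ axes
and compare groups with ANCOVA: the slope test has df (1, *n*₁+*n*₂−4),
the elevation test (1, *n*₁+*n*₂−3) and is only interpretable when the
slopes are homogeneous (flagged).  Log transformation is the default
because raw-scale slope comparisons of power-law data are dominated by
the largest spines; a raw-scale flag is retained.

Four-group comparisons (condition × SER) use the tie-corrected
Kruskal–Wallis H with Dunn's post-hoc z on pooled ranks,
Bonferroni-adjusted over the compared pairs (no correction is claimed by
the original analyses; Bonferroni is the conservative default of common
plotting software).  Normality, where needed for display conventions, is
assessed by Shapiro–Wilk at α = 0.05; summaries always report both
mean ± SEM and median ± IQR.

**Relative change** has no per-spine baseline (control and potentiated
populations are different spines), so each potentiated spine's value is
divided by the *median of the control spines in the same SER stratum*;
the strata are then compared with a Mann–Whitney test.  This
cross-sectional definition is the only one available for independent
populations and is flagged here prominently.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes —
it is the test bed for every downstream stage, not a simulation of EM
images.  Per spine:

* log₁₀ *V* ~ Normal(−1.1, 0.45): volumes centred near 0.08 μm³
  spanning roughly 0.01–1 μm³, the observed log-normal shape of spine
  volumes;
* log₁₀ *A* = 0.9·log₁₀ *V* − 0.3 + ε, with sd(ε) = 0.02 outside the
  decoupling band and 0.30 inside it ([0.04, 0.1] μm³ for control
  spines; [0.048, 0.073] μm³ for potentiated spines, encoding the
  re-coupling of PSD size to spine volume under potentiation);
* log₁₀ *V*ₚ = log₁₀ *A* + log₁₀(0.03) + η, sd(η) = 0.02: the PSD-core
  volume derives from the area at an effective core thickness of 30 nm,
  keeping area and core volume tightly coupled at all volumes — the
  internal control of the method (their mutual profile must stay
  significant everywhere, and does);
* P(SER) = logistic(3.5 + 3·log₁₀ *V*): SER-containing spines are
  preferentially large; spine apparatus occurs in 40% of SER spines;
  perforation probability is 0.25 with SER and 0.01 without, so
  perforated PSDs essentially require SER (about one exception per
  condition at the default sizes);
* cLTP multiplies *A* (and hence *V*ₚ) by 1.8 in every spine, and *V* by
  1.7 only in SER-containing spines.

Sample sizes default to 119 control and 138 potentiated spines from 4
samples per condition.  The cLTP factors were fixed by forward
simulation at those sample sizes so that the group comparisons produce
rank statistics of the magnitude observed in real datasets of this kind,
and the volume distribution places roughly a third of control spines
inside the decoupling band.  Brick scenes for the density census are
homogeneous Poisson with a default intensity of 1.2 μm⁻³, identical in
both conditions (density is not affected by this form of potentiation).

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: decoupling is injected as residual
variance inflation inside a sharp volume band, whereas real decoupling
presumably has soft edges and a mechanistic origin; out-of-band coupling
is much tighter (residual sd 0.02 in log₁₀) than real biological
scatter, which makes the significant/non-significant transition crisper
than in real profiles; there is no dendrite geometry, no neck/head
decomposition, no temporal dynamics of potentiation, and no
per-sample heterogeneity beyond the Poisson census.  Results on
synthetic data validate the *machinery* (estimators, window logic,
statistics), not biological effect sizes.

## Numerical choices and degenerate inputs

* Volume ties in window construction break by stable input order.
* Perfectly monotone subsets: ρ = ±1 exactly, p clamped positive.
* Constant samples: SEM and IQR are 0; Shapiro–Wilk is skipped (NA);
  the pooled-variance t-test returns t = 0, p = 1 when both groups are
  constant and equal, and rejects when constant and unequal.
* A χ² comparison with a zero marginal (e.g. no decoupled spines in
  either group) is rejected with a diagnostic; the pipeline records the
  note and continues.
* Contour generation rescales spheroid cross-sections so that Cavalieri
  summation recovers the target volume to well under 1% (polygon
  discretisation aside); a spine thinner than one section becomes a
  single contour of area *V*/*t*.
* Problem sizes in the test suite were chosen to make sampling error
  negligible relative to the asserted tolerances: marginal recovery at
  n = 2000, band recovery at 250 spines per condition with the full
  2500-resample procedure, null calibration with 20 permutation
  replicates and 1000-replicate type-I simulations.

## Known limitations

* The cylindrical-diameters estimator assumes annotators report spans
  under the half-section visibility convention; systematically counting
  cap slivers as sections would bias thickness low by about one section
  in *s*.
* The decoupling-band detector reports *maximal runs* of non-significant
  spines; a single significant spine inside a true band splits it in
  two.  Users comparing band edges should look at the largest band
  overlapping the range of interest.
* p-averaging is conservative under the null (see above); absolute
  decoupled fractions are therefore not comparable across procedures
  that combine evidence differently, only between conditions analysed
  identically.
* The elevation ANCOVA is reported but flagged non-interpretable when
  slopes differ; it is not suppressed, because figure legends
  conventionally print both.
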
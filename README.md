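# spinecorr

Quantitative analysis of dendritic-spine / postsynaptic-density (PSD)
coupling from serial-section electron-microscopy reconstructions.

## The scientific problem

In 3D EM reconstructions of hippocampal tissue, spine volume *V* (μm³),
PSD surface area *A* (μm²) and PSD-core volume *V*ₚ (μm³) are strongly
correlated across the population — PSD size scales with spine size
approximately as a power law, log₁₀ *A* = a·log₁₀ *V* + b.  The global
correlation can, however, hide *local* failures of that coupling: in a
restricted range of spine volumes, spine size may be a poor predictor of
PSD size.  `spinecorr` implements the sliding-window statistic that
detects such ranges, together with the morphometry and group statistics
needed to run the full analysis on control versus chemically potentiated
(cLTP) spine populations:

* **Contour morphometry** — Cavalieri volumes from closed serial-section
  traces (Σ area × thickness), PSD areas from open polylines
  (length × thickness, PSD perpendicular to the section) and closed
  outlines (PSD parallel to the section), cylindrical-diameters section
  thickness estimation, and per-spine merging of multisynaptic PSDs.
* **Unbiased brick census** — half-open counting bricks
  (10 × 10 × 1.5 μm by default) giving per-sample spine densities per
  tissue volume.
* **Local Spearman profiling** — the core method.  For every spine,
  windows of 14–24 spines (by volume rank) are centred on it; each
  window is resampled 2500 times without replacement to subsets 4 pairs
  smaller than the window (10–20 pairs); Spearman's ρ and its p-value
  are computed per subset and averaged over all subsets and window
  sizes.  Volume ranges where the mean p ≥ 0.05 are the *decoupling
  bands*; the counts of spines in such ranges are compared between
  conditions with a χ² test.
* **Group statistics** — Mann–Whitney tests, pooled-variance t-tests,
  log-log OLS fits with ANCOVA slope/elevation comparison,
  Kruskal–Wallis with Dunn post-hoc, A/V and Vₚ/V ratio metrics,
  SER-stratified relative changes, and 0.05 μm³ volume histograms.
* **Synthetic data** — a generative model (log-normal volumes, power-law
  coupling with a configurable mid-volume decoupling band, SER
  probability rising with volume, cLTP growth factors) that emulates the
  statistical structure of the real datasets, so the entire pipeline is
  testable without image data.

## Worked example

```r
library(spinecorr)

pop <- generate_population(synth_config(seed = 42))
table(pop$condition)
#>    cltp control
#>     138     119

ctl  <- subset(pop, condition == "control")
prof <- local_profile(ctl, parameter = "psd_area",
                      params = local_corr_params(seed = 43))
bands <- nonsignificant_regions(prof)
bands$bands
#>         v_lo      v_hi n_spines
#> 1 0.04092628 0.1124946       45
#> 2 0.15629387 0.1562939        1
round(bands$fraction, 3)
#> [1] 0.387
```

About 39% of the control spines sit in a contiguous volume range
(≈ 0.04–0.11 μm³) where spine volume fails to predict PSD area — the
decoupling band injected by the generator at 0.04–0.1 μm³, recovered to
within a window span.  Comparing conditions:

```r
prof_cltp <- local_profile(subset(pop, condition == "cltp"),
                           parameter = "psd_area",
                           params = local_corr_params(seed = 44))
cmp <- compare_decoupled_counts(prof, prof_cltp, c("control", "cltp"))
cmp$table
#>          correlation
#> group     significant not_significant
#>   control          73              46
#>   cltp            107              31
c(chi_sq = round(cmp$statistic, 2), p = signif(cmp$p_value, 3))
#>  chi_sq       p
#> 7.98000 0.00472
```

The potentiated population has significantly fewer decoupled spines —
potentiation tightens the size coupling.  The global allometry is
summarised by the log-log fit:

```r
loglog_fit(ctl$volume_um3, ctl$psd_area_um2)
#> log-log fit (n = 119): log10(y) = 0.8809 * log10(x) + -0.3355, RSS = 5.924
```

`run_pipeline(pipeline_config(seed = 1))` runs everything — densities,
profiles for the three parameter pairs, ANCOVA, SER-stratified
statistics, perforation cross-tabs — and returns (optionally writes) the
full report bundle.  A thin command-line wrapper ships at
`inst/scripts/spinecorr-cli.R`.

## Vignette

`vignettes/spine-psd-coupling.Rmd` documents the statistical model, the
design decisions behind the estimator (window placement at the profile
edges, p-value averaging, degenerate-resample policy), what the
synthetic generator does and does not emulate, and the package's known
limitations.
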
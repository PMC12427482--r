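---
title: "Methods: quantifying the osteosarcoma tumor microenvironment from imaging mass cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the osteosarcoma tumor microenvironment from imaging mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osimc)
```

## The problem

Imaging mass cytometry (IMC) reads dozens of metal-tagged antibodies off a
tissue section at single-cell resolution, so a tissue microarray (TMA) of
~1 mm tumor cores yields, per core, a table of segmented cells with centroid
coordinates and binary marker-positivity calls. `osimc` turns such tables
into the quantities that matter for studying immunosuppression in the
osteosarcoma tumor microenvironment: which immune and stromal populations
are present and how abundant they are, how closely the immunosuppressive
populations (M2 macrophages, MDSC, Treg — collectively IMSC) cluster around
M2 macrophages, and whether abundance or proximity stratifies
metastasis-free (MFS) and recurrence-free (RFS) survival. A companion
module screens multiplex-bead cytokine panels from macrophage/tumor
co-cultures for differentially abundant analytes.

Because TMA datasets of this kind are rarely public, the package ships a
synthetic-cohort generator with the same statistical structure, so every
stage is exercised end to end by code alone.

## Quality control

Two filters mirror standard IMC practice:

* **Core filter.** Per core, the fraction of cells positive for the
  iridium DNA intercalator (Ir191, the nuclear stain) is computed relative
  to all nuclear-segmented cells. Cores with a fraction strictly below 25%
  are excluded — 25% is an inflection point for poor staining quality, and a
  core at exactly 25% is retained. After the filter, "detectable cells"
  means the Ir191-positive cells of retained cores; every downstream
  percentage uses that denominator.
* **Marker filter.** A case is positive for a marker when at least 3 of its
  cells stain positive; markers positive in fewer than 10% of cases are
  excluded. Both boundaries are inclusive on the keep side because the
  exclusions are phrased with strict `<`.

Both filters are idempotent, and raising the core threshold can only shrink
the retained set; the test suite asserts both properties.

## Phenotyping

Phenotypes are declarative gating rules: required-positive markers,
required-negative markers, and a priority. A cell gets the label of the
first rule (in priority order) it satisfies; unlisted markers are "don't
care"; cells matching no rule are `Unassigned`. The default rule set covers
23 populations (M0/M1/M2 macrophages, monocytic and polymorphonuclear MDSC,
classical/non-classical monocytes, neutrophils, DC, three NK subsets, five
T-cell subsets including Treg and memory subsets, endothelium, fibroblasts,
epithelial-like cells, CD44+ stem-like and Ki-67+ proliferating cells).

Priority resolves the overlaps marker algebra leaves open: a
CD68+CD163+HLA-DR+ cell satisfies both the M1 and M2 marker sets, so
more-constrained rules rank first, memory T subsets rank above their parent
helper/cytotoxic subsets, Treg above helper T, and macrophage subtypes
above generic myeloid rules. Two deliberate choices go beyond the bare
marker sets:

* M1 carries an explicit CD163− constraint so M1/M2 are disjoint regardless
  of priority. The rule set is user-editable (via `ruleset()` or the
  pipeline config), so a site-specific marker table can replace the
  defaults.
* MDSC rules do not require CD68−; priority order (macrophages first)
  performs that exclusion.

The engine is vectorized but is required, by test, to agree exactly with a
naive per-cell priority scan, and to invert the synthetic generator's truth
labels at zero marker noise.

## Abundance and the IMSC composite

Abundance is the percentage of a core's detectable cells carrying each
label; rows of the abundance matrix sum to 100 by construction. The IMSC
composite is the mean of the M2, pooled MDSC (mMDSC + pMDSC) and Treg
percentages; a `sum` mode is provided as well. Since the sum is exactly
three times the mean, a median dichotomization is identical under either
mode — the choice cannot affect survival stratification, and the tests
verify that invariance rather than privileging one reading. Arbitrary
component sets (e.g. M2+MDSC only) are available through
`pairwise_composite()`.

## Spatial statistics

All spatial statistics are M2-centric and restricted to a 250 µm radius —
the reported maximum distance for meaningful hematopoietic cell–cell
communication. Distances are Euclidean between centroids, in µm.

* **Median pair distance.** All (center, target) pairs within the radius are
  pooled per core and the median taken; for M2–M2, unordered pairs count
  once and self-pairs are excluded. The M2–IMSC proximity composite is the
  arithmetic mean of the M2–M2, M2–MDSC and M2–Treg medians.
* **Density.** Per M2 cell, the count of target cells within the radius
  (excluding the center itself); the core's density is the *median count*
  divided by the neighborhood area in mm². The two aggregations differ on
  purpose — pooled pairs for distances, per-center medians for counts —
  matching the two distinct definitions being emulated.
* **Summed IMSC count.** The sum over M2, MDSC and Treg of the median
  per-M2 counts.

Numerical choices:

* Neighbor search uses a grid-bucket index with bucket side equal to the
  radius (only the 3×3 surrounding buckets are scanned). It is exact, and a
  dedicated test requires bit-level agreement with an all-pairs O(n²) scan
  on random cores.
* Cores with no qualifying pairs get a configurable `missing_policy`:
  `missing` (default — the core drops out of the downstream median split),
  `zero`, or `radius_cap`. The default is the statistically safer choice;
  `zero` exists because published group medians of 0 µm can arise from
  empty-neighborhood coding, and the pipeline report always records the
  policy used.
* The density denominator is the full disc πr² by default. Because 250 µm
  is half the core radius, neighborhoods of peripheral cells leave the
  core; `clip_area = TRUE` divides by the mean intersection area of the
  query disc with the core disc instead (a closed-form lens area). A test
  confirms the clipped estimator is unbiased for a homogeneous field of
  known intensity.

## Survival analysis

Cases metastatic at diagnosis are excluded; metrics are median-dichotomized
among the remaining localized cases (the cutoff is computed on the analysis
set, not the full cohort). Values at or below the median form the
low/near group — ties go low, so group sizes differ by at most the tie
count. Each (metric, endpoint) pair gets a Kaplan–Meier fit, a two-sided
log-rank test, and a univariable Cox proportional-hazards hazard ratio of
high/far versus low/near with a Wald 95% CI (the `survival` package does
the estimation). P-values are reported unadjusted because the screen is
exploratory; `adjust = TRUE` appends a clearly-labeled Benjamini–Hochberg
column as an extension.

Any strictly monotone transform of a metric leaves the groups, the log-rank
p and the HR unchanged — a property test, and the reason the mean/sum
composite choice is immaterial.

## Cytokine screen

Raw bead MFIs are background-subtracted per analyte (mean of the background
wells) and floored at 0, since MFI is a non-negative physical quantity.
Per analyte, a two-way ANOVA of MFI on culture condition × cell line is
followed by Tukey-adjusted contrasts of co-culture versus each mono-culture
control within each cell line. A cell line counts as significant only when
the co-culture differs from **both** controls (tumor-alone and
macrophage-alone) — the conservative reading; `contrast = "either"` is
available. An analyte is selected when ≥ 2 of 3 cell lines are significant.
Analysis is on linear MFI (a log option exists); because F statistics are
scale-invariant, a common positive rescaling cannot change the selection.
Under a global null the ≥2-of-3 rule with Tukey adjustment is strongly
conservative; the test suite bounds the null selection count by Monte Carlo
against the naive 48·(3α)² envelope.

## The synthetic generator

`simulate_cohort()` emulates the study conditions the pipeline assumes:

* 51 cores of 1.0 mm diameter (analyzable area 0.785 mm²), Poisson cell
  counts with mean 111980/51 ≈ 2196 — the cohort totals roughly 112,000
  nucleated cells. Poisson counts are the standard point-process choice;
  overdispersion is out of scope.
* Cells are uniform in the core disc, except phenotypes listed in
  `clustered_children`, which are placed as Gaussian-displaced children of
  M2 parents (a Thomas process) with rejection resampling keeping children
  inside the disc. At `clustering_sigma = 0` children coincide with their
  parents; the median M2–child distance grows monotonically with sigma.
  Labels drawn as children are removed from the base mixture (their mixture
  entries only validate membership) and the remaining proportions are
  renormalized.
* Marker calls come from the gating rules' truth table (positives on,
  negatives off, unlisted off) with independent per-marker flip noise
  (default 2%), so gating inverts the generator exactly at zero noise.
  Nuclear-stain positivity is Bernoulli per cell with a per-core rate
  (default 90%, configurable per core to exercise the 25% QC boundary).
* Clinical outcomes are proportional-hazards: exponential event times with
  hazard `h0 · exp(β · I[covariate > median])` on the core's true IMSC
  fraction, independent uniform censoring on [0, T] with T solved
  numerically (by `uniroot` on the closed-form censoring probability) for
  the target censored fraction, and times in abstract months — no
  follow-up distribution is being imitated. Defaults: baseline hazard
  0.02/month, HR 2.5, 30% censoring.
* The cytokine generator produces log-normal MFIs for the 48-plex panel in
  three conditions × three OS cell lines with duplicate measurements and a
  log-scale noise SD of 0.1 (a ~10% CV, typical of bead arrays), a shifted
  co-culture mean per engineered effect, and a background condition for
  subtraction.

What the generator does **not** emulate: marker intensities (calls are
binary with symmetric flip noise — no spillover, batch, or
intensity-threshold structure), irregular core shapes or tissue-loss holes,
segmentation errors (over/under-merging), spatial niches other than
M2-centered Thomas clusters, correlated censoring, or cohort-level
covariates (age, stage). Passing tests therefore show the *procedures* are
correct under the stated model, not that the biological conclusions of any
particular dataset would replicate.

## Problem sizes used by the test suite

The suite runs the gating oracle at 10³ random cells, spatial oracle
equivalence on 100 random cores of ≤ 500 cells, mixture recovery at 10⁵
cells, survival parameter recovery at 200 cores × 50 seeds (true
HR = 2.5, 30% censoring), Cox consistency at n = 100/400/1600, and the
cytokine null Monte Carlo at 120 seeds × 48 analytes — sizes at which the
Monte Carlo standard errors are far smaller than the effects being
checked, while the whole suite stays fast enough to run routinely.

## Known limitations

* Phenotype priorities are a modeling choice; different orderings give
  different labels for genuinely ambiguous cells. The rule set is
  configurable precisely because the canonical marker table of any given
  panel should replace the defaults.
* Median-count densities are biased low by at most half a count for skewed
  neighbor distributions; this mirrors the emulated definition rather than
  an estimator-optimal one.
* The survival screen fits one binary covariate per model; no multivariable
  adjustment, proportionality diagnostics or time-dependent effects.
* With duplicate measurements the cytokine ANOVA has few residual degrees
  of freedom; small fold changes (≲1.3×) are detectable only at low noise.
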
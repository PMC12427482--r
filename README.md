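# osimc

Quantification of the osteosarcoma tumor microenvironment (TME) from
imaging mass cytometry (IMC).

IMC profiles a tissue-microarray (TMA) core — ~1 mm of tumor, analyzable
area 0.785 mm² — as a table of segmented cells with centroid coordinates
and binary marker-positivity calls. `osimc` implements the downstream
quantification for studying immunosuppression in osteosarcoma:

* **QC** — drop cores with < 25% nuclear-stain (Ir191⁺) cells; keep markers
  with ≥ 3 positive cells per core in ≥ 10% of cases.
* **Phenotyping** — declarative marker gates with priority-based conflict
  resolution (M2 = CD68⁺CD163⁺, mMDSC = CD11b⁺CD14⁺CD15⁻,
  Treg = CD3⁺FoxP3⁺, … 23 rules), one label per cell.
* **Abundance** — per-core percentages of detectable cells and the IMSC
  composite, mean(M2% , MDSC% , Treg%) (sum mode available; the median
  split is identical either way).
* **Spatial statistics** — within 250 µm of M2 macrophages: median M2–M2,
  M2–MDSC, M2–Treg pair distances, their mean (the M2–IMSC proximity
  composite), median-count densities in cells/mm², and summed IMSC counts.
  Exact grid-indexed neighbor search, verified against an all-pairs scan.
* **Survival** — exclude initially metastatic cases, median-dichotomize any
  per-core metric into high/low (near/far for distances, ties going
  low/near), then Kaplan–Meier, log-rank, and a univariable Cox hazard
  ratio per metric × endpoint (MFS, RFS).
* **Cytokine screen** — background-subtracted bead MFIs, per-analyte
  two-way ANOVA (condition × cell line) with Tukey post hoc; an analyte is
  differentially abundant when co-culture differs from both mono-culture
  controls in ≥ 2 of 3 cell lines.
* **Synthetic cohorts** — a Thomas-process generator (uniform cells in the
  core disc, Gaussian-displaced IMSC children around M2 parents, truth-table
  marker calls with flip noise, proportional-hazards outcomes) reproducing
  the study scale: 51 cores, ~2196 cells/core, ~112k cells.

## Worked example

```r
library(osimc)

co <- simulate_cohort(cohort_config(n_cores = 20, cells_per_core = 800, seed = 7))
rep <- run_pipeline(list(simulate = list(n_cores = 20, cells_per_core = 800, seed = 7)))
head(rep$survival[, c("metric", "endpoint", "n", "logrank_p", "hazard_ratio")], 4)
```

```
          metric endpoint  n    logrank_p hazard_ratio
1 imsc_abundance      MFS 20 0.0005852363   17.3332426
2 imsc_abundance      RFS 20 0.0648290373    3.2340016
3        dist_M2      MFS 20 0.4393447058    0.6327471
4        dist_M2      RFS 20 0.9866713768    0.9902735
```

The generator ties each core's event hazard to its true IMSC fraction
(HR = 2.5 across the median split), so the IMSC abundance composite is the
metric that stratifies metastasis-free survival (log-rank p ≈ 6e-4; the
small-n hazard-ratio estimate is inflated, as single-covariate Cox fits on
20 cases are), while the unrelated spatial metrics stay null. With
`out_dir` set, every stage writes its TSV (QC reports, phenotyped cells,
abundance, spatial metrics, survival screen) plus a `report.yaml` echoing
every threshold, seed and policy applied.

The `analysis/` directory holds the same pipeline as six numbered
narrative drivers (simulate → QC/phenotype/abundance → spatial → survival →
cytokines → demographics) writing their tables under `results/`.

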
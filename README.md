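# pmiclock

Estimating the postmortem interval (PMI) — the time elapsed between death
and examination — from molecular decay is a long-standing goal in forensic
science. `pmiclock` implements, as a tested and reusable R pipeline, a
small-RNA-based approach to PMI estimation in a rodent cardiac model:

* **RNA-integrity clocks.** RIN values (the 1–10 RNA Integrity Number)
  decline approximately linearly with PMI at organ-specific rates.
  `pmiclock` fits per-organ regressions `RIN(t) = a - b·t` and benchmarks
  four multi-organ PMI regressors (lasso, elastic net, a 100-tree random
  forest and a 50–20 ReLU network), with pooled out-of-fold `R²`/MAE/RMSE,
  normalized feature importance and exact interventional Shapley values.
* **Small non-coding RNA annotation.** Collapsed 15–45 nt reads are
  annotated against a reference hierarchy (rRNA → YRNA → miRNA → piRNA →
  tRNA → snoRNA; host genome; else unmapped/exogenous) with one-mismatch
  ungapped matching, the four-way tsRNA taxonomy (5′, 3′-CCA of mature,
  3′ of pre-tRNA, internal; mature tRNAs are built by intron splicing +
  3′ `CCA` + 5′ `G` for histidine), unique rsRNA assignment by ascending
  rRNA length, and reads-per-million (RPM) normalization.
* **Temporal dynamics.** Class-level Student's *t* tests against 0 h with
  Benjamini–Hochberg correction, and fuzzy c-means clustering of
  standardized miRNA profiles (memberships `u_ij = 1/Σ_k(d_ij/d_kj)^{2/(m-1)}`)
  with per-cluster peak time points.
* **Two-stage biomarker stability selection.** Stage 1: per-seed random
  forest recursive feature elimination scored by repeated 3×5-fold CV over
  a 40-seed grid; features recurring in more than 35 per-seed optimal
  subsets become candidates. Stage 2: per-seed 5-fold outer CV with RFECV
  (500-tree forests, `R²` metric) inside each training fold; the
  best-scoring seeds are retained and the most recurrent features form
  the core biomarker panel for a final 15-fold-cross-validated random
  forest on qPCR ΔCt features, with Gini importance and exact Shapley
  attribution. A nine-model benchmark (RF, distance-weighted 3-NN, two
  gradient-boosting variants, two SVRs, ridge/lasso with leave-one-out
  tuning, the 50–20 network) is included.
* **Exogenous bacterial fragments.** Host-unmapped reads are tabulated,
  filtered (`total < 1000` excluded), tested for differential abundance
  with a simplified negative-binomial Wald test (median-of-ratios size
  factors, moment dispersion), assigned to species by exact full-length
  matching, and summarized as composition percentages and genome
  match-rate trajectories.
* **Cross-kingdom target scanning.** Host miRNA target tables are
  filtered at context score ≤ −0.2 and percentile ≥ 90, gene sets are
  tested by hypergeometric enrichment, and a simplified seed-match
  scanner (perfect complement of miRNA positions 2–8) counts candidate
  bacterial mRNA targets per temporal cluster.

Because no public sequencing accession accompanies the study design this
pipeline follows, a first-class **synthetic-data module** generates every
input with the study's statistical structure: toy reference sets with all
invariants enforced, collapsed libraries with planted class trajectories
(tsRNA ×1.50 at 12 h and ×1.76 at 18 h, ysRNA ×0.5 at 30 h, rsRNA flat),
declining RIN tables, a 20-feature ΔCt panel with 7 planted biomarkers
over 71 animals at PMIs ≤ 1470 min, and a late bacterial fragment spike.

## Worked example

```r
library(pmiclock)

cfg  <- sim_config(seed = 1)
refs <- generate_toy_references(seed = 1)
dct  <- generate_deltact_matrix(cfg)

s2 <- stage2_core_biomarkers(dct$x, dct$pmi_min, seeds = 10:15, top_k = 2)
s2$core
#> [1] "piR-mmu-12238" "piR-mmu-34076" "piR-mmu-67900" "tsRNA-Ala-07"
#> [5] "tsRNA-Arg-10"  "tsRNA-Gly-01"  "tsRNA-Lys-04"

fin <- final_model(dct$x, dct$pmi_min, s2$core, k = 15, seed = 1)
round(fin$metrics, 3)
#> r_squared       mae      rmse
#>     0.793   166.480   202.744
```

The selected panel is exactly the seven planted biomarkers, and the final
random forest explains about 79% of the PMI variance with a mean absolute
error of ~166 minutes on pooled out-of-fold predictions — the qualitative
behaviour expected when seven informative ΔCt markers (slopes of
1.2–2.5 × 10⁻³ cycles/min against 0.8 cycles of noise) are measured over a
0–1470 min range. `run_all(run_config(seed = 1))` executes the whole
pipeline (simulate → annotate → dynamics → RIN models → selection → final
model → exogenous → cross-kingdom) into a run directory of TSV/JSON
artifacts that is byte-identical across reruns of the same configuration.

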
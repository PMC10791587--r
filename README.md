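# ncatlas

Multi-tissue noncoding RNA aging trajectories and heterochronic
parabiosis effects, as a tested, reusable R workflow.

## The problem

Body-wide small-RNA sequencing studies profile noncoding RNAs (miRNA,
piRNA, tRNA, rRNA, sno/sn/scaRNA, lncRNA fragments) across many organs
and the whole lifespan, and ask three questions:

1. Which ncRNAs change with age, and are those changes organ-specific
   ("local aging") or shared across the body ("global aging")?
2. Do the globally aging miRNAs repress coherent mRNA target programs?
3. Are age-related expression changes reversed when an aged animal
   shares circulation with a young one (heterochronic parabiosis)?

`ncatlas` implements the full analysis chain for such studies —
filtering, classification, clustering, target inference and parabiosis
effect quantification — together with a negative-binomial synthetic
cohort generator that plants known ground truth, so every stage can be
validated end to end without the original sequencing data.

## The methods at the core

* **Normalization and filtering.** Counts are scaled to reads per mapped
  million, `rpmm_j(f) = c_j(f) · 10⁶ / Σ_f c_j(f)`, once at load.
  Samples need ≥ 2·10⁶ aligned reads; piRNAs must come from prepachytene
  genomic clusters; features need ≥ 1 rpmm in ≥ 1 sample (global
  analyses) or in ≥ 10% of a tissue's samples (local analyses).
* **Aging classification.** Per tissue, Spearman's ρ between each
  feature's rpmm and age. A miRNA is *globally aging* when |ρ| > 0.5
  with one sign in **more than five** tissues, *local* when at least one
  tissue exceeds the ±0.5 interval, *non-aging* otherwise.
* **Nonlinear deregulation.** Fold changes of each later timepoint
  against the 3-month baseline; FC strictly outside [2/3, 3/2] is
  deregulated; Welch t-tests (≥ 3 samples/group) with Benjamini–Hochberg
  correction per (tissue, timepoint) stratum.
* **Trajectory clustering.** Per (feature, tissue), the mean-per-
  timepoint trajectory is z-scored and clustered across all organs with
  fuzzy c-means (Bezdek updates, k-means++ initialization, fuzzifier
  estimated from the data dimensions); the cluster number c ∈ [2, 20] is
  chosen from the minimum-centroid-distance (Dmin) curve; a cluster is
  tissue-specific when ≥ 30% of members come from one tissue.
* **Target inference.** miRNA–mRNA pairs with Spearman ρ < −0.4 and
  P < 0.05 in ≥ 2 tissues; a mirrored positive-correlation control; and
  conserved binding-site enrichment per site type (8mer, 7mer-m8,
  7mer-1a) with two-sided Fisher exact tests on the 2×2 pair counts.
* **Parabiosis.** Fold changes HA/IA (rejuvenation, REJ), HY/IY
  (accelerated aging, ACC) and 21 m/3 m (physiological aging, AGE);
  deregulation = FC outside [2/3, 3/2] **and** P < 0.05; features are
  classified into REJ-unique, ACC-unique, REJ-opposite-AGE and
  AGE-with-ACC groups, and per-feature z-score effect sizes quantify how
  far the heterochronic groups moved.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic cohorts (seed 42) and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_filter_composition.R
Rscript analysis/03_aging_signatures.R
Rscript analysis/04_trajectory_clusters.R
Rscript analysis/05_target_inference.R
Rscript analysis/06_parabiosis.R
```

Selected output from a run:

```
prepachytene filter: piRNAs 60 -> 20
global >=1 rpmm filter: 280 -> 263 features
global aging calls: 20 (20 planted; sensitivity 1.00, 0 false)
local aging calls: 30 (30 planted)
cross-tissue co-clustering of planted global miRNAs: 1.00
8mer      9.69% vs  2.32% -> fold 4.2, Fisher p 1.9e-14
any      24.27% vs  8.23% -> fold 2.9, Fisher p 2.1e-26
planted reversible miRNAs in REJ-opposite-AGE groups: 0.52
```

Reading: the filtering funnel removes the artifact-dominated piRNA
background (60 → 20 → 3 abundant piRNAs survive both filters); all 20
planted global aging miRNAs are recovered with no false global calls;
their trajectories from all six tissues land in common clusters; the
planted conserved-site enrichment in inverse-correlation targets is
detected at every site type; and about half of the planted reversible
miRNAs reach the strict REJ-and-AGE double-deregulation call — the
conjunction of a fold-change window and a t-test at 4–7 samples per
group is power-limited, which the methods vignette quantifies.

A motif check on mature sequences, e.g. the EV-sorting EXOmotif:

```r
scan_motif("CUGGUG", "CNGGNC", max_mismatch = 1)
#   position mismatches matched_substring
# 1        0          1            CUGGUG
```

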
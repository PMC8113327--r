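# ipnimmune

Quantifying how anti-tumour immunity evolves across the ordered histologic
stages of early lung adenocarcinoma — normal lung (NL), atypical adenomatous
hyperplasia (AAH), adenocarcinoma in situ (AIS), minimally invasive (MIA)
and frankly invasive adenocarcinoma (ADC) — from immune-panel expression,
TCR-beta repertoires, allele-specific HLA copy number, neoantigen and
promoter-methylation data, and multiplex-immunofluorescence (mIF) phenotype
calls. Built for computational immunologists analysing indeterminate
pulmonary nodule (IPN) cohorts, and for method developers who need a fully
synthetic, seeded test bed for this class of analysis.

## What the package computes

* **Panel normalization** — negative-control background correction (floor
  1), two-step geometric-mean scaling (6 positive controls, then 40
  housekeeping genes), quantile normalization of endogenous genes, log2.
* **Differential expression** — per-gene one-way ANOVA across stages; the
  p-value distribution is fitted with a beta-uniform mixture
  f(p) = λ + (1−λ) a p^(a−1), giving the null-proportion bound
  π̂₀ = λ + (1−λ)a and the largest cutoff τ with model FDR
  π̂₀τ / (λτ + (1−λ)τ^a) ≤ 0.1%; right-tailed Fisher gene-set enrichment
  with BH adjustment.
* **TCR repertoire** — clonality 1 + Σᵢ pᵢ log₂ pᵢ / log₂ N (one minus
  Pielou's evenness), inverse Simpson diversity 1/Σᵢ pᵢ², density
  (templates per ng usable DNA), and the top-clone rank-bin decomposition
  (top 1 / 2–10 / 11–100 / 101–200 / 201–500 / 501–1000 / beyond 1000).
* **HLA LOH** — per-bin allele copy numbers from logR/BAF by ASCAT-style
  purity/ploidy inversion nB = (ρ − 1 + BAF·2^logR(2(1−ρ)+ρψ))/ρ; LOH
  called when median minor-allele CN < 0.5 **and** paired t-test p < 0.01;
  per-stage frequencies with a chi-square test.
* **Neoantigens × methylation** — all mutant 9–12-mers covering a missense
  site (42 for interior positions); binders at IC50 < 500 nM or rank < 2%;
  mutation-level counts with and without the promoter-hypermethylation
  (>30% CpG) depletion filter.
* **mIF phenotyping** — gate expressions over per-cell marker calls
  (Treg = CD3+CD8−FoxP3+, CTL = CD3+CD8+GZMB+, ThCTL = CD3+CD8−GZMB+, …),
  percent-of-nucleated-cells abundances, marker-signature scores (Th1 =
  mean of IFNG, IL12A, IL12B) and ratios.
* **Association layer** — Spearman / Wilcoxon / Kruskal–Wallis / chi-square
  dispatch over a declared plan of feature pairs, BH adjustment, CNV/AI
  burden summaries.
* **Synthetic cohort generator** — a seeded multi-stage cohort with planted
  progressive expression effects, stage-decreasing clonality and top-clone
  share, stage-increasing HLA LOH (0/0/7/15/33%) and promoter
  hypermethylation, stage-decreasing global methylation, and planted
  cross-feature correlations, so every module's recovery is testable.

## A worked example

```r
library(ipnimmune)
result <- run_pipeline(cohort_config(n_per_stage = 20, seed = 7))
result
```

```
Immunogenomic pipeline run (seed 7 )
  DEGs selected: 182 at tau = 0.000307 
  Stage summary:
 stage  n clonality top1_share topk_share density loh_freq hypermeth_gene_frac
    NL 20     0.288     0.2428      1.000    40.3     0.00               0.126
   AAH 20     0.243     0.1463      1.000    48.8     0.00               0.193
   AIS 20     0.219     0.1115      0.993    59.5     0.15               0.266
   MIA 20     0.179     0.0799      0.960    70.7     0.15               0.380
   ADC 20     0.163     0.0518      0.895    79.5     0.35               0.485
 global_methylation pct_treg pct_ctl
              0.783     0.80    8.30
              0.767     1.20    6.74
              0.743     1.43    5.35
              0.702     2.21    3.90
              0.685     2.15    2.64
```

Reading the table: 182 of the 730 endogenous genes pass the BUM-derived
cutoff τ = 3.1×10⁻⁴ (the generator planted 182 progressive genes in this
configuration). Down the stages, T cell clonality and the top-1 clone share
fall (reduced clonal expansion), density rises (more, but less expanded, T
cells), HLA LOH frequency climbs from 0 to 35% of lesions, the
hypermethylated-gene fraction triples, global methylation falls, Tregs rise
and cytotoxic CD8 T cells fall — the picture of a progressively less
effective, more intensively regulated immune response. `result$associations`
holds the planned Spearman/Kruskal–Wallis/chi-square tests with BH-adjusted
q-values; `plot_stage_trend(result$features, "clonality")` draws any
per-lesion feature across stages.

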
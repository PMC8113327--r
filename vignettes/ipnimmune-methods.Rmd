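---
title: "Methods: quantifying immune evolution across early lung adenocarcinoma stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying immune evolution across early lung adenocarcinoma stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipnimmune)
```

## The scientific problem

Early lung adenocarcinoma develops along an ordered histologic continuum:
morphologically normal lung (NL), atypical adenomatous hyperplasia (AAH, the
recognized preneoplasia), adenocarcinoma in situ (AIS), minimally invasive
adenocarcinoma (MIA) and frankly invasive adenocarcinoma (ADC). A central
question in cancer immunology is how the anti-tumour immune response changes
along that continuum — whether immune surveillance weakens gradually, and
which genomic and epigenomic lesions (HLA loss, chromosomal instability,
promoter hypermethylation) accompany the change.

`ipnimmune` implements the quantitative layer of that analysis as a tested,
reusable pipeline over five assay types: immune gene-expression panels,
TCR-beta repertoires, allele-specific HLA copy number, neoantigen
prediction combined with promoter methylation, and multiplex
immunofluorescence (mIF) phenotyping — plus the association statistics that
tie the features together and a synthetic cohort generator so every stage of
the pipeline is testable without restricted-access patient data.

## Panel normalization

Raw panel counts are processed in a fixed order:

1. **Background correction** — per sample, the mean of the negative-control
   probes is subtracted from every endogenous and housekeeping gene.
   Corrected counts are floored at 1 (not 0) so geometric means and the log2
   transform stay defined; this is standard practice for count panels of
   this design.
2. **Two-step geometric-mean scaling** — each sample is scaled so its
   positive-control geometric mean matches the across-sample mean of those
   geometric means, then again using the 40 housekeeping genes. Scale
   factors outside [0.1, 10] trigger a warning, mirroring panel QC
   conventions.
3. **Quantile normalization** of the endogenous genes only (controls have
   done their job and are excluded from the global adjustment), followed by
   **log2** for variance stabilization.

Tie handling in quantile normalization assigns every member of a tie block
the mean of the reference values over the ranks the block occupies. Two
consequences worth knowing: with ties present, the normalized columns are
*almost* but not exactly identical in distribution, and a second application
of quantile normalization is only guaranteed to be a no-op on tie-free
columns. Both are properties of tie-averaging itself, shared by the standard
implementations, and the package's tests treat them accordingly.

Because each scaling step targets the arithmetic mean of control geometric
means across samples, multiplying one sample's raw counts by a constant
rescales the whole normalized matrix by one global factor (the constant
cancels within that sample; the data-dependent target shifts for everyone).
Relative structure — the only thing downstream statistics consume — is
unaffected.

## Differential expression and the beta-uniform mixture

Stage-associated genes are found by a classical one-way fixed-effects ANOVA
per gene (computed in closed form; genes with zero between-group variation
report F = 0, p = 1 by convention). The resulting p-value distribution is
modelled as a **beta-uniform mixture (BUM)**:

$$f(p) = \lambda + (1-\lambda)\, a\, p^{a-1}, \qquad
  \lambda \in [0,1],\; a \in (0,1],$$

a uniform null plus a decreasing beta capturing signal near zero. The
restriction $a \le 1$ keeps the beta component decreasing, which is what
makes the null-proportion bound $\hat\pi_0 = \lambda + (1-\lambda)a$ (the
density at $p = 1$) valid. Parameters are fitted by maximum likelihood with
bounded L-BFGS-B from a 3 × 3 grid of starting values; the grid removes the
sensitivity of a single start to the flat likelihood ridge that appears when
signal is weak.

The FDR of selecting all $p \le \tau$ under the fitted model is

$$\mathrm{FDR}(\tau) = \frac{\hat\pi_0\,\tau}{\lambda\tau + (1-\lambda)\tau^a},$$

which is increasing in $\tau$ for $a < 1$, so the largest cutoff meeting a
target (default 0.1%) is found by bisection to an interval of $10^{-10}$.
A pure-null fit ($\hat\pi_0 = 1$) has $\mathrm{FDR} \equiv 1$ and returns no
cutoff. Selected gene lists feed a right-tailed Fisher's exact test per gene
set with Benjamini–Hochberg adjustment across sets.

## TCR repertoire metrics

All metrics use the proportional abundances $p_i$ of *productive*
rearrangements only; non-productive rows are dropped at entry with a logged
count.

* **Clonality** $= 1 + \sum_i p_i \log_2 p_i / \log_2 N$ (one minus Pielou's
  evenness, base-2). Zero for a perfectly even repertoire; undefined at
  $N = 1$ where $\log_2 N = 0$, which the package treats as an error. The
  perfectly even case returns exactly 0 rather than a floating-point
  residual.
* **Inverse Simpson diversity** $= 1/\sum_i p_i^2$, ranging from 1
  (monoclonal) to $N$ (even).
* **Density** = total productive templates / usable DNA mass, in templates
  per ng. The normalization constant is a package decision (documented here)
  since per-genome alternatives exist; usable mass is an input.
* **Top-clone bins** — frequency shares of the rank bins top 1, 2–10,
  11–100, 101–200, 201–500, 501–1000 and beyond 1000, plus a configurable
  top-$k$ share (default $k = 100$). Rank ties break lexicographically by
  rearrangement id so results are deterministic.

## Allele-specific HLA loss of heterozygosity

Input per HLA gene is a table of bins with a coverage log-ratio (logR) and
B-allele fraction (BAF) measured at mismatch positions between the two
homologous alleles, plus tumor purity $\rho$ and ploidy $\psi$. The
ASCAT-style inversion gives per-bin allele copy numbers

$$n_B = \frac{\rho - 1 + \mathrm{BAF}\cdot 2^{\mathrm{logR}}\,
  (2(1-\rho) + \rho\psi)}{\rho},$$

symmetrically for $n_A$ with $1-\mathrm{BAF}$; logR is centred so 0 means
coverage at the average tumor ploidy (the forward model in the simulator
uses the matching denominator $\rho\psi + 2(1-\rho)$, so noise-free profiles
round-trip exactly at any purity and ploidy). Values are reported unclipped;
alleles are relabelled so $n_A \ge n_B$, making calls invariant to input
allele order.

**LOH is called when the median across bins of the minor-allele copy number
is below 0.5 *and* a two-sided paired t-test of per-bin major vs minor copy
numbers gives p < 0.01.** The paired t-test is our reading of the
unspecified test behind the p < 0.01 rule; it is the natural test across
mismatch-position bins. Noise-free profiles make the paired differences
numerically constant, where the t statistic is degenerate; the package's
convention is p = 0 for a nonzero constant difference and p = 1 for zero,
so clean planted losses are called and clean balanced profiles never are.
Fewer than 3 bins yields an abstained call rather than a guess. The
"copy number < 0.5" rule is applied to the minor allele — the only reading
under which it defines loss of heterozygosity.

Lesion-level LOH (any HLA gene) is cross-tabulated against stage and tested
with Pearson's chi-square.

## Neoantigens and the methylation filter

For a missense mutation, all 9–12-mer windows fully inside the mutant
protein that contain the mutated position are candidate peptides (an
interior mutation yields 9 + 10 + 11 + 12 = 42). Stop-gain mutations
truncate the protein without creating novel sequence, so they contribute
zero candidates, with a warning — we prefer an explicit convention over
invented junction logic. MHC class I and II candidates are treated
identically; binding predictions arrive as inputs.

A candidate is a **binder** when IC50 < 500 nM *or* percentile rank < 2%
(strict inequalities). A mutation is neoantigen-associated when at least one
of its peptides binds. The **methylation-depletion filter** keeps only
neoantigen mutations whose source gene's promoter has at most 30% of CpGs
methylated; a fraction strictly above 30% defines promoter hypermethylation
(silenced, therefore unlikely to present its neoantigen). The per-lesion
share of genes above that threshold is the hypermethylated-gene fraction.

## Immune phenotyping

Per-cell boolean marker calls (from segmented mIF images; segmentation is
out of scope) are gated: total T = CD3+; CD8 T = CD3+CD8+;
CTL = CD3+CD8+GZMB+; ThCTL = CD3+CD8−GZMB+; Treg = CD3+CD8−FoxP3+. The CD4
compartment is represented by CD3+CD8− because direct CD4 staining is
unreliable in mIF; double-negative T cells are a small, acknowledged
contamination. Abundances are percentages of all nucleated cells.
Signature scores are unweighted means of normalized log2 expression over
marker genes — Th1 uses IFNG, IL12A, IL12B; the Th2 (IL4, IL5, IL13) and
Th17 (IL17A, IL17F, RORC) sets are package defaults for lineage-defining
cytokines/factors and are configurable, since no canonical panel lists
exist. Count-based ratios (e.g. Treg/CTL) add a pseudocount of 0.01
percentage points to both terms; score ratios of positive quantities use no
pseudocount.

## Association layer

Continuous–continuous pairs use two-sided Spearman rank correlation with
mid-rank ties (asymptotic p, appropriate under ties); continuous–categorical
uses the Wilcoxon rank-sum test for two levels (exact when both groups have
at most 25 observations and no ties, otherwise the normal approximation
with tie correction) or the Kruskal–Wallis H test for more;
binary–categorical uses Pearson's chi-square. Benjamini–Hochberg adjustment
is applied within an explicit test plan, and significance flagged at
p < 0.05. Every result row carries its test name so dispatch is auditable.

## The synthetic cohort generator

The generator is first-class, tested code: it draws a cohort whose
statistical structure matches what the analyses assume, so planted
parameters can be recovered end-to-end.

* **Stages** — equal lesion counts per stage (default 50, the scale at
  which the stage-trend tests are exercised).
* **Expression** — 730 endogenous + 40 housekeeping + 6 positive + 8
  negative controls (the negative-control count is unspecified in panel
  descriptions; 8 is a configurable default). A quarter of endogenous genes
  shift by ±0.25 log2 per stage step over log-normal noise (sd 0.4 log2),
  per-sample scale factors and Poisson background make the normalization
  steps non-trivial.
* **Repertoires** — clone frequencies follow a stick-breaking (GEM) law,
  Beta(1, α) stick fractions, with α rising from 8 (NL) to 60 (ADC): a
  single parameter controls evenness, so the expected top-clone share and
  clonality fall monotonically with stage while diversity rises. Template
  counts are a multinomial draw (totals scale with usable DNA mass and a
  stage-increasing density), and zero-template clones are dropped, as a
  sequenced repertoire never reports them.
* **HLA** — lesion-level LOH planted with probabilities 0, 0, 0.07, 0.15,
  0.33 across NL…ADC; one of three HLA genes takes copy numbers (2, 0).
  Emitted logR/BAF are the exact forward-model values plus truncated
  Gaussian noise (sd 0.08 / 0.03).
* **Methylation and instability** — promoter CpG fractions are Beta draws
  with stage-rising means 0.15 → 0.31 (precision 8), chosen so the >30%
  hypermethylation rate climbs realistically from ~13% to ~45%; a latent
  per-lesion chromosomal-instability variable couples stage-declining
  global methylation to AI/CNV burden and Treg infiltration, planting the
  negative cross-feature correlations the association layer must recover.
* **Seeding** — one config seed expands into fixed per-block substreams, so
  regeneration is bit-identical and adding a feature block never perturbs
  earlier blocks.

What the generator does *not* emulate: read-level data (no FASTQ/BAM),
spatial structure in mIF (cells are exchangeable rows), shared clones
across samples, batch effects, and the long-tailed V/J usage structure of
real repertoires. Passing tests therefore demonstrate that the statistical
machinery recovers planted effects under the stated noise models — not that
the pipeline is robust to every artefact of real assays.

## Numerical choices and degenerate inputs

* BUM fitting replaces p = 0 by the smallest positive double (with a
  warning) and errors only if no start converges.
* The FDR-cutoff bisection terminates at an interval of $10^{-10}$;
  a cutoff is "absent" (NA) when even the smallest representable p fails
  the target.
* ANOVA returns p = 1 for genes with no between-group variation, including
  the all-constant 0/0 case.
* Constant vectors make Spearman's rho undefined; the result is flagged
  missing rather than erroring, so one degenerate feature does not abort an
  association plan.
* Even repertoires return clonality exactly 0; single-rearrangement
  repertoires error for clonality (undefined) but return 1 for inverse
  Simpson.

## Problem sizes used in the test suite

Unit and property tests run on small synthetic cohorts (8 lesions per
stage, 120-gene panels, repertoires of 80–160 clones) where oracle
comparisons are exact and fast. Calibration and trend-recovery checks use
the sizes at which those properties are specified: 50 replicate p-value
datasets of 1000 genes for FDR calibration, 1000 noise-free profiles for
LOH specificity, and ten full cohorts at 50 lesions per stage for the
stage-trend medians. These sizes are the package's definition of the study
conditions; they were fixed before the checks were run and are not tuned.

## Known limitations

* The BUM-based cutoff controls *model-based* FDR; when the beta component
  has substantial mass away from zero (small signal, a near 1), realized
  FDP fluctuates around the target with Monte-Carlo error, which is the
  designed behaviour of the estimator rather than a defect.
* The paired t-test interpretation of the LOH p-value is one defensible
  reading of an under-specified rule; alternative tests (e.g. rank-based)
  would change borderline calls.
* Pathway-activation directionality scores from proprietary knowledge bases
  are out of scope; only the Fisher enrichment statistic is implemented.
* TIMER-style deconvolution, HLA typing, purity/ploidy estimation, binding
  prediction and image segmentation are consumed as inputs, never
  re-implemented.

## A worked example

```{r example, eval = FALSE}
library(ipnimmune)

result <- run_pipeline(cohort_config(n_per_stage = 20, seed = 7))
result$summary          # per-stage means of every headline feature
result$associations     # planned tests with BH-adjusted q-values
plot_stage_trend(result$features, "clonality")
```

The per-stage summary shows clonality and top-clone share falling, density
rising, LOH frequency and the hypermethylated-gene fraction rising, and
global methylation falling across NL → ADC — the qualitative trends the
generator plants and the statistics recover.
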
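# immunosig

Transcriptional immune-signature scoring for immunotherapy response, and
its genomic correlates.

Tumors differ sharply in how likely they are to respond to immunotherapy,
and that likelihood tracks both transcriptional immune activity and the
tumor's genomic configuration: mutation-rich ("mutator", M-type) tumors
tend to respond, chromosome-instable (C-type) tumors tend not to.
`immunosig` is for computational biologists and biostatisticians who want
to train and transfer such a predictor and reproduce the downstream
analyses on their own cohorts — or on fully synthetic ones, since the
package ships a cohort generator that makes every stage testable without
any download.

## What it computes

**Immune signature (IS) score.** Genes differentially expressed between
responders and non-responders are selected by a pooled-variance Student
t-test at *P* < 0.005 with a 1.5-fold difference on log2 expression.
The selected genes form a compound covariate per sample,
*c<sub>j</sub>* = Σ<sub>g</sub> *t<sub>g</sub>* *x<sub>gj</sub>* (weights =
training t statistics), and a Bayesian compound covariate predictor
(BCCP) models *c* with equal-variance Gaussian class densities. The IS
score is the posterior responder probability

> IS(c) = π<sub>R</sub> φ(c; m<sub>R</sub>, s) /
> [π<sub>R</sub> φ(c; m<sub>R</sub>, s) + π<sub>N</sub> φ(c; m<sub>N</sub>, s)] ∈ [0, 1],

with responder calls at IS > 0.5. Cohorts are median-centered per gene
before training and before scoring; genes missing on a validation
platform are dropped and the class densities refitted on the surviving
genes. `roc_analysis()` reports AUC (rank formulation, tie-corrected) and
the cutoff maximizing sensitivity + specificity.

**CIN score.** Chromosomal instability per sample as the sum of squared
gene-level GISTIC2 continuous copy-number values, optionally multiplied
by tumor purity.

**Genomic typing.** M (non-synonymous mutations > 200), C (CIN > 5000),
NOS (neither), MC (both, kept explicit).

**Downstream statistics.** Wilcoxon rank-sum scans of IS by
mutation/amplification/deletion status over driver-gene universes with
Benjamini–Hochberg FDR control (1% default); per-cancer logistic odds
ratios of dichotomized genomic status on IS; IS-vs-burden/CIN
regressions on a log10(x+1) axis; Kaplan–Meier, log-rank and Cox
analyses of survival stratified by IS > 0.5.

## Worked example

```r
library(immunosig)

config <- simulation_config(seed = 1)        # 2000 genes, 25 responders / 25 non-responders
cohort <- simulate_cohort(config)

centered  <- center_genes(cohort$expr)
selection <- select_signature(centered)      # P < 0.005 and 1.5-fold
model  <- fit_bccp(centered, selections = selection)
scores <- score_bccp(model, centered)
roc    <- roc_analysis(scores$is_score, cohort$expr$annotations$response)

burden <- count_burden(cohort$mutations, roster = cohort$clinical$sample_id)
cin    <- cin_score(cohort$cna)
types  <- classify_type(burden, cin)         # M: >200 mutations, C: CIN > 5000

surv <- survival_cohort(cohort$clinical, scores, cutoff = 0.5)
lr   <- logrank_test(surv)
```

Output:

```
selected 112 genes (recall of planted DE genes: 1.00)
training AUC 1.000; 25/50 responder calls at IS > 0.5

  M NOS
 30  20
log-rank chi-square 3.78, p = 0.052
```

The 112 selected genes contain all 100 planted differentially expressed
genes plus a handful of false positives, consistent with the 0.005
selection level over 2000 genes; the predictor separates the training
classes completely (AUC 1.000 at effect size 2 SD); with a uniform 0–400
mutation burden 30/50 samples exceed the M threshold while the simulated
copy-number magnitude keeps CIN below the C threshold; and the planted
hazard ratio of 2 yields a borderline log-rank contrast at n = 25 per
arm.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `06_survival.R`), each writing its tables
under `results/`; run them in order from the repository root.

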
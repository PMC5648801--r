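---
title: "The immune-signature pipeline: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The immune-signature pipeline: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Only a subset of cancer patients respond to immunotherapy, and response
correlates with transcriptional immune activity in the tumor and with two
broad genomic configurations: mutation-rich tumors (which present many
neoantigens) tend to respond, while tumors dominated by chromosomal copy-
number instability tend not to. `immunosig` implements the full analysis
chain behind that picture:

1. a transcriptional **immune signature (IS)** trained on a cohort of
   immunotherapy responders versus non-responders;
2. an **IS score** per tumor — the Bayesian posterior probability of the
   responder class under a compound covariate predictor;
3. a **CIN score** summarising chromosomal instability from gene-level
   GISTIC2 copy-number values;
4. a **genomic typing** of tumors into mutator (M), chromosome-instable
   (C), both (MC) or neither (NOS);
5. association scans, regressions and survival analyses connecting the IS
   score to those genomic axes.

A synthetic cohort generator reproduces the statistical structure each
stage assumes, so the whole chain is testable without any external data.

## Signature training

Genes are tested one at a time with a pooled-variance two-sample Student
t-test of responders versus non-responders on log2 expression. A gene
enters the signature when

* `P < 0.005` (two-sided), and
* the class-mean difference on the log2 scale is at least `log2(1.5)`
  (a 1.5-fold difference).

Both thresholds are exposed as arguments of `select_signature()`. The
pooled-variance variant (rather than Welch) is deliberate: it is the
convention of the classical microarray class-comparison toolkits this
design descends from, and it makes the per-gene statistic exactly the
weight the predictor expects. The fold-change filter is applied to the
difference of class means of log2 values; on log2 data this equals
thresholding the ratio of geometric means on the linear scale, so the two
readings of "1.5-fold difference" coincide under this definition.

Degenerate genes are handled explicitly: a gene constant in both classes
has an undefined t statistic and is reported unselected with `p = 1` (with
a warning); a gene with zero within-class variance but distinct means
separates the classes perfectly and is reported with infinite t and
`p = 0` — it passes the p filter but cannot serve as a weight, so
`fit_bccp()` refuses non-finite weights rather than silently clipping.

## Centering and cross-platform transfer

Training and test cohorts are re-normalized independently by centering
each gene across the samples of its own cohort (`center_genes()`). The
centering statistic is the **median** by default: "centering across the
tissues" does not pin down a statistic, and the median is the robust
choice when a signature moves between platforms with different outlier
behavior. The mean is available as an option, and centering is idempotent
either way. RNA-seq inputs are expected on a `log2(x + 1)` scale before
centering; the package consumes already-normalized matrices and does not
re-run probe summarization (a two-column probe-to-gene mapping can be
supplied to `score_bccp()` instead).

## The Bayesian compound covariate predictor

The selected genes are collapsed into one scalar per sample, the compound
covariate

$$c_j = \sum_{g \in S} t_g \, x_{gj},$$

with $t_g$ the training t statistic of gene $g$ and $x_{gj}$ the centered
expression. On the training data the predictor fits equal-variance
Gaussian class-conditional densities of $c$: class means $m_R, m_N$ and a
pooled SD $s$. The IS score of a sample is the posterior responder
probability

$$\mathrm{IS}(c) = \frac{\pi_R\,\varphi(c; m_R, s)}
  {\pi_R\,\varphi(c; m_R, s) + \pi_N\,\varphi(c; m_N, s)},$$

computed in log space so that extreme covariates do not underflow.
Responder calls use `IS > 0.5`. Three conventions are worth stating
because the construction leaves them open:

* **Priors** default to (0.5, 0.5). Equal priors make the 0.5 cutoff the
  likelihood-ratio boundary, which is the natural reading of a "0.5
  posterior cutoff"; they are configurable.
* **Variance pooling**: a single pooled SD is the default; an
  unequal-variance variant is available (`pool_variance = FALSE`).
* **Gene loss on transfer**: when a validation platform lacks some
  signature genes, the missing weights are dropped *without* re-normalizing
  the survivors, and the class densities are refitted on the training data
  restricted to the surviving genes. This keeps the training and scoring
  covariates on the same scale — refitting only the densities, never the
  weights, mirrors how per-platform gene exclusions are handled when a
  fixed signature is transferred.

`roc_analysis()` evaluates a scoring: AUC by the rank (Mann-Whitney)
formulation with midrank tie handling, and the cutoff maximizing
sensitivity + specificity (Youden), ties broken toward the higher cutoff.
The Youden cutoff is reported alongside the fixed 0.5 call threshold but
does not replace it unless the user says so: the two rules answer
different questions (optimal separation on one cohort versus a portable
probability threshold).

## CIN score and genomic typing

The chromosomal-instability score of a sample is the sum of squared
gene-level GISTIC2 continuous values, $\mathrm{CIN}_j = \sum_g g_{gj}^2$;
amplifications and deletions contribute symmetrically and the statistic
scales quadratically. When tumor purity (in (0, 1]) is available the
purity-adjusted score $\text{purity} \times \mathrm{CIN}$ is reported
alongside; either a histological or a consensus (CPE) purity column is
accepted.

Mutation burden is counted from MAF records per sample:
`n_nonsynonymous` covers all protein-altering classes (missense, nonsense,
nonstop, splice-site, translation-start-site, frameshift and in-frame
indels), `n_indel` tallies the indel classes separately as a sub-count,
`n_silent` and `n_other` cover the rest, and
`n_total = n_nonsynonymous + n_silent + n_other` counts every record
exactly once. Both the inclusive non-synonymous count and the separate
indel tally are emitted because the burden axis can be read either way;
the inclusive count is the default typing axis.

Typing uses strict thresholds, read literally from the defining rule
("more than"): M when non-synonymous mutations `> 200`, C when CIN
`> 5000`, NOS when neither. A sample exceeding both gets the explicit
label **MC** rather than a silent precedence rule; by default MC samples
are excluded from M-versus-C contrasts, and the count of MC samples is
logged so the overlap is never invisible. Boundary samples (exactly 200
mutations or CIN exactly 5000) are NOS.

## Association analyses

`scan_features()` tests, for each gene of a fixed universe (e.g. 373
mutation drivers, 87 amplified / 123 deleted genes, supplied as
one-symbol-per-line files via `read_gene_list()`), whether IS scores
differ between altered and wild-type samples. The test is a two-sided
Wilcoxon rank-sum: exact enumeration when the smaller arm has at most 8
samples and there are no ties (which is what makes small-sample oracles
possible), otherwise the normal approximation with tie and continuity
correction. The named test is a rank test, so the scan reports **medians**
per arm and takes its direction from the median difference, even though
the shift it detects is often described in terms of means. FDR control is
Benjamini-Hochberg across the tested universe, with the 1% threshold as
the scan default and 5% elsewhere; `bh_fdr()` validates its input and
returns adjusted values in input order.

`per_cancer_logistic()` fits, within each cancer type, a logistic
regression of a dichotomized genomic status on the IS score and reports
the odds ratio with a Wald CI. Dichotomization at the **within-cancer**
median is the intended default (a global median would confound cancer
type with status). Complete separation is flagged and the OR reported as
a sentinel (`Inf`/0 with `NA` CI) rather than a misleading finite number.

`regress_is()` regresses IS on burden or CIN with a `log10(x + 1)`
transform by default — these relationships are conventionally displayed
on log axes, and the +1 offset (documented, configurable) admits zero
counts. Only linear fits are provided; smooth (GAM) overlays are a
display refinement, not part of the inference, and are out of scope.
`group_compare()` serves the subtype/MSI/viral contrasts: Wilcoxon for
two groups, one-way ANOVA for three or more, with per-group n, median and
quartiles.

## Survival

`survival_cohort()` joins clinical follow-up with IS scores and
dichotomizes at 0.5 into high/low IS groups. Subjects with a zero
follow-up time are excluded with a warning (their risk interval is
undefined). Kaplan-Meier curves, the log-rank test and Cox proportional-
hazards fits (Efron tie handling; optionally stratified by cancer type;
either the group contrast or the continuous IS score as covariate) are
computed with the standard partial-likelihood machinery of the
**survival** package — these are textbook estimators, not contributions
of this pipeline, so the package wraps rather than reimplements them.
Monotone likelihood in the Cox fit is flagged. Progression-free survival
construction from therapy-start/-end annotations is an input-preparation
recipe: the functions consume prepared `(time, event)` pairs.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions; its defaults are the
conditions under which the pipeline's recovery properties are asserted:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes in the expression/CNA matrices |
| `n_samples_per_class` | 25 | responders and non-responders each |
| `frac_de` | 0.05 | fraction of genes with a planted response effect |
| `effect_size` | 2 | log2 shift in responders, units of `noise_sd` |
| `noise_sd` | 1 | Gaussian noise SD (log2 scale) |
| `n_driver_genes` | 100 | driver universe mutations fall on |
| `burden_range` | (0, 400) | uniform per-sample non-synonymous count, spanning the M threshold |
| `cna_magnitude` | 1 | SD of GISTIC2-like values; E[CIN] = `n_genes * cna_magnitude^2` |
| `hazard_ratio` | 2 | hazard multiplier for planted responders |
| `seed` | 1 | master seed; generator k uses `seed + k` |

Expression values are `baseline + effect + noise` with gene baselines
drawn from N(7, 1) on the log2 scale — realistic microarray magnitudes,
irrelevant after centering. Each generator derives its stream from the
master seed by a fixed offset (expression +0, mutations +1, copy number
+2, clinical +3), so subsets are independently reproducible.
`simulate_expression()` can re-plant a given DE gene set, which is how an
independent validation cohort with the same responding biology is
simulated. Survival times are exponential with baseline rate 1/365 per
day, censoring uniform over a 3-year window, purity uniform on (0.5, 1).
The hazard of planted responders is multiplied by `hazard_ratio` as
stated; the favorable-survival direction seen for high-IS patients
corresponds to `hazard_ratio < 1`.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: probe-level microarray artifacts
and batch effects; correlation structure among genes (noise is iid, so
real signatures built from co-regulated genes carry less independent
information than the simulation suggests); copy-number segment structure;
any dependence of mutation burden or CNA on expression beyond the shared
class label; non-exponential hazards; cancer-type heterogeneity.

## Numerical choices and degenerate inputs

* Expression/GISTIC matrices are TSV in the UCSC/TCGA dialect (tab-
  separated, header row, first column ids); duplicated identifiers and
  malformed numeric cells are errors naming the offending row and column;
  missing expression values are rejected unless per-gene median
  imputation is explicitly enabled.
* MAF `Variant_Classification` terms come from the standard GDC
  vocabulary; unknown terms are preserved, flagged, and counted as
  "other".
* Posterior computation is done on log densities with max-subtraction;
  scores are exactly reproducible against a direct density ratio to
  1e-12 in non-underflowing regimes.
* `score_bccp()` refuses to score when fewer than half the model genes
  match (override with `force = TRUE`).
* Test problem sizes were chosen to keep every Monte-Carlo check
  well-powered at desk scale: 200 replicate null gene sets of 300 genes
  for selection calibration, 200 null scans of 40 features for FDR
  calibration, 500 replicates for log-rank type-I error, 50 replicates at
  the planted conditions (effect 2 SD, n = 25/25) for recall and held-out
  AUC, 200 replicates at n = 500 for Cox coverage.

## Known limitations

The signature machinery assumes exactly two classes; the Wilcoxon exact
switch is unavailable under ties (the corrected normal approximation is
used instead); the logistic separation heuristic (diverging slope or SE)
is a flag, not a test; and none of the calibration results transfer
automatically to real cohorts with correlated genes, batch structure or
informative censoring — the generator's scope, above, is the honest
boundary of what the test suite certifies.
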
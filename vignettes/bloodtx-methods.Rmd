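---
title: "Models and design choices in bloodtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in bloodtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bloodtx` analyses two-cohort whole-blood expression studies of ALS-like
case-control designs end to end. This vignette explains the statistical
models behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices we made where the
design was genuinely open.

## The measurement model and preprocessing

Bead-array intensities are modelled on the log2 scale. Detection p-values
should decrease with intensity; when a cohort stores them as 1 − p
(a real defect in public ALS blood data), the per-sample Spearman
correlation between detection p and intensity flips from strongly negative
to strongly positive. `orient_detection_pvalues()` flips any sample with
r > +0.90 and reports it; samples with constant detection p have no
defined correlation and are left unchanged with a warning rather than
guessed at.

Background correction uses the normal–exponential convolution: observed
intensity X = B + S with B ~ N(μ, σ²) background and S ~ Exp(α) signal.
Parameters are estimated per sample by maximum likelihood (saddle-point
approximation as a numerical fallback), and each value is replaced by
E[S | X], which is strictly positive and monotone in X. Quantile
normalization then forces every sample to the mean order-statistic
distribution, with ties receiving the average of their quantiles — this
makes the operation exactly idempotent. Probes mapping to the same gene
are collapsed to the probe with the highest mean expression
(lexicographic tie-break, so the operation is deterministic), and
detection filtering keeps a gene iff it is detected (p < 0.05) in
strictly more than ⌊0.2·n⌋ samples — a strict inequality, so 148 of 740
fails and 149 passes.

Batch structure is handled by parametric empirical-Bayes ComBat
(location and scale), protecting group and sex through the model matrix.
Whether to protect group during batch adjustment is not a settled
question; we default to protecting it (and sex) and expose the covariate
argument, because unprotected adjustment with unbalanced group-batch
layouts can absorb real signal. One caveat the tests document explicitly:
empirical-Bayes shrinkage equalizes batch means *exactly* only when the
standardized batch effects are identical across genes; with heterogeneous
per-gene shifts a small O(τ) residual remains. Outlier screening applies
one round of the two-sided Grubbs test (maximum studentized deviation)
on the first two PC axes at α = 0.05 — a deliberately conservative,
"less aggressive" policy; flagged samples are logged, never silently
dropped. PCA fixes each component's sign by forcing its
largest-magnitude loading positive so results are reproducible across
BLAS builds.

Platform harmonization Z-scores every gene within each platform. This
removes platform-level location/scale differences by construction and is
what makes the √rank signature scores unit-free.

## Differential expression and meta-analysis

Sex effects are removed per gene by least-squares residualization on a
0–1 indicator (equivalently, centering within sex), and the residuals
feed a two-group moderated-t test: per-gene variances s² with d residual
df are shrunk toward a prior s₀² with d₀ df estimated by moment matching
on log s² (digamma/trigamma inversion; d₀ = ∞ when the observed
dispersion of log-variances is at or below its theoretical minimum, in
which case the moderated t reduces to an equal-variance ordinary t).
The implementation delegates to limma's lmFit/eBayes; the test suite
checks it to 1e−8 against an independent transcription of the formulas.

Cohorts are integrated late: per-gene log2 fold-changes and standard
errors from each cohort are pooled for the genes detectable in both, by
DerSimonian–Laird random effects — τ² = max(0, (Q − (k−1))/(Σw − Σw²/Σw))
with w = 1/se², pooled estimate weighted by w* = 1/(se² + τ²), and a
normal z test for the pooled p (the standard output of random-effects
meta-analysis; the choice of the normal reference is ours). DEGs require
FC > 1.10 or FC < 0.909 *and* FDR < 0.10, all strict, applied to the
anti-logged meta estimate.

## Cell-type signature scores

Whole-blood expression is dominated by cell-type composition.
Signatures are derived from a purified-cell reference compendium
(12 types: NP, MC, DC, MP, PL, RBC, ES, CD4, CD8, GDT, B, NK): for each
type, a moderated-t comparison against the pooled other types, the 150
elevated genes with lowest p, re-sorted by fold change, top 100 kept.
Ranks map to weights √(101 − r)/10 — rank 1 gets weight 1, rank 100
weight 0.1 — and a sample's score is the weighted mean of its Z-scored
expression over the signature genes. Missing signature genes renormalize
the weights over the present genes (coverage is recorded); this is our
extension, since the original scheme assumes full coverage. Myeloid and
lymphoid composites are unweighted means of (DC, MP, MC, NP, PL, RBC,
ES) and (CD8, CD4, GDT, NK, B), and the subgroup rule is applied
verbatim: myeloid iff myeloid > 0.05 and lymphoid < −0.05, mirrored for
lymphoid, everything else unassigned. External signatures (e.g. a
100-gene altitude-response list) are scored with the same √rank scheme
by default — whether such lists should instead get equal weights is not
documented anywhere we could rely on, so the weighting is exposed as a
choice.

## Enrichment and GWAS proximity

The rank-enrichment statistic sorts genes by a score, tracks the
cumulative fraction of a gene set recovered versus rank fraction, and
averages the displacement from the diagonal (bounded by ±0.5); the
p-value is a two-sided Wilcoxon rank-sum test of set versus complement.
Fisher overlap tests are two-sided by the minimum-likelihood rule (the
sidedness convention of `fisher.test`), with a Haldane-corrected odds
ratio when a margin contains a zero.

GWAS proximity measures each gene's point-to-interval distance to the
nearest locus (0 inside the span; coordinates 1-based inclusive, with
BED export converting to 0-based half-open). Because gene density and
locus density vary, significance comes from resampling: the observed
mean distance of a top set is compared with means of 10,000 same-size
uniform draws from the universe, and the empirical p uses the add-one
rule (r + 1)/(n + 1) — conservative, and never exactly zero.

## Diagnostic cross-validation

Every trial draws class-balanced disjoint train/test sets (296 + 100 per
class at full scale; smaller studies are scaled proportionally and the
scaling is logged), ranks genes by training-set moderated-t p, fits a
PCA on the training partition only and projects the test partition on
the training loadings — no test information touches any fitted object.
The gene-ranking rule for the "input genes" axis is our choice (the
obvious alternatives — variance, fold change — behave similarly).
Classifiers are unpenalized logistic regression (PC features are
orthogonal, so no penalty is needed), random forest (default
ntree = 400, mtry = 50 at the full-scale feature count), and an
RBF-kernel SVM. Per trial we record accuracy, sensitivity, specificity
and a McNemar test of marginal homogeneity — continuity-corrected
chi-squared, switching to the exact binomial when the off-diagonal total
is under 25, and p = 1 when it is zero.

## Survival modelling

The genome-wide screen fits one covariate-adjusted Cox model per
detectable gene (age, sex, site of onset, cohort; Efron ties), with
expression standardized per gene so hazard ratios are per SD. Genes at
P < 0.15 are clustered on |1 − r| (average linkage) and the tree is cut
to a target group count — we default to candidate count / 13.4, i.e.
about 13 genes per group; the representative of each group is its
lowest-p gene (ties: larger |log HR|, then gene id). Stepwise selection
then adds the candidate with the smallest likelihood-ratio p while below
0.15 and drops any member whose drop-one LRT p exceeds 0.15; we use LRT
rather than Wald criteria because it is stable near collinearity (the
referenced stepwise tools use Wald-style rules; only the 0.15 threshold
is fixed by convention). An oscillation guard terminates if a model
state repeats.

Concordance defaults to Harrell's C (exactly testable by pair
enumeration); the Heagerty–Zheng incident/dynamic integrated AUC — the
index the original analyses quote — is provided as an option, computed
as the risk-set rank AUC at each event time integrated with weights
2·f(t)·S(t) from the Kaplan–Meier estimate. Cross-validation compares a
base model (covariates only) with a full model (covariates + signature)
on held-out linear predictors; the signature may be fixed before CV
(default, matching how a fixed gene list is usually evaluated) or
re-selected inside each training partition (`reselect = TRUE`) to expose
selection optimism. AFT contrasts fit a Weibull model — the family is
our choice; the log-linear median property makes the high-vs-low
(80th/20th percentile) median-survival ratio exactly exp(β·Δx) —
and `predicted_survival_spread()` contrasts the patients whose predicted
median survival sits nearest the 20th and 80th percentiles of the
fitted Cox model's predictions.

## The synthetic generator

`generate_cohorts()` builds each sample as the log2 of a
proportion-weighted linear-scale mixture of purified reference profiles.
Per-sample proportions are Dirichlet draws (concentration 80) around a
realistic whole-blood baseline (neutrophils 55%, CD4 8%, monocytes and
platelets 8%, …), with ALS multiplying the neutrophil mean by 1.5 and
the erythroid mean by 0.67 — these effect sizes are set for testability;
no published composition effect sizes exist for this design, so they
are not biological calibrations. On top of the mixture: 50 direct DEGs
at ±0.5 log2 restricted to the shared panel, a 25-gene male-additive sex
effect (0.5 log2), an additive per-gene batch shift (SD 0.4) applied to
the second index-contiguous block of each cohort, a per-gene platform
offset (SD 0.25) on cohort 2, and N(0, 0.3²) noise. Detection p-values
follow a decreasing sigmoid of intensity centred at the sample's 20%
intensity quantile (slope 3), with uniform noise added on the *logit*
scale — on the p scale, noise destroys the rank correlation in the
saturated tails and would make the orientation defect irreparable — and
30% of samples store 1 − p. Survival times are proportional-hazards
Weibull (shape 1.5, baseline median 2.5 years) with log hazard linear in
age, sex, onset site and five planted genes at |log HR| = 0.5 per SD;
uniform censoring has its upper bound solved numerically so the expected
censored fraction is 30%. GWAS loci are placed round-robin within 9 kb
of target genes for a configured fraction and uniformly elsewhere.

Default sizes are ≈1/4 of a full-scale study (cohort 1: 60 ALS/120 CTL;
cohort 2: 40 ALS/35 CTL/20 MIM; 2000 genes with 1800 shared), chosen so
the complete pipeline, the calibration suites and the recovery
experiments all run in minutes on one CPU; full-size runs only need a
different `sim_config()`. The recovery experiments use 400 patients and
2000 genes with 30% censoring, and the diagnostic-power fixture plants a
50-gene 2-SD shift.

What the generator does *not* emulate: probe-level bead data, spatial
array artifacts, correlated gene modules beyond those induced by the
mixture, non-proportional hazards, informative censoring, and ALS-mimic
(MIM) samples with their own expression signature (MIM samples differ
from CTL only through sampling noise). Passing tests therefore certify
the statistical machinery — calibration under the null, recovery of
planted effects through the full pipeline — not performance on real
cohorts; headline numbers from real data (DEG counts in the thousands,
~87% diagnostic accuracy, concordance 0.74) are out of reach of any
desk-scale simulation and are not targets of the test suite.

## Numerical conventions

Empirical p-values use (r + 1)/(n + 1). Strict inequalities everywhere a
threshold is quoted. Signature selection requires elevation beyond 1e−9
log2 units so floating-point jitter can never count as "elevated".
Quantile-normalization ties average; probe-collapse ties take the
lexicographically smallest probe; cell-type assignment ties take the
first type in canonical order, with a warning. Gene coordinates are
1-based inclusive internally; BED I/O converts explicitly. All
generators take integer seeds and are bit-reproducible; every
stochastic pipeline function accepts a seed and derives per-trial
streams from it.

## Containers

Expression grids stay plain numeric matrices (genes × samples) — the
convention of the field's linear-model tooling, and the natural shape
for per-gene operations. Everything tabular that a user reads or joins —
DE and meta tables, Cox screens, enrichment results, scores, CV
summaries — is a tibble, pipes cleanly, and has `tidy()`/`glance()`
methods on the fitted-object side (`de_result`, `meta_de_result`,
`stepwise_cox`, `cv_outcome`, `cv_survival`) plus `autoplot()` methods
for enrichment curves, PC scores and resampling nulls.
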
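---
title: "Molecular activity scoring for ulcerative colitis biopsies: models and methods"
author: "colitisScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular activity scoring for ulcerative colitis biopsies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colitisScore)
```

## The problem

Ulcerative colitis (UC) is managed against ordinal, observer-dependent
instruments: the endoscopic Mayo subscore (0–3), the partial and total Mayo
composites, the physician's global assessment, and fecal calprotectin. This
package implements a molecular scoring workflow for colon-biopsy
transcriptomes that (i) maps genome-wide probe-set expression against binary
endoscopic activity (Mayo subscore > 1 vs ≤ 1), (ii) reduces the transcriptome
to a continuous *probability of active disease* via a cross-validated
ensemble classifier, (iii) summarizes calprotectin biology in the tissue as a
control-standardized transcript-set score (MCalpro), and (iv) relates these
molecular scores to 3–6-month clinical outcome.

Because the cohort the workflow was designed around is not publicly
deposited, the package ships a seeded synthetic cohort generator with planted
ground truth. Every statistical guarantee the package claims is demonstrated
on that generator, at the cohort scale the workflow targets.

## Data model

`ColitisCohort` extends `SummarizedExperiment`: the `"exprs"` assay holds
log2 probe-set intensities (probes × samples), `colData` the clinical table
(diagnosis UC / IBDU / control, Mayo components, fecal calprotectin µg/g,
labeling kit, status code), and `rowData` the probe → gene annotation with
interest-set flags. Validity rules enforce finite expression, unique ids,
Mayo subscores for every diseased biopsy, and no clinical grading on
controls.

Two labeling-kit batches are harmonized by `applyKitCorrection()`: per probe,
an additive log2 offset equalizes the kit means (a multiplicative correction
factor on the linear scale), with the larger kit as reference. This was a
genuinely open design point — a per-probe additive offset is the simplest
harmonization consistent with a "correction factor"; it is idempotent and
preserves all within-kit contrasts, but deliberately does not adjust any
kit–class confounding (the generator keeps kit assignment independent of
severity by default, with a confounded variant behind a flag so the
correction can be stress-tested).

## Differential expression: the moderated t

`fitModeratedT()` fits, per probe, the two-group comparison on log2 values
with an empirical-Bayes moderated t-statistic. With per-probe pooled residual
variance $s_g^2$ on $d_g$ degrees of freedom, a scaled inverse-chi-square
prior $(d_0, s_0^2)$ is estimated by moment matching on the log-variance
scale: with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$\operatorname{trigamma}(d_0/2) = \operatorname{Var}(e) - \operatorname{trigamma}(d_g/2),
\qquad s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\},$$

solved with a Newton trigamma-inverse. The posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and

$$t_g = \frac{\bar x_{g,\text{active}} - \bar x_{g,\text{inactive}}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d_g} \text{ under } H_0.$$

When the observed variances are no more dispersed than chi-square sampling
noise the prior df is infinite and all probes shrink to the common
(arithmetic-mean) variance; in particular, with identical per-probe sample
variances the moderated t equals the ordinary pooled t exactly. The test
suite verifies the whole fit — prior df, prior variance, t, and p — against
the limma implementation to near machine precision on random data, and
verifies null calibration (fraction of p < 0.05 ≈ 0.05) on signal-free
cohorts of 5,000 probes.

FDR control is Benjamini–Hochberg step-up (`benjaminiHochberg()`, checked
identically against `p.adjust`). Group means are reported as linear-scale
geometric means, $2^{\overline{\log_2 x}}$, the magnitude convention of
expression tables; controls never enter the test and contribute only a
display column. Ranked top lists (`rankTranscripts()`) sort by unadjusted p
with ties broken by larger |log2 fold change| then probe id, optionally
collapsed to each gene's best probe ("unique transcripts").

## The ensemble classifier

`crossValidate()` implements the Mayo_Prob construction:

* stratified 10-fold split (fold sizes and per-fold class counts within one
  sample of balance; `assignFolds()`),
* **fold-internal** feature selection: ordinary two-sample t-test on the 90%
  training split only, top 20 probes by p (`selectFoldFeatures()`),
* a 12-learner panel fit on the standardized 20-feature training submatrix,
* out-of-fold scoring of the held-out 10%, so each biopsy is scored exactly
  once by a model that never saw it,
* the per-sample **median** of the 12 learner probabilities as the ensemble
  score, and the pooled out-of-fold Mann–Whitney AUC as the performance
  summary.

The roster maps the intended algorithm panel to the implementations available
in this stack: `lda` (MASS), `rda` (an in-package shrunken-covariance
Gaussian discriminant), `mda` (mclust mixture discriminant), `fda` (quadratic
discriminant as the flexible-boundary analogue), `gbm` (xgboost), radial and
linear SVMs with Platt-calibrated probabilities (e1071), `rf` (randomForest),
a decision tree (rpart), `nnet`, ridge-penalized logistic and elastic-net
logistic (glmnet). Hyperparameters are fixed, sensible defaults with no
per-fold tuning; each learner has a more-regularized fallback and is dropped
with a warning if both fits fail (the fold aborts if more than half the
roster drops). The roster is an ordinary list argument, so an alternative
panel can be swapped in everywhere.

Two cohorts are scored throughout: `Mayo_Prob_1` (UC biopsies only) and
`Mayo_Prob_2` (UC + IBDU). Feature selection is a deterministic ranking, so
the final-refit feature list (`fitFinalClassifier()`) is seed-free; fold
assignment and the stochastic learners are governed by the single `seed`
argument, and identical seeds reproduce identical outputs byte for byte.

Two properties of this design carry the scientific weight, and both are
tested: **out-of-fold discipline** (poisoning held-out columns with NaN does
not change fold-internal feature selection; signal-free cohorts yield
chance-level AUC — the guard against selection-bias leakage that fold-external
feature selection would fail) and **power at the design operating point**
(AUC ≥ 0.85 with 200 planted probes of ~1 log2-unit effect among 5,000, at
n = 140).

## Transcript-set scores and MCalpro

`standardizeToControls()` divides each probe's linear expression by its
geometric mean over the control biopsies: $2^{\,x_{gs} - \bar x_{g,\text{ctl}}}$.
"Standardized" admitted two readings (z-score vs fold-of-control); the fold
scale was chosen because reported transcript-set scores live on a positive
few-fold scale and a geometric mean of z-scores (which can be ≤ 0) is
ill-defined. A z-score variant remains available behind `method = "zscore"`
for sensitivity analysis. A transcript set's score is the geometric mean of
its probes' standardized values (`transcriptSetScore()`); by construction the
control population's geometric-mean score is exactly 1 for every set.
`mcalproScore()` builds the molecular calprotectin set from every probe
annotated S100A8 or S100A9 — the calprotectin heterodimer subunits, read out
in tissue.

## Overrepresentation analysis

`oraTest()` computes, per gene set, the one-sided hypergeometric tail
$P(X \ge k)$ for the overlap $k$ between the query (by default the top 150
activity-increased unique genes, `selectEnrichmentInput()`) and the set,
conditioned on a universe of all genes represented on the array — enrichment
conditioned on measurability. Gene-set collections are inputs (GMT files, no
downloads), since term memberships are database-version dependent. BH applies
across each collection. The implementation is verified against the one-sided
Fisher exact test on 500 random configurations (agreement to 1e-10).

## Outcome association battery

The clinical endpoint is the 3–6-month status code dichotomized at > 1 (poor
outcome). `buildPredictorTable()` assembles, per diseased biopsy, both
out-of-fold ensemble scores, MCalpro, and the clinical covariates; every
downstream statistic is complete-case and reports its n (fecal calprotectin
and follow-up are only partially observed, as in real cohorts).

* `spearmanTest()`: midrank correlation, t-approximation p on n − 2 df;
  constant inputs return an explicit *undefined* marker.
* `welchTest()`: Welch/Satterthwaite via `t.test`.
* `aucMannWhitney()`: midrank AUC; invariant to monotone transforms.
* `singlePredictorScreen()`: univariate logistic fits, Wald p, predictor AUC;
  perfect separation is flagged and falls back to a ridge-penalized Wald p.
* `likelihoodRatioCompare()`: nested logistic models,
  $\Lambda = 2(\ell_{full} - \ell_{reduced})$, chi-square df = rank
  difference (aliased covariates add nothing). Type-I error is verified at
  0.05 ± 0.02 over 1,000 null simulations at n = 140.
* `permutationImportance()`: a 500-tree probability forest (ranger,
  √p features per split); importance = mean decrease in **out-of-bag** AUC
  over 50 permutations per variable, computed from per-tree predictions and
  the kept in-bag matrix. AUC-decrease was chosen over Gini so importances
  compare across mixed-scale predictors. Deterministic per seed and invariant
  to predictor column order.

## The synthetic cohort generator

`simulateCohort()` emulates the study conditions end to end; its defaults are
the emulated cohort: 128 UC + 13 IBDU biopsies, 17 normal controls, 49,495
probe sets, Mayo subscore weights (25, 33, 49, 34)/141.

The severity structure is the generator's central modeling decision. Each
diseased biopsy has an *endoscopic severity* equal to its Mayo subscore plus
U(−0.25, 0.25) jitter (scores vary within subscore groups), and a latent
*molecular severity* equal to the endoscopic severity plus N(0, 0.6):
endoscopy grades tissue inflammation with error, a clinically documented
property of the instrument (substantial intra- and inter-observer
variability). Expression shifts, tissue calprotectin, fecal calprotectin, and
the status code are all driven by molecular severity; the Mayo subscore is
the imperfect observation of it. This is what makes the outcome analyses
non-circular: molecular features can genuinely out-predict the endoscopic
grading because they read the driver more directly.

Remaining constants, chosen once:

* baseline log2 means ~ N(7, 1.5); per-probe noise SD = `noise_sd` ×
  lognormal(0, 0.25);
* planted effects: `effect_size` × U(0.5, 1.5) per unit severity, random
  sign; defaults 200 signal probes, effect 1.0;
* S100A8/A9: always planted, always increased, coupling 0.8 × `effect_size`
  with low probe noise (SD 0.35) — abundant transcripts reading out
  neutrophil influx directly. This puts MCalpro on the few-fold-over-control
  scale that transcript-set scores occupy in practice;
* fecal calprotectin: ln(fcal) = ln 60 + 1.6 × (S100 log2 shift) +
  N(0, 1.8) — lognormal (strictly positive, heavy-tailed), observed for 60%
  of diseased biopsies. The noise is large on purpose: stool calprotectin is
  a noisy, indirect readout, and these constants place the simulated
  MCalpro–fecal-calprotectin Spearman correlation near 0.6 and make fecal
  calprotectin a weak outcome predictor, the regime the workflow is designed
  for;
* status code: Pr(status > 1) = logistic(−2.2 + 1.3 × molecular severity);
  within the poor (2, 3) and good (0, 1) grades the code is uniform; 57% of
  diseased biopsies have follow-up;
* labeling kit: second kit with probability 0.5, per-probe offsets
  N(0, 0.25), independent of severity unless the confounded variant is
  requested.

The truth table (signal set, per-probe planted effects, per-sample
severities, kit offsets, baselines, the S100 probe ids) travels with the
cohort in metadata and round-trips through a JSON sidecar next to the
written files.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: probe-level (pre-summarization) intensities and RMA,
patient-level repeat-biopsy correlation (each biopsy is independent),
center effects on expression, gene–gene correlation beyond the shared
severity factor, and any treatment effect between biopsy and follow-up.
Real-data performance claims require the real cohort.

## Numerical choices and degenerate inputs

Zero-variance probes get t = 0, p = 1 and a flag rather than an error.
Ranking ties break by |fold change| then probe id, so orders are total and
reproducible. Ensemble medians over an even learner count average the central
pair; dropped learners shrink the median's denominator rather than
invalidating the fold. Scores outside [0, 1] beyond 1e-6 tolerance are a
contract violation and raise an error; inside tolerance they are clamped.
Constant predictors return explicit *undefined* markers, never silent zeros.
All seeds are derived from a single user seed through a fixed integer mixer,
and every stochastic component (fold assignment, learners, forests,
permutations) consumes only derived seeds, which keeps whole-pipeline runs
byte-identical under a fixed config.

## Problem sizes used in validation

The heavy validation runs use n = 140 biopsies with 5,000 probe sets — the
design's sample size with a probe dimension scaled ~10× below the full array
— and 10 generator seeds for the leakage guard. The forest-importance
structure (molecular features out-ranking clinical covariates for outcome
prediction) is asserted on the importance ranking averaged over 5 generator
seeds: with ~57% follow-up and ~60% calprotectin availability the forest's
complete-case n is ≈ 40, where any single ranking among seven correlated
predictors is dominated by sampling noise; the seed-averaged ranking is the
stable qualitative object. These sizes are stated here as the package's
validation design so that reruns are comparable.

## Known limitations

* The kit correction equalizes marginal kit means only; confounded designs
  need an explicit covariate model.
* The classifier panel's analogue learners (rda, fda, gbm, C5.0, bayesglm
  mappings) are commodity substitutes aggregated by a median precisely so
  that no single learner's idiosyncrasy matters; an exact-match roster can be
  swapped in via the `roster` argument.
* Single-predictor p-values in the outcome battery are Wald p's from
  univariate logistic fits; with n ≈ 40–80 complete cases they are
  screening-grade, not confirmatory.
* MCalpro uses every probe annotated to S100A8/S100A9; probe-level
  disagreement within a gene is averaged, not modeled.
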
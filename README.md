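# colitisScore

Molecular activity scoring for ulcerative colitis (UC) biopsy
transcriptomes. For gastroenterology and translational-genomics groups
working with bulk microarray expression of colon biopsies, the package turns
a probe-set × sample log2 expression matrix plus a clinical table into:

* a **molecular landscape** of disease activity — an empirical-Bayes
  moderated t-test of every probe set against binary endoscopic activity
  (Mayo subscore > 1 vs ≤ 1), with BH-FDR, ranked top lists, and a volcano
  table;
* a **probability of active disease** per biopsy — stratified 10-fold
  cross-validation with fold-internal top-20 feature selection feeding a
  12-learner panel whose per-sample *median* is the ensemble score
  (`Mayo_Prob_1` on UC biopsies, `Mayo_Prob_2` on UC + IBDU), summarized by
  the pooled out-of-fold Mann–Whitney AUC;
* **MCalpro**, a molecular calprotectin score — the geometric mean of
  S100A8/S100A9 expression standardized to a normal-colon control
  population (control geometric mean ≡ 1);
* **overrepresentation analysis** of the top activity-increased genes
  against user-supplied GMT gene-set collections (one-sided hypergeometric
  test);
* an **outcome battery** against the 3–6-month status code (> 1 = poor
  outcome): Spearman correlation tables, Welch group tests, univariate
  logistic screens, nested-model likelihood-ratio comparisons, and
  random-forest permutation importance by out-of-bag AUC decrease.

The moderated statistic is
t = Δx̄ / (s̃ √(1/n₁ + 1/n₂)) with posterior variance
s̃² = (d₀s₀² + d s²)/(d₀ + d), the prior (d₀, s₀²) moment-matched to the
observed residual-variance distribution on the log scale; p-values use
d₀ + d degrees of freedom.

Because the cohort this workflow targets is not publicly deposited, the
package includes a first-class synthetic cohort generator
(`simulateCohort()`) with planted ground truth — activity-coupled signal
probes, S100A8/A9 tied to a noisy lognormal fecal calprotectin, two
labeling-kit batches, and status codes driven by latent molecular severity —
against which every stage is validated. See the methods vignette
(`vignettes/molecular-scoring-methods.Rmd`) for the models, the generator's
design, and its limitations.

## Worked example

```r
library(colitisScore)

co  <- applyKitCorrection(simulateCohort(cohortConfig(n_probesets = 5000, seed = 1)))
co
#> ColitisCohort: 5000 probe sets x 158 biopsies
#>   diagnosis: control=17, IBDU=13, UC=128
#>   endoscopic Mayo: 0=19, 1=38, 2=56, 3=28
#>   planted truth: 200 signal probe sets

cl1 <- defineActivityClasses(co)           # Mayo_Prob_1 cohort: UC only
#> ActivityClasses [Mayo_Prob_1]: 128 biopsies (78 active, 50 inactive)

de <- fitModeratedT(co, cl1)
sum(de$p_fdr < 0.05)
#> [1] 203
rankTranscripts(de, "increased", k = 3, collapse_to_genes = TRUE)[,
  c("probe_id", "gene_symbol", "mean_active", "mean_inactive", "mean_control", "p_fdr")]
#>         probe_id gene_symbol mean_active mean_inactive mean_control   p_fdr
#> 283  PS000283_at   GENE00283        6131         845.5          657 6.2e-21
#> 4200 PS004200_at   GENE00266         225          32.2           19 6.2e-21
#> 505  PS000505_at   GENE00505        5873         650.9          366 5.5e-20

cv1 <- crossValidate(co, cl1, k = 10, seed = 1)
cv1
#> CrossValidationResult [Mayo_Prob_1]: 128 biopsies, 10 folds, 12 learners
#>   pooled out-of-fold ensemble AUC: 0.963

mc  <- mcalproScore(co)                     # control geometric mean == 1
s   <- sampleInfo(co); dis <- rownames(s)[s$diagnosis != "control"]
spearmanTest(mc[dis], s[dis, "fecal_calprotectin"])[c("rho", "p", "n")]
#> $rho  0.63
#> $p    6.5e-11
#> $n    88
```

Reading the numbers: 203 of 5,000 probe sets pass FDR < 0.05 — almost
exactly the 200 planted signal probes. The top transcripts show the
7–10-fold active/inactive linear-scale (geometric-mean) differences typical
of strongly activity-coupled genes. The out-of-fold AUC of 0.963 is the
honest (leakage-guarded) estimate of how well the 20-probe ensemble
separates Mayo > 1 from Mayo ≤ 1 on this cohort, and the tissue MCalpro
score correlates with the simulated stool calprotectin at ρ = 0.63 on the 88
biopsies where it was measured.

`runPipeline()` executes the whole chain (simulate-or-load → kit correction
→ DE → both classifiers → MCalpro → enrichment → outcome battery) from one
config list and writes every stage table as CSV plus a `report.json`;
identical config and seed reproduce byte-identical outputs.

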
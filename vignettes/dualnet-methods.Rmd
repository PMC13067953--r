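---
title: "Dual local-global SNP prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual local-global SNP prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualnet)
```

## The problem

Regional case-control sequencing panels — for example the dense SNP set
around *APOE* in Alzheimer's disease cohorts — contain thousands of
correlated variants, only a few of which carry disease signal. `dualnet`
ranks the SNPs of such a panel by how much each one contributes to
predicting case status, using two complementary sources of evidence:

* **Local evidence.** SNPs are partitioned into nonoverlapping windows of
  100 consecutive SNPs. For each window, a stacking ensemble is trained on
  the window's genotypes and its holdout classification accuracy becomes
  the *local score* of every SNP in the window. Windows capture short-range
  structure: haplotype blocks, local epistasis, LD with an unobserved
  causal variant.
* **Global evidence.** Each SNP carries four functional annotations
  (genomic context, gene biotype, most severe consequence, clinical
  significance). For every annotation group (e.g. all "missense variant"
  SNPs), the same ensemble is trained on the group's genotypes —
  regardless of genomic distance — and each SNP's *global score* is the
  mean accuracy of the groups containing it. Groups capture long-range,
  biology-mediated structure that windows cannot see.

The two scores are blended per SNP:

$$\text{combined}_j \;=\; \alpha\,\text{local}_j + (1-\alpha)\,\text{global}_j,
  \qquad \alpha \in [0,1],$$

and SNPs are ranked by the combined score. $\alpha = 1$ ranks on window
evidence alone, $\alpha = 0$ on annotation evidence alone.

## The stacking ensemble

Every score in the pipeline is the holdout performance of the same
ensemble (`fit_oof_stack()`):

1. the training samples are split into 5 stratified folds;
2. two base classifiers are trained on each set of 4 folds and predict the
   held-out fold, giving every sample exactly one *out-of-fold* (OOF)
   probability per base learner;
3. a logistic metamodel is fitted on the two OOF probability columns — it
   never sees a base model's in-sample predictions, which is what keeps the
   stack from simply memorizing base-model overfit;
4. the base learners are refitted on the full training set, and holdout
   samples are scored by feeding the refit learners' probabilities through
   the metamodel.

The default base pair is a random forest (100 trees, `mtry =
floor(sqrt(p))`, seeded; via \pkg{ranger}) and a lightly ridge-penalized
logistic regression ($\lambda = 1/n$, via \pkg{glmnet} — penalized so the
fit is well-defined for wide annotation groups with $p > n$ and under
separation). The second slot is pluggable behind a fit/predict contract:
`mlp_learner()` provides a single-hidden-layer neural network
(\pkg{nnet}), and configurations written for an attentive tabular network
(`n_d`, `n_steps`, ...) are accepted and mapped onto it. The logistic
partner is the default because it is fast, convex and deterministic, which
matters when the pipeline fits thousands of stacks; the scores it produces
are holdout accuracies, so any probabilistic classifier pair can sit
behind the same contract without changing the method.

Refitting on the full training subset before holdout prediction (rather
than averaging the five per-fold base models) was a genuine design choice;
refit models use 25% more data per learner and keep prediction a single
model call.

## Nested cross-validation and the $\alpha$ grid

Model selection and evaluation are strictly separated:

* **Outer loop** — 5 stratified folds. Each outer training set (80% of the
  cohort) is used to compute window scores, group scores and $\alpha$; the
  untouched outer test fold only ever evaluates finished panels.
* **Score split** — within each outer training set, an 80/20 stratified
  split provides the train/holdout pair for window and group scoring. The
  80% figure balances fitting (each window model still sees ~380 of 600
  samples) against holdout precision (~120 samples per accuracy estimate).
* **Inner loop** — for each $\alpha$ on the grid $\{0.0, 0.1, \dots,
  1.0\}$, SNPs are re-ranked, the top 100 form a candidate panel, and the
  ensemble is evaluated on that panel by 5-fold OOF cross-validation over
  the outer-training samples, with the metamodel itself cross-validated
  over the OOF rows so that no sample's own data enters either level of
  its prediction. The $\alpha$ with the highest mean inner accuracy wins;
  exact ties break toward the smallest $\alpha$, favouring the
  annotation-informed blend. Window and group scores are computed once per
  outer fold and reused across the grid — only the candidate-panel
  evaluation is recomputed — and identical candidate panels (adjacent
  $\alpha$ values often select the same 100 SNPs) are evaluated once.

The final cross-fold ranking averages each SNP's combined score over the
outer folds (each fold using its own chosen $\alpha$), then re-ranks.
Averaging scores rather than ranks preserves the magnitude information in
fold-level accuracies.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_size` | 100 | SNPs | dense regional panels put ~100 SNPs in a few kb; 14,094 SNPs give 140 full windows |
| trailing partial window | dropped | — | a short tail window's accuracy is not comparable to full windows; `keep_partial = TRUE` retains it |
| `alpha_grid` | 0.0–1.0 by 0.1 | — | 11 points resolve the blend adequately; the inner CV cannot distinguish finer steps |
| `top_k` | 100 | SNPs | candidate-panel size for the inner loop |
| `panel_sizes` | 100, 500, 1000 | SNPs | evaluation panels; bottom panels of the same sizes are the negative control |
| `min_group_size` | 10 | SNPs | a group must support stratified 5-fold fitting with both classes |
| QC thresholds | call rate ≥ 0.95, HWE p ≥ 1e-6, MAF ≥ 0.01, GQ ≥ 20, DP ≥ 10, missing ≤ 0.20 | — | standard WGS case-control practice |
| `knn_k` | 5 | neighbours | imputation neighbourhood |

## Quality control and imputation

QC removes variants in a fixed order (multiallelic, low call rate, excess
missingness, Hardy-Weinberg, MAF, monomorphic) so each removal has exactly
one reported reason; the first failing rule wins. Variants with more than
20% missing calls are *removed* rather than wholly set to missing —
keeping an all-missing column would only defer the failure to imputation.
The Hardy-Weinberg test is the two-sided exact test on the conditional
distribution of the heterozygote count given allele counts.

kNN imputation measures Euclidean distance over mutually non-missing
variants, rescaled by the fraction of coordinates observed (pairs that
share few observed variants are not spuriously close). The neighbour mean
is rounded to the nearest genotype in $\{0,1,2\}$ — half-way ties round
down — so downstream Hardy-Weinberg and LD computations keep integral
genotypes. If fewer than `k` donors exist at a column the column mean is
used and logged; an all-missing column is an error naming the variant.

## The synthetic cohort generator

Real cohorts at this scale are access-restricted, so the package ships a
generator with the statistical structure the method assumes:

* **LD-block genotypes** — a latent-Gaussian threshold model: within each
  block of 50 SNPs, samples draw an exchangeably-correlated normal vector
  ($\rho = 0.7$ by default) and each coordinate is cut at the
  Hardy-Weinberg quantiles of its allele frequency (uniform on
  0.05–0.5). Marginals are Hardy-Weinberg exact by construction and
  within-block LD is directly controlled; a coalescent simulator would be
  more realistic but adds nothing the method exercises.
* **Phenotype** — logistic: $P(\text{case}) = \text{logit}^{-1}(\beta_0 +
  \sum_j \beta_j g_j)$ over planted causal SNPs. Default effects are
  $+0.5$ log-odds per allele for the first half of the causal set and
  $-0.5$ for the second half: causal SNPs are planted as genomically
  contiguous clusters, so each cluster carries a sign-coherent signal —
  as LD-shared risk signals do — while the opposing clusters keep overall
  prevalence near one half. (Alternating the sign per SNP would make the
  effects of LD-correlated neighbours cancel, leaving almost no liability
  variance to recover.)
* **Annotations** — background category frequencies chosen to resemble a
  dense intronic/intergenic region (rare "pathogenic"/"missense" labels);
  causal SNPs receive the informative value of each family with
  probability `annotation_enrichment` (default 0.9).
* **Artifacts** — configurable fractions of missing calls and of calls
  degraded to GQ < 20 or DP < 10, so QC and imputation do real work.

What the generator does **not** emulate: population structure, relatedness,
recombination-map LD decay, allele-frequency spectra from demography, and
annotation families correlated with each other. Passing tests on this
generator therefore demonstrate the pipeline's mechanics and calibration —
leakage-freedom, chance-level behaviour under the null, recovery of
planted signal — not clinical-grade performance on real cohorts.

The test suite and acceptance script run this generator at $n = 600$
samples and 2,000 SNPs (20 causal SNPs concentrated in two windows) for
the planted-signal study, and $n = 400$ / 1,000 SNPs for null calibration;
these sizes give stable averages over 10 seeded replicates while keeping a
full nested-CV run to about a minute.

## Numerical and degenerate-input choices

* Accuracy thresholds metamodel probability at 0.5; a probability of
  exactly 0.5 counts as a control call.
* AUC is the midrank Mann-Whitney statistic, invariant to monotone score
  transforms; single-class inputs are an error, not 0.5.
* Fold-wise confidence intervals are the normal approximation
  $\bar x \pm 1.96\, s/\sqrt{k}$; with 5 folds a t-quantile would be
  wider, but the normal form is the convention for fold-CI reporting.
* A window or group whose stack fails to fit (degenerate columns) scores
  0.5 — uninformative — and is logged, rather than aborting the run.
* Paired t tests on fold metrics: zero-variance differences report
  p = 1 when the mean difference is 0 and are flagged degenerate
  otherwise.
* Ranking ties break by ascending genomic position, then SNP id; rankings
  are total orders, reproducible byte-for-byte under a fixed seed.
* LD $r^2$ is the squared Pearson correlation of unphased additive
  genotypes (composite LD) over mutually non-missing samples — consistent
  with having only genotype matrices, no phased haplotypes.
* Cross-cohort transfer matches variants by (chrom, pos, ref, alt) with a
  logged ref/alt-swap tolerance; position-only matching is available by
  flag. Ablated panels are backfilled from the next ranks by default
  (`backfill = FALSE` gives the conservative shortened panel).

## Known limitations

* Windows are fixed-size and nonoverlapping; LD-adaptive windows might
  score block boundaries better.
* Global scores average all groups containing a SNP with equal weight;
  families whose "unknown" categories correlate are implicitly
  double-counted.
* The blend is linear and global; per-SNP or nonlinear fusion is out of
  scope.
* No covariate adjustment (age, sex, principal components) and no
  polygenic-score comparators — the method ranks SNPs within one region.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(300, 500, block_size = 50,
                  causal_snp_indices = 101:110,
                  annotation_enrichment = 0.9, seed = 1)
sim <- simulate_cohort(cfg)
res <- run_nested_cv(sim$gm, sim$annotations, panel_sizes = 100, seed = 1)
res$alphas                      # chosen blend weight per outer fold
res$panel_evaluations$top_100   # fold AUCs with a 95% CI
head(res$final_ranking)         # the cross-fold SNP ranking
```
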
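---
title: "Developing and validating small-panel polygenic risk scores with prsforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating small-panel polygenic risk scores with prsforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design this package models

`prsforge` implements the two-cohort development-and-validation design that
is standard in candidate-SNP polygenic risk score (PRS) work on breast
cancer and similar common diseases. A GWAS-scale *training* cohort
(thousands of cases and controls with array genotypes) supplies per-SNP
weights for a small curated panel — here, a 24-SNP panel of the kind
assembled from literature-reported susceptibility loci. An independent,
smaller *validation* case-control cohort, genotyped only on that panel, is
scored and the score's predictive ability and calibration are measured.

The PRS itself is the additive score

$$\mathrm{PRS}_i = \sum_{k=1}^{n} \beta_k x_{ik},$$

where $x_{ik} \in \{0,1,2\}$ counts copies of the effect (minor) allele of
SNP $k$ in individual $i$ and $\beta_k$ is a per-allele log odds ratio.
Three weighting approaches are provided through one fitting front end,
`prs_fit()`:

* **RLR (repeated logistic regression).** One unadjusted univariate
  logistic regression per SNP; $\beta_k$ is the marginal per-dosage
  log-OR. This is the summary-statistic-compatible classic: the weights
  can be taken from published association results without individual-level
  data. Its known weaknesses are double-counting of SNPs in linkage
  disequilibrium (LD) and susceptibility to confounding.
* **LRR (logistic ridge regression).** A single multivariate logistic
  model containing all panel SNPs simultaneously, adjusted for age and the
  first two genotype principal components; an L2 penalty applies to the
  SNP coefficients only (intercept and covariates unpenalized). The
  penalty $\lambda$ is chosen by 10-fold cross-validated log-loss, with
  ties resolved toward the stronger penalty. The PRS uses the SNP
  coefficients only.
* **ANN.** A small feed-forward network: the SNP dosages pass through
  fully connected hidden layers of width $\lfloor\sqrt{n_{\text{in}}}\rceil
  + 2$ with leaky-ReLU activations (negative slope 0.01) and dropout, into
  a *linear bottleneck* of length 6; the output neuron sees the bottleneck
  together with age and the two PCs and applies a sigmoid. Training
  minimizes cross-entropy with the Adam optimizer (learning rate 0.01) in
  full-batch epochs. The PRS is the genotype pathway's contribution to the
  pre-sigmoid logit — output weights applied to the bottleneck activations
  — which keeps the score covariate-free and comparable with the linear
  scores. The default hyperparameters (60 iterations, 3 hidden layers,
  dropout 0.4) are the cross-validation-tuned values reported for the
  array-scale study this design emulates; `cross_validate()` retunes them
  for other data.

Because ANN scores have an arbitrary scale per trained network, and tiny
networks are sensitive to initialization and dropout noise, `prs_fit()`
trains `n_restarts` independent networks (default 3) and averages their
per-restart standardized scores. Setting `n_restarts = 1` recovers the
bare single-network score. An alternative score definition — the full
logit minus covariate terms — is available via
`ann_config(score_mode = "full_minus_cov")` and is identical by
construction, since covariates enter the logit additively.

Subtype-specific PRSs (`case_set = "er_pos"` / `"er_neg"`) are trained on
exactly the estrogen-receptor subtype's cases plus *all* controls,
mirroring how subtype scores are built in practice.

# Quality control

Two regimes are bundled as presets of `qc_thresholds()`:

* `"array"` (training cohort): SNP and sample call rate ≥ 99 %, MAF ≥ 1 %,
  exact Hardy–Weinberg test at $P < 10^{-6}$ in controls and $P <
  10^{-10}$ in cases, and exclusion of one member of any sample pair with
  KING-robust kinship $\varphi > 0.0884$ (the conventional second-degree
  cutoff).
* `"panel"` (validation cohort): SNP call rate ≥ 98 %, duplicate-pair
  concordance ≥ 99 %, HWE $P \ge 0.05$ in controls, monomorphic SNPs
  dropped, samples with ≥ 3 failed (missing) genotype calls excluded, and
  population-mean imputation of surviving sporadic missingness.

Filters run in a fixed order (SNP call rate, sample call rate, MAF, HWE by
stratum, duplicate concordance, monomorphic, kinship, failed-SNP count,
imputation), with per-SNP statistics recomputed after every
sample-removal step; imputation is strictly the final step, and MAF/HWE
always use observed (hard-call) dosages, which also makes `apply_qc()`
idempotent. The exact HWE test is the standard exact conditional
construction: conditioning on allele counts, the two-sided $P$ is the sum
of probabilities of all heterozygote configurations no more probable than
the observed one. Kinship exclusion keeps the member with the higher call
rate (ties: the earlier sample in input order survives). "≥ 3 failed
SNPs" is read as three or more missing calls per sample among surviving
SNPs, the panel-genotyping reading of a per-sample assay failure.

One guard is intentional: the KING estimator is hopelessly noisy on a
two-dozen-SNP panel, so the kinship filter requires at least
`kinship_min_snps` (default 100) markers and otherwise steps aside with a
warning. Kinship filtering is meant for array-scale data; on a 24-SNP
validation panel it would mostly remove unrelated people.

# SNP selection

`ld_r2()` is composite LD — the squared Pearson correlation of dosages —
because phase is unobserved in genotype data; haplotype-based $r^2$ from
reference panels will differ slightly, a known dialect difference.
`find_proxy()` implements proxy substitution (best candidate with $r^2 >
0.9$, lexicographic tie-break), `prune_tight_ld()` greedy input-order
pruning at $r^2 > 0.8$ (or 0.3 for rigorous pruning),
`significance_filter()` the genome-wide screen at $P < 5\times10^{-8}$
(strict inequality; boundary values are dropped), and
`direction_concordance()` the cross-cohort same-sign rule, where an
exactly-zero estimate demonstrates no effect and is dropped with a flag.
Greedy input-order pruning is deterministic given panel file order; the
procedure is its own fixed point, so re-running selection on its output
changes nothing.

# Evaluation

`evaluate_prs()` assembles, per adjustment:

* **IQ-OR** — the odds ratio per control-interquartile-range increase of
  the score: logistic regression of status on `score / IQR(controls)`,
  Wald 95 % CI. Invariant to increasing affine transforms of the score.
* **Q4 vs Q1 OR** — extreme-quartile contrast with cut points from the
  control distribution, Woolf CI, Haldane–Anscombe +0.5 on zero cells.
* **AUC** — Mann–Whitney with ties counting one half, standard error by
  Hanley–McNeil ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$), normal CI truncated
  to $[0,1]$.
* **Calibration** — samples are binned by control-score deciles; with the
  pooled middle (5th–6th) bins as reference, the *expected* log-OR of a
  bin is its mean score minus the reference mean (valid because PRS
  weights live on the log-OR scale) and the *observed* log-OR comes from
  the bin-vs-reference 2×2 table. The O/E OR is the through-origin
  least-squares slope of observed on expected log-ORs; 1 means relative
  risks are well calibrated. The middle-bin reference was chosen so
  expected log-ORs straddle zero; `reference = "first"` is available, and
  whether such a slope should carry an intercept is genuinely ambiguous —
  through-origin is used because the coefficient itself is the quantity
  of interest.
* **Residual adjustment** — the PRS is regressed (OLS) on non-genetic
  factors and the residual is evaluated: either the externally computed
  5-year absolute risk alone (`"gail"`; the external risk model is
  consumed as an opaque column, never reimplemented) or the classical
  factor set (age, age at menarche, live births, family history, BMI,
  menopausal status; `"classical"`).
* **Interaction scan** — for every unordered SNP pair, logistic
  regression of status on both dosages and their product, Wald test of
  the product term, with the Bonferroni threshold $0.05/\binom{m}{2}$
  ($\approx 1.8\times10^{-4}$ for 24 SNPs). Separation falls back to a
  likelihood-ratio test, flagged.

# The synthetic cohort generator

No controlled-access data ships with (or is needed by) this package: the
`simulate_cohort()` generator produces cohorts with the statistical
structure the analysis assumes.

*Genotypes.* Hardy–Weinberg proportions at configured MAFs; within an LD
block, each haplotype copies a shared latent Bernoulli allele with a
block-specific mixture weight, solved in closed form from the target
composite $r^2$ and otherwise redrawn at a frequency that preserves each
SNP's marginal MAF. For equal-MAF blocks the realized dosage correlation
equals $\sqrt{r^2_{\text{target}}}$ exactly; for unequal MAFs it is capped
at the attainable (Fréchet) bound.

*Disease.* Status is drawn from
$\operatorname{logit} P(\text{case}) = \alpha + \sum_k \beta_k x_k +
\text{covariate terms} + \sum \delta\, x_i x_j$, with $\alpha$ calibrated
by bisection (tolerance $10^{-4}$) so the expected case fraction matches
the requested quota ratio on a calibration draw; sampling then continues
until exactly `n_cases` and `n_controls` are collected. ER subtype is
assigned by label thinning at `er_pos_fraction` (default 0.70, matching
the ER+ share in validation cohorts of this design), or — when
`subtype_effects` overrides are supplied — from two distinct competing
liabilities whose intercepts are calibrated separately; the latter mode
creates genuinely subtype-specific genetic architecture.

*Covariates.* Defaults emulate an urban Chinese female study population:
age uniform 35–70; BMI normal(23.5, 3) clipped to \[15, 40\]; age at
menarche rounded normal(14, 1.5) in \[10, 18\]; live births
binomial(4, 0.3) (median 1); family history 2 %; menopause probability
rising around age 49; the external 5-year absolute risk logit-normal
around 0.54 %. These are conventions, not reproductions — the source
cohorts' covariate distributions are not public. Covariates are drawn
independently of genotypes by default (real PRSs correlate negligibly
with questionnaire risk factors); `genetic_covariate_corr` can induce
correlation for robustness studies, and a two-subpopulation MAF-shift
mode exists for population-structure/PC testing.

*Artifacts.* `inject_missingness()` adds sporadic missing calls;
`add_related_samples()` appends duplicate, parent-offspring, or
second-degree pairs by explicit Mendelian transmission, for exercising
the concordance and kinship filters.

What the generator does **not** emulate: genome-scale panels, realistic
recombination maps, genotyping batch effects, case-control ascertainment
biases beyond the liability model, or real LD structure. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on any real cohort; the headline
numbers of the real study (IQ-OR ≈ 1.5–1.8, AUC ≈ 0.58–0.60 on its
controlled-access validation cohort) are not reproduction targets.

# Numerical choices

* The ridge solver is Newton–IRLS on the exact penalized likelihood
  ($-\ell + \tfrac{\lambda}{2}\lVert\beta_{\text{SNP}}\rVert^2$) with
  step-halving; at $\lambda \to 0$ it matches `glm()` to $10^{-3}$, and
  the SNP-coefficient L2 norm is non-increasing in $\lambda$.
* The exact HWE test computes configuration probabilities in log space
  with a $1+10^{-9}$ relative slack on the "no more probable" comparison
  so that exact ties are always included; it agrees with direct factorial
  enumeration to $10^{-12}$ on all tables with total ≤ 50.
* ANN inputs (dosages and covariates) are standardized internally, with
  centers and scales stored in the model, purely for optimizer
  conditioning; scores are unaffected in meaning.
* CV folds are stratified by case status to avoid degenerate folds; the
  fold partition is seeded and recorded.
* Discrete scores can collide on quantile cut points; `quartile_or()` and
  `prs_calibration()` fail loudly rather than merge bins silently.
* All randomness flows from explicit seeds; `simulate_cohort()`,
  `prs_fit(method = "ann")` and `run_pipeline()` are bit-reproducible
  given their seed, and the pipeline derives per-stage seeds from one
  global seed recorded in its manifest.

# Design notes and known limitations

* *Bottleneck width vs the width rule.* The hidden-width rule
  $\lfloor\sqrt{n_{\text{in}}}\rceil + 2$ gives 7 for 24 SNPs while the
  bottleneck is 6; the two are deliberately distinct settings
  (`bottleneck_dim` is its own field, default 6). Whether the bottleneck
  is a narrower extra layer or the last hidden layer is ambiguous in the
  design this follows; the distinct-bottleneck reading is the default and
  the other is reachable by setting `bottleneck_dim` equal to the hidden
  width.
* *Panel-derived principal components.* With only a small panel
  available, `compute_pcs()` necessarily works on the panel itself, and
  the unpenalized PC pathway then absorbs a couple of directions of real
  genetic signal (in the extreme — a 2–3 SNP panel — all of it, which is
  why some tests pass externally supplied structure scores). In the
  array-scale setting this emulates, PCs come from genome-wide data and
  the issue vanishes. This slightly handicaps the LRR and ANN scores in
  the bundled synthetic demos.
* *Epistasis demonstration.* `demo_epistasis_design()` fixes the
  conditions under which non-linear weighting should pay off, mirroring
  the mechanisms claimed for ANN superiority: three 3-SNP blocks at
  composite $r^2 = 0.78$ (just under the loose 0.8 exclusion bound, so
  univariate weights double-count them) and one pure-epistasis pair (MAF
  0.45, interaction log-OR 0.7, no marginal effects). In the scaled-down
  experiments the ANN uses 200 iterations and 2 hidden layers — the
  values the package's own 10-fold CV tuning prefers at these cohort
  sizes (n ≈ 3,000 training samples), where the array-scale defaults
  underfit/overfit respectively — with dropout and all other settings at
  their defaults.
* *Problem sizes in the test suite.* Parameter-recovery checks use
  n = 20,000 with the 24-SNP panel; calibration coverage uses 100
  replicates at n = 20,000; the epistasis comparison uses 20 paired
  replicates at n = 3,000/2,000 (train/validation); the interaction-scan
  power check uses a 6-SNP panel. These sizes were chosen to make the
  Monte-Carlo error small relative to the effects being demonstrated
  while keeping the suite quick to run.
* *Pipeline demo.* The bundled pipeline simulates a 4,000-sample
  training cohort and an 800-sample validation cohort (2,200/1,800 and
  430/370 cases/controls), close to the post-QC sizes of the design it
  emulates, and emits the full method × case-set × adjustment report
  grid. With 24 SNPs the kinship filter steps aside (see above) — on
  array-scale input it engages.

# A short tour

```{r, eval = FALSE}
library(prsforge)

# simulate a training and a validation cohort
train <- simulate_cohort(sim_config(2200, 1800, demo_snp_panel(), seed = 1))
valid <- simulate_cohort(sim_config(430, 370, demo_snp_panel(), seed = 2))

# QC both cohorts
qct <- apply_qc(train$genotypes, train$samples, qc_thresholds("array"))
qcv <- apply_qc(valid$genotypes, valid$samples, qc_thresholds("panel"))

# fit the three PRSs and score the validation cohort
fit_rlr <- prs_fit(qct$genotypes, qct$samples, method = "rlr")
fit_lrr <- prs_fit(qct$genotypes, qct$samples, method = "lrr")
fit_ann <- prs_fit(qct$genotypes, qct$samples, method = "ann")
scores <- predict(fit_lrr, qcv$genotypes)

# Table-style evaluation
evaluate_prs(scores, qcv$samples$status, qcv$samples,
             adjustments = c("none", "classical"), method = "lrr")

# or run everything at once
res <- run_pipeline(pipeline_config(
  train = sim_config(2200, 1800, demo_snp_panel(), seed = 1),
  validation = sim_config(430, 370, demo_snp_panel(), seed = 2),
  seed = 1))
res$evaluation
```
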
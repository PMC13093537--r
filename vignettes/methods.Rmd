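---
title: "Individual molecular connectomes: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual molecular connectomes: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imconn)
```

## The perturbation model

A molecular connectome is the region-by-region partial Pearson correlation
matrix of regional PET SUVR values across subjects. `imconn` maps a single
subject onto this group-level object by perturbation: with a normative
reference group of $N$ cognitively normal, amyloid-negative subjects, the
reference connectome $PPC_N$ is the partial correlation of every region pair
controlling for age, sex and education; adding the target subject and
recomputing gives the perturbed connectome $PPC_{N+1}$; the subject's
individual connectome is, per edge $(i,j)$,

$$\mathrm{Strength}(i,j) \;=\;
  \frac{PPC_{N+1}(i,j) - PPC_N(i,j)}
       {\sqrt{\bigl(1 - PPC_N(i,j)^2\bigr)/(N-1)}}.$$

The denominator is the classical sampling standard deviation of a Pearson
correlation at the observed reference value, so Strength expresses the
subject-induced change in units of the reference estimate's own
uncertainty. Two consequences matter for interpretation:

- The *sign* of an edge only records the direction in which the perturbed
  correlation moved away from the reference one. It is not a statement that
  the subject's regional uptake rose or fell.
- The *scale* of Strength for a null subject (one drawn from the normative
  distribution itself) is not unity. A single added observation moves a
  correlation estimated from $N$ points by $O(1/N)$, while the denominator
  is $O(1/\sqrt{N})$, so null Strength values have standard deviation
  $\approx \sqrt{(N-1)/(N(N+1))} \approx 1/\sqrt{N}$ — about $0.10$ at
  $N = 100$ — with mean zero. The statistic is therefore a *relative*
  perturbation score whose null spread shrinks with the reference size; it
  is calibrated (mean zero, known spread), but it is not a unit-variance
  z-score. The package's tests verify both the mean and the $1/\sqrt{N}$
  spread by simulation.

Partial correlation is computed by least-squares residualization of every
region on an intercept plus the covariates, followed by Pearson correlation
of the residuals; this is algebraically the textbook partial correlation,
and the single-covariate closed form serves as an independent oracle in the
tests. For the perturbed network the covariate regression is *refit* on the
$N+1$ sample including the target subject's covariates: recomputing the
partial correlation across $N+1$ subjects means recomputing the whole
estimator, residualization included. Edges with $|r| = 1$ in the reference
make the denominator zero and raise an error by default; an opt-in clip at
$1 - 10^{-12}$ exists for degenerate synthetic inputs and announces itself
when used.

Region ordering is frozen from the input table header into every derived
artifact. Mismatched orders are an error, never silently realigned; edges
live in strict row-major upper-triangle order ($R(R-1)/2$ edges for $R$
regions: 561 for 34, 2278 for 68), with `from_upper_triangle()` as the
exact inverse. Diagonals are excluded everywhere downstream.

## Fingerprinting

Identification correlates upper-triangle edge vectors between baseline and
follow-up connectomes (Pearson), assigns each query to its best-matching
candidate, and counts a success when the identities agree; both directions
are run and pooled (successes over $2n$). Identification runs within
diagnostic group. Argmax ties — measure zero for continuous data — break to
the smallest candidate index and emit a message. Only the first follow-up
scan per subject should be supplied; selecting a later follow-up is the
caller's choice of input.

## Edge contributions, alteration, and the boosting protocol

All supervised learning uses one three-stage XGBoost protocol
(`boost_protocol()`): (1) k-fold cross-validation on the training samples
with early stopping to pick the optimal iteration count, (2) training at
that count and extraction of per-feature gain, (3) evaluation on held-out
samples. The full-scale defaults are `nrounds = 1500`,
`early_stopping_rounds = 50`, `nfold = 10`, `eta = 0.05`, with objectives
`binary:logistic`, `multi:softprob` (3 classes) and `reg:squarederror`, and
AUC as the CV metric for classification. CV folds are built class-balanced
in-package, since a fold missing a class leaves the held-out AUC undefined.

Per-edge *contribution* to diagnostic discrimination is gain-based feature
importance from the multiclass model, normalized to sum to one within each
repetition (features never split on get zero), then averaged over repeated
balanced subsamples and renormalized. Gain is the boosting library's
canonical importance; the importance type is a parameter for sensitivity
analysis. Repetition $r$ seeds its subsample with `seed + r`, so long runs
are reproducible and extensible.

A scan's raw alteration is $\sum_i \mathrm{Strength}_i^2 \times
\mathrm{Contribution}_i$ over upper-triangle edges. Across a batch of scans
a single Box–Cox exponent is fitted by one-dimensional profile maximum
likelihood (the closed-form one-sample profile log-likelihood, maximized by
`optimize` on $[-5, 5]$; the log limit is taken below $|\lambda| <
10^{-8}$), and the transformed values are min-max normalized to $[0,1]$
over the batch. Both transforms are monotone, so ranks are preserved. Raw
values of exactly zero (a null subject under a sparse contribution map) are
offset by half the smallest positive raw value in the batch before the
Box–Cox step; the offset is recorded on the result. The exponent is fitted
per tracer per cohort over all scans entering the batch.

## Group and longitudinal inference

Cross-sectional comparisons use a Kruskal–Wallis omnibus test calibrated by
label permutation, followed by one-sided post hoc Wilcoxon rank-sum tests
in the a-priori disease-severity direction (AD > MCI > CN), also
permutation-calibrated, with Benjamini–Hochberg correction across the post
hoc family. Permutation p-values use the add-one estimator
$(1 + \#\{T^\ast \ge T\})/(B+1)$ and hence lie in $[1/(B+1), 1]$.

Longitudinal trajectories are linear mixed-effects models of alteration on
time since first scan with subject-specific random intercepts and slopes
(`score ~ time + (time | subject)`), fitted by REML; the across-group model
adds group and group-by-time interaction. All scans of all subjects enter.
Fixed-effect p-values use the Satterthwaite approximation (lmerTest) —
the closest available analogue of a Wald test with finite-sample
denominator degrees of freedom. Singular or non-convergent random-slope
fits (e.g., no within-subject time variation) fall back to random
intercepts only and are flagged on the result. The fitted line and 95%
band are computed from the fixed effects and their covariance on a time
grid.

## Benchmarks

Binary diagnostic classification repeatedly draws a stratified training set
(`per_group_train_n` per class), tests on the remainder, and reports the
AUC distribution (median and central 95% interval), per-repetition ROC
curves, and a one-sided sign test of the AUCs against 0.5. AUC is computed
by the Mann–Whitney rank identity with ties averaged, making it invariant
to strictly increasing transforms of the score.

Composite SUVR baselines are volume-weighted means over user-supplied
region sets (YAML: name, regions, volumes); composite-region label tables
are configuration, not code. Paired model comparison uses a one-sided
paired t statistic calibrated by random sign flips of the paired
differences. Cognitive prediction trains a boosted regression of each
outcome on age, sex, education and one-hot dementia status using baseline
scans, evaluates Pearson R (plus MSE/MAE) on follow-up scans, and repeats
with one added scalar feature. Because a single train/test split yields a
single R per model, the package deliberately does not implement a paired
t-test "across" those single values; comparisons of predictive models
should be run on per-subject squared-error pairs via the same sign-flip
permutation device, and the two accuracies are reported side by side.
Scan-to-examination matching takes the nearest examination within 183 days,
ties to the earlier visit; missing outcomes are excluded per outcome.

## Transcriptome association

From a gene-by-region expression matrix the reference transcription
network is the region-pair Pearson correlation across all $N$ genes.
Leaving one gene out and recomputing gives that gene's specific network,

$$(PC_N - PC_{N-1}) \,/\, \sqrt{(1 - PC_N^2)/(N-1)},$$

with $N$ the full gene count in the denominator (the correlation's sample
size, mirroring the subject-level formula). Note the deliberate sign
convention: *reference minus perturbed*, the mirror image of the
subject-level connectome. A positive edge means the gene's presence raises
that correlation. `gene_network_matrix()` computes all genes at once by
downdating the correlation's sufficient statistics (sums, squares, cross
products), which matches the per-gene brute-force recomputation to
$10^{-12}$ and turns an $O(G^2 R^2)$ loop into $O(G R^2)$.

The susceptibility map is the common logarithm of each edge's contribution
on the expression atlas's region subset; zero contributions are floored one
decade below the smallest positive contribution so the map stays finite.
Susceptibility prediction treats edges as samples and genes as features
(raw strengths, not standardized — the importance extraction is
scale-insensitive for trees), repeatedly splits the edges (500/61 for a
561-edge map), and reports per-repetition train/test Pearson R, a one-sided
sign test of test R against zero, and gain-based per-gene contributions
averaged over repetitions.

Gene sets (GMT, exact identifier match against the gene universe) are
retained when their overlap lies in $[10, 200]$ inclusive — the stated rule
excludes overlaps below 10 or above 200, so the bounds themselves are kept.
A set's fold enrichment is its share of total per-gene contribution divided
by its share of the universe; scores above 2 are enriched, below 0.5
unrelated, and the two modalities combine into tau / amyloid / both /
neither. Per-gene categorization uses the above-average rule; contributions
are normalized to sum to one so "average" and "1/number of genes" coincide.

## The synthetic cohort generator

The generator is first-class, tested code that emulates the statistical
structure the pipeline assumes — not the physiology of any tracer. For
subject $s$, scan at time $t$, region $r$:

$$\mathrm{SUVR} = \mu + \text{covariate effects}
  + (B u_s + a_s)_r + (\gamma_g + \beta_g t)\, h \, d_r + \varepsilon$$

- $B u_s + a_s$ is a subject-stable trait profile: shared low-rank loadings
  $B$ (rank 2, loading SD 0.1) with per-subject scores, plus an
  idiosyncratic loading $a_s$ (SD `subject_loading_sd`). It is constant
  across a subject's scans, supplies the reference group's latent
  covariance ($BB^\top + \sigma_a^2 I + \sigma_\varepsilon^2 I$, exposed by
  `reference_covariance()` and verified against the empirical covariance at
  $n = 2000$), and is what fingerprinting keys on. The identity
  signal-to-noise ratio is `subject_loading_sd / noise_sd`; at SNR 3 and
  $n = 20$ subjects per group, pooled identification is perfect, while
  zeroing every subject-stable term makes subjects exchangeable and drops
  accuracy to the $1/n$ chance level.
- $(\gamma_g + \beta_g t)\, h\, d_r$ is the disease signal: a per-scan
  factor score $h \sim \mathcal N(1, 0.5^2)$ on a region-loading vector $d$
  supported on a random 30% subset of regions, scaled by an ordered group
  grade $\gamma$ (0.6 / 1.2 / 1.8 for CN+/MCI+/AD+; 0 for the reference)
  and drifting at $\beta_g$ per year (0.05 / 0.10 / 0.15). The positive
  factor mean makes affected regions co-elevate — tracer pathology
  accumulates, it does not oscillate — so the group effect lives in the
  edges among affected regions with a consistent direction. The implied
  per-edge weights (outer product of $d$, normalized) are returned as
  `true_edge_weights`, the ground-truth contribution map.
- Covariate effects of age, sex and education enter with region-specific
  weights; cognitive outcomes follow the benchmark covariates plus a
  planted term in the disease severity $(\gamma_g + \beta_g t)$, with 5%
  missingness.

Default sizes are a deliberately scaled-down cohort — reference $N = 100$,
30 patients per group, 20 regions, two scans per patient two years apart —
chosen so that every stage of the pipeline, including the repeated boosting
protocols, runs in seconds to a few minutes on one CPU. The expression
generator is low-rank-plus-noise with an optional planted "driver" gene
whose removal detectably shifts one chosen region pair; the gene-set
generator can plant one set concentrated on the highest-contribution genes.

What passing tests on these cohorts do show: the estimators are correctly
implemented (oracle equivalence to brute force), calibrated under their
nulls (chance-level AUC under permuted labels, uniform permutation
p-values, mean-zero Strength for null subjects), and able to recover
planted structure (discriminative edges, driver genes, slopes,
fingerprints). What they do not show: anything about real tracer kinetics,
real Desikan–Killiany regional means, atlas registration, partial-volume
effects, or the effect sizes of real cohorts — the generator makes no
attempt to mimic those.

## Numerical choices and scaled-down protocol sizes

- Partial correlation via QR residualization; correlations clamped to
  $[-1, 1]$ and symmetrized against floating-point drift.
- Desk-scale boosting protocol used by the test suite and the acceptance
  script: `nrounds = 150`, `early_stopping_rounds = 15`, `nfold = 5`,
  `eta = 0.05` — the same staged procedure at sizes that keep a full run in
  minutes; repetition counts in tests are 2–100 against full-scale defaults
  of 1000, and permutation counts 99–4999 against 10,000.
- Functions that consume seeds preserve the caller's RNG state
  (`withr::local_preserve_seed`), so seeded pipeline stages compose without
  clobbering surrounding simulations; the permutation tests take
  `seed = NULL` by default and then draw from the ambient stream.
- xgboost's CV fold assignment is replaced by in-package class-balanced
  folds (a fold without one class makes multiclass AUC undefined).
- All artifacts are plain text: labeled TSV matrices with JSON provenance
  sidecars, CSV tables, GMT gene sets, YAML configuration.

## Known limitations

- The null spread of Strength is $1/\sqrt{N}$, not 1 (see above); analyses
  comparing cohorts built on reference groups of different sizes should
  rescale accordingly.
- The mixed-model p-values are Satterthwaite approximations; with very few
  subjects the random-slope model often falls back to random intercepts.
- Gain-based importance is one of several defensible "contribution"
  readings; Cover/Frequency are available as a sensitivity check.
- Identifier mapping between gene universes is out of scope: membership is
  exact string match.
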
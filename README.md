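# imconn

Individual molecular connectomes from regional PET SUVR data.

## The problem

Group-level PET studies of Alzheimer's disease describe how tau and amyloid
pathology co-vary across brain regions in a cohort, but say nothing about any
single patient. `imconn` maps a *molecular connectome for one subject* by a
statistical perturbation device: build the region-by-region partial Pearson
correlation matrix over a normative group of N cognitively normal,
amyloid-negative subjects (controlling for age, sex and education), add the
target subject, recompute, and express the change at every region pair in
units of the reference correlation's sampling standard deviation:

```
Strength(i,j) = ( PPC_{N+1}(i,j) - PPC_N(i,j) ) / sqrt( (1 - PPC_N(i,j)^2) / (N - 1) )
```

The resulting edge matrix is the subject's individual connectome. On top of
it the package provides the full downstream analysis suite:

- **Fingerprinting** — identify subjects across timepoints by Pearson
  correlation of upper-triangle edge vectors, within diagnostic group and in
  both directions (`match_identity`, `bidirectional_accuracy`).
- **Edge contributions and the alteration score** — repeated multiclass
  gradient tree boosting (XGBoost; 10-fold CV for the optimal iteration
  count, then training and gain extraction) estimates each connection's
  contribution to discriminating CN/MCI/AD; a scan's alteration is
  `BoxCox( sum_i Strength_i^2 * Contribution_i )`, min-max normalized to
  [0, 1] across the batch (`edge_contributions`, `raw_alteration`,
  `alteration_scores`).
- **Inference** — permutation-calibrated Kruskal–Wallis and one-sided
  rank-sum tests across diagnostic groups, and linear mixed-effects models
  of alteration over time with random intercepts and slopes
  (`group_difference_tests`, `lmm_fit`).
- **Benchmarks** — repeated binary classification with AUC distributions
  and sign tests against chance, volume-weighted composite SUVR baselines,
  permutation-calibrated paired model comparison, and benchmark-plus-feature
  cognitive prediction (`repeated_binary_classification`, `composite_suvr`,
  `model_comparison`, `cognition_prediction`).
- **Transcriptome association** — leave-one-gene-out transcription networks
  from a gene-by-region expression matrix, boosted prediction of the
  per-edge susceptibility map (log10 contribution), and gene-set fold
  enrichment with the 10–200 overlap filter and >2 / <0.5 thresholds
  (`gene_network_matrix`, `susceptibility_prediction`, `fold_enrichment`).
- **Synthetic cohorts** — a generator that emulates the statistical
  structure every stage assumes (latent-factor regional covariance,
  group-graded edge effects, subject-stable fingerprint loadings,
  longitudinal drift, planted cognitive signal), so the entire pipeline is
  exercisable without access-restricted clinical data (`synth_cohort`,
  `synth_expression`, `synth_gene_sets`).

A thin command-line dispatcher over these functions lives in `exec/imconn`
(subcommands `simulate`, `build-connectomes`, `fingerprint`,
`contributions`, `alteration`, `classify`, `group-stats`, `transcriptome`,
`enrich`), reading and writing only plain CSV/TSV/GMT/JSON files.

## Worked example

```r
library(imconn)

cohort <- synth_cohort(cohort_spec(seed = 1))
meta   <- cohort$suvr$meta
normative <- subset_scans(cohort$suvr,
                          meta$diagnosis == "CN" & meta$amyloid_status == "neg")
baseline  <- subset_scans(cohort$suvr,
                          meta$amyloid_status == "pos" & meta$time_years == 0)
cons <- individual_connectomes(normative, cohort$covariates, baseline,
                               c("age", "sex", "education"))
print(cons[[1]])
#> Individual connectome: scan S0101_T00 (subject S0101), 20 regions, N_ref = 100
#> Edge strength range [-0.677, 0.554], mean |strength| 0.079

raw <- vapply(cons, function(x) raw_alteration(x$strength,
                                               cohort$true_edge_weights), 0)
scores <- alteration_scores(raw)
tapply(scores$normalized, meta$diagnosis[meta$amyloid_status == "pos" &
                                         meta$time_years == 0], median)
#>        AD        CN       MCI
#> 0.7334305 0.3717205 0.5767762
```

The per-edge Strength values are z-like: a subject drawn from the normative
distribution barely perturbs the connectome (edge strengths a few percent of
the reference correlation's sampling SD), while disease-graded subjects
perturb the affected edges progressively — the normalized alteration medians
above order CN < MCI < AD.

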
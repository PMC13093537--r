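# Shared fixtures: everything is generated in code at test time.

# Small boosting protocol for tests: same staged CV/train/test procedure,
# scaled down so suites stay fast.
desk_protocol <- function() {
  boost_protocol(nrounds = 150, early_stopping_rounds = 15, nfold = 5)
}

std_covariates <- c("age", "sex", "education")

# Build individual connectomes for a synthetic cohort: normative = CN
# amyloid-negative scans, targets = amyloid-positive scans (baseline only
# unless followup requested).
cohort_connectomes <- function(cohort, timepoint = c("baseline", "followup"),
                               covariate_names = std_covariates) {
  timepoint <- match.arg(timepoint)
  m <- cohort$suvr$meta
  normative <- subset_scans(cohort$suvr,
                            m$diagnosis == "CN" & m$amyloid_status == "neg")
  keep <- m$amyloid_status == "pos" &
    (if (timepoint == "baseline") m$time_years == 0 else m$time_years > 0)
  targets <- subset_scans(cohort$suvr, keep)
  list(connectomes = individual_connectomes(normative, cohort$covariates,
                                            targets, covariate_names),
       labels = m$diagnosis[keep], meta = m[keep, , drop = FALSE],
       normative = normative)
}

# Wrap a symmetric strength matrix as an individual_connectome object.
as_connectome <- function(strength, scan_id = "scan", subject_id = scan_id,
                          n_reference = 100) {
  structure(list(strength = strength, scan_id = scan_id,
                 subject_id = subject_id, n_reference = n_reference,
                 region_order = rownames(strength)),
            class = "individual_connectome")
}

# Connectome cohort in which exactly one edge carries a graded group effect:
# edge vectors are iid standard normal except the planted edge, which is
# shifted by 0 / 1.5 / 3 for CN / MCI / AD.
planted_edge_cohort <- function(seed, n_regions = 12, per_group = 20,
                                planted_edge = 30,
                                shift = c(CN = 0, MCI = 1.5, AD = 3)) {
  set.seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  ne <- n_regions * (n_regions - 1) / 2
  g <- rep(names(shift), each = per_group)
  cons <- lapply(seq_along(g), function(i) {
    v <- stats::rnorm(ne)
    v[planted_edge] <- v[planted_edge] + shift[[g[i]]]
    as_connectome(from_upper_triangle(v, regions), sprintf("s%03d", i))
  })
  list(connectomes = cons, labels = g, planted_edge = planted_edge)
}

# Independent brute-force partial correlation: explicit per-column lm
# residuals, then plain cor. Used as the from-scratch oracle.
brute_partial_cor <- function(values, covar = NULL) {
  res <- apply(values, 2, function(col) {
    if (is.null(covar)) col - mean(col)
    else stats::residuals(stats::lm(col ~ ., data = as.data.frame(covar)))
  })
  stats::cor(res)
}

# Independent brute-force Strength: recompute both correlations from scratch.
brute_strength <- function(ref_values, ref_covar, new_values, new_covar) {
  p0 <- brute_partial_cor(ref_values, ref_covar)
  p1 <- brute_partial_cor(rbind(ref_values, new_values),
                          if (is.null(ref_covar)) NULL
                          else rbind(ref_covar, new_covar))
  s <- (p1 - p0) / sqrt((1 - p0^2) / (nrow(ref_values) - 1))
  diag(s) <- 0
  s
}
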
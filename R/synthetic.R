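#' Specification of a synthetic PET cohort
#'
#' Collects the generative parameters for [synth_cohort()]. The generator
#' emulates the statistical structure the analysis pipeline assumes: a
#' normative reference group with latent-factor regional covariance; patient
#' groups whose disease signal lives in the *co-variation* of a subset of
#' regions (graded CN+ < MCI+ < AD+), so that connectomes rather than
#' regional means carry the group signal; a subject-stable regional loading
#' that makes scans of the same subject recognizably similar (fingerprint
#' identity); per-group longitudinal drift of the disease signal; and
#' covariate effects of age, sex and education. Defaults are a scaled-down
#' cohort (reference n = 100, 30 patients per group, 20 regions, two scans
#' per patient).
#'
#' @param n_regions number of atlas regions.
#' @param n_reference normative (CN amyloid-negative) subjects.
#' @param n_per_group named counts of amyloid-positive patients per
#'   diagnostic group.
#' @param group_grade named disease-signal multipliers, ordered
#'   CN <= MCI <= AD.
#' @param affected_frac fraction of regions carrying the disease loading.
#' @param disease_loading_sd scale of the disease region-loading vector.
#' @param base_rank,base_loading_sd rank and loading scale of the shared
#'   latent covariance.
#' @param subject_loading_sd SD of the subject-stable regional effect
#'   (fingerprint identity strength; SNR = subject_loading_sd / noise_sd).
#' @param disease_factor_mean,disease_factor_sd moments of the per-scan
#'   disease factor score; a positive mean makes the affected regions
#'   co-elevate (tracer accumulation), so the group signal is directional.
#' @param group_slope named per-year drift of the disease-signal magnitude.
#' @param noise_sd scan-level regional noise SD.
#' @param scans_per_subject scans per patient (1 = baseline only).
#' @param follow_dt years between consecutive scans.
#' @param mean_suvr baseline regional mean SUVR.
#' @param covariate_effects list with `age`, `sex`, `education` per-unit
#'   effects on SUVR (applied with region-specific weights).
#' @param cognition_gamma strength of the planted link between disease
#'   severity and the cognitive outcomes.
#' @param missing_rate fraction of cognitive values set missing.
#' @param seed integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 20, n_reference = 100,
                        n_per_group = c(CN = 30, MCI = 30, AD = 30),
                        group_grade = c(CN = 0.6, MCI = 1.2, AD = 1.8),
                        affected_frac = 0.3, disease_loading_sd = 0.15,
                        base_rank = 2, base_loading_sd = 0.1,
                        subject_loading_sd = 0.05,
                        disease_factor_mean = 1, disease_factor_sd = 0.5,
                        group_slope = c(CN = 0.05, MCI = 0.10, AD = 0.15),
                        noise_sd = 0.1, scans_per_subject = 2,
                        follow_dt = 2, mean_suvr = 2,
                        covariate_effects = list(age = 0.002, sex = 0.02,
                                                 education = -0.002),
                        cognition_gamma = 1, missing_rate = 0.05, seed = 1) {
  stopifnot(n_regions >= 3, n_reference >= 5, all(n_per_group >= 1),
            noise_sd >= 0, subject_loading_sd >= 0, scans_per_subject >= 1)
  if (is.unsorted(group_grade[c("CN", "MCI", "AD")])) {
    stop("group grades must be ordered CN <= MCI <= AD")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

## Fixed (seed-derived) cohort-level structure: latent loadings, disease
## pattern, covariate weights.
cohort_structure <- function(spec) {
  set.seed(spec$seed)
  r <- spec$n_regions
  regions <- sprintf("R%02d", seq_len(r))
  base_load <- matrix(stats::rnorm(r * spec$base_rank, 0, spec$base_loading_sd),
                      r, spec$base_rank)
  n_aff <- max(2, round(spec$affected_frac * r))
  affected <- sort(sample(r, n_aff))
  d <- numeric(r)
  d[affected] <- abs(stats::rnorm(n_aff, spec$disease_loading_sd,
                                  spec$disease_loading_sd / 4))
  covw <- matrix(stats::runif(r * 3, 0.5, 1.5), r, 3)
  list(regions = regions, base_load = base_load, disease_load = d,
       affected = affected, cov_weights = covw)
}

#' Reference-group covariance implied by a cohort spec
#'
#' The model covariance of a single reference scan's regional SUVR vector:
#' the subject-stable latent structure (shared low-rank loadings plus the
#' idiosyncratic subject loading) plus scan noise on the diagonal.
#'
#' @param spec a [cohort_spec()].
#' @return n_regions x n_regions covariance matrix.
#' @export
reference_covariance <- function(spec) {
  withr::local_preserve_seed()
  st <- cohort_structure(spec)
  v <- tcrossprod(st$base_load) +
    diag(spec$subject_loading_sd^2 + spec$noise_sd^2, spec$n_regions)
  dimnames(v) <- list(st$regions, st$regions)
  v
}

#' Generate a synthetic PET cohort
#'
#' Draws a [suvr_table()], a covariate table and per-scan cognitive outcomes
#' from a [cohort_spec()]. The generative model for subject s, scan at time
#' t, region r is
#' `SUVR = mean + covariate effects + (B u_s + a_s)_r
#'  + (grade_g + slope_g t) h d_r + noise`,
#' where `B u_s + a_s` is the subject-stable trait profile (shared low-rank
#' loadings `B` with per-subject scores `u_s`, plus an idiosyncratic loading
#' `a_s` with SD `subject_loading_sd`), `h` is a per-scan disease factor
#' score and `d` the disease region-loading vector (zero outside the
#' affected subset). Scan-to-scan variation within a subject is the scan
#' noise plus the disease state, so the fingerprint identity strength is
#' governed by `subject_loading_sd / noise_sd`. Cognitive outcomes follow
#' the benchmark covariates plus a planted term in the disease severity
#' `(grade_g + slope_g t)`. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `synth_cohort`: `suvr` ([suvr_table()] of all scans,
#'   reference and patients), `covariates` (data.frame), `cognition`
#'   (data.frame scan_id/outcome/value), `true_edge_weights` (symmetric
#'   matrix over the affected edges, normalized to sum 1 on the upper
#'   triangle), `spec`.
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_preserve_seed()
  st <- cohort_structure(spec)
  r <- spec$n_regions
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n_pat <- length(groups)
  n_sub <- spec$n_reference + n_pat
  subject_id <- sprintf("S%04d", seq_len(n_sub))
  is_ref <- seq_len(n_sub) <= spec$n_reference
  covariates <- data.frame(
    subject_id = subject_id,
    age = stats::rnorm(n_sub, 72, 6),
    sex = stats::rbinom(n_sub, 1, 0.5),
    education = pmax(8, round(stats::rnorm(n_sub, 16, 2.5))),
    stringsAsFactors = FALSE
  )
  ## subject-stable trait profile: shared low-rank latent scores plus an
  ## idiosyncratic loading; constant across a subject's scans (this is what
  ## fingerprinting keys on, and what gives the reference group its
  ## covariance structure)
  trait <- t(st$base_load %*% matrix(stats::rnorm(spec$base_rank * n_sub),
                                     spec$base_rank, n_sub)) +
    matrix(stats::rnorm(n_sub * r, 0, spec$subject_loading_sd), n_sub, r)
  scan_rows <- list()
  cov_shift <- function(i) {
    st$cov_weights[, 1] * spec$covariate_effects$age * (covariates$age[i] - 72) +
      st$cov_weights[, 2] * spec$covariate_effects$sex * covariates$sex[i] +
      st$cov_weights[, 3] * spec$covariate_effects$education *
        (covariates$education[i] - 16)
  }
  draw_scan <- function(i, t, grade, slope) {
    h <- stats::rnorm(1, spec$disease_factor_mean, spec$disease_factor_sd)
    spec$mean_suvr + cov_shift(i) + trait[i, ] +
      (grade + slope * t) * h * st$disease_load +
      stats::rnorm(r, 0, spec$noise_sd)
  }
  k <- 0L
  add_row <- function(i, t, dx, ab, grade, slope) {
    k <<- k + 1L
    scan_rows[[k]] <<- list(
      scan_id = sprintf("%s_T%02d", subject_id[i], round(t * 10)),
      subject_id = subject_id[i], time_years = t, diagnosis = dx,
      amyloid_status = ab, values = draw_scan(i, t, grade, slope),
      severity = grade + slope * t
    )
  }
  for (i in which(is_ref)) add_row(i, 0, "CN", "neg", 0, 0)
  for (j in seq_len(n_pat)) {
    i <- spec$n_reference + j
    g <- groups[j]
    for (s in seq_len(spec$scans_per_subject)) {
      add_row(i, (s - 1) * spec$follow_dt, g, "pos",
              spec$group_grade[[g]], spec$group_slope[[g]])
    }
  }
  suvr <- do.call(rbind, lapply(scan_rows, `[[`, "values"))
  colnames(suvr) <- st$regions
  tab <- suvr_table(
    vapply(scan_rows, `[[`, "", "scan_id"),
    vapply(scan_rows, `[[`, "", "subject_id"),
    vapply(scan_rows, `[[`, 0, "time_years"),
    vapply(scan_rows, `[[`, "", "diagnosis"),
    vapply(scan_rows, `[[`, "", "amyloid_status"),
    suvr
  )
  severity <- vapply(scan_rows, `[[`, 0, "severity")
  cognition <- synth_cognition(tab, covariates, severity, spec)
  w <- tcrossprod(st$disease_load)
  diag(w) <- 0
  uw <- upper_triangle(w)
  if (sum(uw) > 0) w <- from_upper_triangle(uw / sum(uw), st$regions)
  dimnames(w) <- list(st$regions, st$regions)
  structure(
    list(suvr = tab, covariates = covariates, cognition = cognition,
         true_edge_weights = w, severity = severity, spec = spec),
    class = "synth_cohort"
  )
}

## Planted cognitive outcomes: benchmark covariates + severity term + noise.
synth_cognition <- function(tab, covariates, severity, spec) {
  outcomes <- c("global", "visuospatial", "memory", "attention", "executive")
  coefs <- data.frame(
    outcome = outcomes,
    b0 = c(12, 2, 4, 40, 95),
    b_age = c(0.15, 0.01, 0.05, 0.6, 1.2),
    b_edu = c(-0.3, -0.02, -0.1, -0.8, -2.0),
    b_dx = c(6, 0.6, 2, 12, 35),
    sd = c(4, 0.5, 1.5, 10, 25)
  )
  idx <- match(tab$meta$subject_id, covariates$subject_id)
  dxcode <- match(tab$meta$diagnosis, c("CN", "MCI", "AD")) - 1
  rows <- lapply(seq_len(nrow(coefs)), function(o) {
    cf <- coefs[o, ]
    val <- cf$b0 + cf$b_age * (covariates$age[idx] - 72) +
      cf$b_edu * (covariates$education[idx] - 16) + cf$b_dx * dxcode +
      spec$cognition_gamma * cf$b_dx * severity +
      stats::rnorm(nrow(tab$meta), 0, cf$sd)
    val[stats::runif(nrow(tab$meta)) < spec$missing_rate] <- NA
    data.frame(scan_id = tab$meta$scan_id, outcome = cf$outcome, value = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort\n")
  print(x$suvr)
  invisible(x)
}

#' Generate a synthetic regional expression matrix
#'
#' Low-rank region structure plus gene-level noise:
#' `X = W L + noise_sd * E`, with gene loadings `W` (genes x rank) and region
#' factors `L` (rank x regions). Optionally plants one "driver" gene carrying
#' a large aligned signal on one region pair, so that leaving it out shifts
#' that pair's correlation detectably.
#'
#' @param n_genes,n_regions dimensions.
#' @param rank latent rank (must be <= n_regions).
#' @param noise_sd gene-level noise SD.
#' @param seed integer seed.
#' @param driver optional list `list(edge = c(i, j), magnitude = m)`.
#' @return Genes x regions matrix (rownames `G...`, colnames `R...`), with
#'   attribute `driver`.
#' @export
synth_expression <- function(n_genes, n_regions, rank = 3, noise_sd = 1,
                             seed = 1, driver = NULL) {
  if (rank > n_regions) stop("latent rank cannot exceed n_regions")
  if (n_genes < rank) stop("need n_genes >= rank")
  withr::local_preserve_seed()
  set.seed(seed)
  w <- matrix(stats::rnorm(n_genes * rank), n_genes, rank)
  l <- matrix(stats::rnorm(rank * n_regions), rank, n_regions)
  x <- w %*% l + matrix(stats::rnorm(n_genes * n_regions, 0, noise_sd),
                        n_genes, n_regions)
  rownames(x) <- sprintf("G%05d", seq_len(n_genes))
  colnames(x) <- sprintf("R%02d", seq_len(n_regions))
  if (!is.null(driver)) {
    m <- if (is.null(driver$magnitude)) 6 * stats::sd(x) else driver$magnitude
    x[1, ] <- stats::rnorm(n_regions, 0, noise_sd / 2)
    x[1, driver$edge] <- m
  }
  attr(x, "driver") <- driver
  x
}

#' Generate synthetic gene-set collections
#'
#' Random gene sets drawn from a universe, optionally with one planted set
#' concentrated on the highest-contribution genes (so its fold enrichment
#' exceeds 2 by construction when contributions are heavy-tailed).
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of random sets.
#' @param size_range inclusive bounds on set sizes.
#' @param planted optional named numeric vector of per-gene contributions;
#'   when given, a set `"planted"` of the top-contribution genes is added.
#' @param planted_size size of the planted set.
#' @param seed integer seed.
#' @return Named list of character vectors.
#' @export
synth_gene_sets <- function(universe, n_sets = 50, size_range = c(10, 40),
                            planted = NULL, planted_size = 15, seed = 1) {
  withr::local_preserve_seed()
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, min(k, length(universe))))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(planted)) {
    top <- names(sort(planted, decreasing = TRUE))[seq_len(planted_size)]
    sets$planted <- top
  }
  sets
}

#' Simulate longitudinal alteration records
#'
#' Direct simulator for the mixed-effects layer: subject trajectories
#' `score = intercept + u0 + (beta_time + u1) * time + noise`, with random
#' intercepts `u0` and slopes `u1`.
#'
#' @param n_subjects,n_scans cohort shape.
#' @param beta_time fixed slope (score units per year).
#' @param intercept fixed intercept.
#' @param rint_sd,rslope_sd random intercept/slope SDs.
#' @param resid_sd residual SD.
#' @param dt years between scans.
#' @param group label stored on the records.
#' @param seed integer seed.
#' @return data.frame: subject_id, time, score, group.
#' @export
synth_longitudinal <- function(n_subjects = 60, n_scans = 3, beta_time = 0.10,
                               intercept = 0.3, rint_sd = 0.10,
                               rslope_sd = 0.03, resid_sd = 0.05, dt = 1,
                               group = "CN", seed = 1) {
  withr::local_preserve_seed()
  set.seed(seed)
  u0 <- stats::rnorm(n_subjects, 0, rint_sd)
  u1 <- stats::rnorm(n_subjects, 0, rslope_sd)
  rows <- lapply(seq_len(n_subjects), function(i) {
    t <- (seq_len(n_scans) - 1) * dt
    data.frame(subject_id = sprintf("L%03d_%s", i, group), time = t,
               score = intercept + u0[i] + (beta_time + u1[i]) * t +
                 stats::rnorm(n_scans, 0, resid_sd),
               group = group, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
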
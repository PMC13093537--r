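make_table <- function(values, ids = NULL) {
  n <- nrow(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("R%02d", seq_len(ncol(values)))
  }
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  suvr_table(paste0(ids, "_T0"), ids, rep(0, n), rep("CN", n),
             rep("neg", n), values)
}

test_that("perfect collinearity gives correlation 1 and plain Pearson is recovered without covariates", {
  a <- c(1, 2, 3, 5)
  tab <- make_table(cbind(A = a, B = 2 * a))
  ref <- reference_connectome(tab)
  expect_equal(ref$ppc["A", "B"], 1)
  set.seed(1)
  x <- matrix(runif(6 * 4, 1, 2), 6, 4)
  tab2 <- make_table(x)
  ref2 <- reference_connectome(tab2)
  expect_equal(unname(ref2$ppc), unname(cor(x)), tolerance = 1e-12)
  expect_true(isSymmetric(ref2$ppc))
  expect_equal(unname(diag(ref2$ppc)), rep(1, 4))
})

test_that("partial correlation matches the single-covariate closed form", {
  set.seed(42)
  n <- 5
  x <- matrix(runif(n * 3, 1, 3), n, 3)
  z <- rnorm(n)
  tab <- make_table(x)
  cov <- data.frame(subject_id = tab$meta$subject_id, z = z)
  ref <- reference_connectome(tab, cov, "z")
  r <- cor(cbind(x, z))
  for (i in 1:2) for (j in (i + 1):3) {
    closed <- (r[i, j] - r[i, 4] * r[4, j]) /
      sqrt((1 - r[i, 4]^2) * (1 - r[4, j]^2))
    expect_equal(ref$ppc[i, j], closed, tolerance = 1e-10)
  }
})

test_that("the perturbation statistic reproduces the hand-computed two-region case", {
  # reference A, B uncorrelated (r = 0, N = 4); adding the subject one unit
  # above both means gives the 5-sample Pearson r = 2/7 and
  # Strength = r * sqrt(3) (shifted +1 so SUVR stays positive; Pearson is
  # location-invariant)
  tab <- make_table(cbind(A = c(0, 1, 2, 1) + 1, B = c(1, 0, 1, 2) + 1))
  ref <- reference_connectome(tab)
  expect_equal(ref$ppc["A", "B"], 0, tolerance = 1e-14)
  con <- individual_connectome(tab, NULL, c(A = 3, B = 3),
                               subject_id = "new")
  expect_equal(con$strength["A", "B"], (2 / 7) * sqrt(3), tolerance = 1e-12)
  expect_equal(diag(con$strength), c(A = 0, B = 0))
})

test_that("individual connectomes match a from-scratch brute-force recomputation", {
  set.seed(7)
  n <- 30; r <- 20
  vals <- matrix(runif(n * r, 1, 2), n, r,
                 dimnames = list(NULL, sprintf("R%02d", 1:r)))
  covar <- data.frame(age = rnorm(n, 70, 5), sex = rbinom(n, 1, 0.5),
                      education = rnorm(n, 16, 2))
  tab <- make_table(vals)
  cov_df <- cbind(subject_id = c(tab$meta$subject_id, "NEW"),
                  rbind(covar, data.frame(age = 71, sex = 1, education = 12)))
  new_scan <- setNames(runif(r, 1, 2), colnames(vals))
  con <- individual_connectome(tab, cov_df, new_scan,
                               c("age", "sex", "education"),
                               subject_id = "NEW")
  expected <- brute_strength(vals, covar, new_scan,
                             data.frame(age = 71, sex = 1, education = 12))
  expect_lt(max(abs(con$strength - expected)), 1e-12)
  # and without covariates
  con0 <- individual_connectome(tab, NULL, new_scan, subject_id = "NEW")
  expected0 <- brute_strength(vals, NULL, new_scan, NULL)
  expect_lt(max(abs(con0$strength - expected0)), 1e-12)
})

test_that("degenerate inputs raise informative errors; clipping is opt-in", {
  a <- c(1, 2, 3, 5)
  tab <- make_table(cbind(A = a, B = 2 * a, C = c(2, 1, 3, 2)))
  expect_error(
    individual_connectome(tab, NULL, c(A = 1, B = 2, C = 1.5)),
    "zero denominator"
  )
  expect_message(
    con <- individual_connectome(tab, NULL, c(A = 1, B = 2, C = 1.5),
                                 clip = TRUE),
    "clipping"
  )
  expect_true(all(is.finite(con$strength)))
  tab2 <- make_table(cbind(A = a, B = rep(1.5, 4)))
  expect_error(reference_connectome(tab2), "constant")
  cov <- data.frame(subject_id = tab$meta$subject_id, age = a)
  expect_error(reference_connectome(tab, cov, "apoe"), "missing covariate")
  expect_error(
    individual_connectome(tab, NULL, c(B = 1, A = 2, C = 1)[c("B", "A", "C")]),
    "region order"
  )
})

test_that("adding a pure-noise covariate barely moves the reference correlations", {
  set.seed(11)
  n <- 2000
  x <- matrix(rnorm(n * 6, 5, 0.5), n, 6)
  colnames(x) <- sprintf("R%02d", 1:6)
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  tab <- make_table(x)
  cov <- data.frame(subject_id = tab$meta$subject_id, noise = rnorm(n))
  plain <- reference_connectome(tab)
  adj <- reference_connectome(tab, cov, "noise")
  expect_lt(max(abs(plain$ppc - adj$ppc)), 0.01)
})

test_that("edge vectorization is row-major with the documented lengths and inverse", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[1, 2] <- m[2, 1] <- 1.5; m[1, 3] <- m[3, 1] <- -2; m[2, 3] <- m[3, 2] <- 7
  expect_equal(unname(upper_triangle(m)), c(1.5, -2, 7))
  expect_equal(names(upper_triangle(m)), c("a|b", "a|c", "b|c"))
  expect_length(upper_triangle(diag(34)), 561)
  expect_length(upper_triangle(diag(68)), 2278)
  set.seed(2)
  v <- rnorm(561)
  m2 <- from_upper_triangle(v, sprintf("R%02d", 1:34), diag_value = 0)
  expect_true(isSymmetric(m2))
  expect_equal(unname(upper_triangle(m2)), v)
  expect_error(upper_triangle(matrix(1, 2, 3)), "square")
  expect_error(from_upper_triangle(rnorm(10), letters[1:3]), "does not match")
})

test_that("null perturbations calibrate to mean zero with the formula's 1/sqrt(N) spread", {
  # a subject drawn from the reference distribution leaves the connectome
  # nearly unchanged: Strength averages 0 with SD ~ sqrt((N-1)/(N(N+1)))
  sp <- cohort_spec(n_per_group = c(CN = 1, MCI = 1, AD = 1),
                    group_grade = c(CN = 0, MCI = 0, AD = 0),
                    group_slope = c(CN = 0, MCI = 0, AD = 0),
                    covariate_effects = list(age = 0, sex = 0, education = 0),
                    scans_per_subject = 1, seed = 4)
  co <- synth_cohort(sp)
  m <- co$suvr$meta
  normative <- subset_scans(co$suvr, m$amyloid_status == "neg")
  mu <- colMeans(normative$suvr)
  cl <- chol(reference_covariance(sp))
  set.seed(9)
  vals <- replicate(150, {
    x <- mu + drop(rnorm(length(mu)) %*% cl)
    upper_triangle(individual_connectome(normative, NULL, x,
                                         subject_id = "new"))
  })
  n <- sp$n_reference
  expect_lt(abs(mean(vals)), 0.02)
  expect_equal(sd(vals), sqrt((n - 1) / (n * (n + 1))), tolerance = 0.1)
})
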
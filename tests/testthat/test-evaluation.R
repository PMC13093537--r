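test_that("rank AUC matches the pROC oracle and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(1)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(60) + y
    oracle <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
    expect_equal(rank_auc(s, y), oracle, tolerance = 1e-12)
    expect_equal(rank_auc(exp(s), y), rank_auc(s, y))
    expect_equal(rank_auc(rank(s), y), rank_auc(s, y))
  }
  expect_error(rank_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("a perfectly separable feature classifies at AUC 1 in every repetition", {
  y <- rep(c("CN", "AD"), each = 30)
  x <- ifelse(y == "AD", 5, 1)
  res <- repeated_binary_classification(x, y, per_group_train_n = 15,
                                        n_reps = 5, seed = 1,
                                        protocol = desk_protocol())
  expect_true(all(res$auc_samples == 1))
  expect_lt(res$sign_test_p, 0.05)
})

test_that("permuted labels classify at chance and a d=1 feature approaches the closed-form optimum", {
  set.seed(3)
  n <- 120
  x <- c(rnorm(n / 2), rnorm(n / 2, 1))
  y_true <- rep(c("a", "b"), each = n / 2)
  y_perm <- sample(y_true)
  null_res <- repeated_binary_classification(x, y_perm, per_group_train_n = 30,
                                             n_reps = 10, seed = 2,
                                             protocol = desk_protocol())
  expect_lt(abs(null_res$summary[["median"]] - 0.5), 0.12)
  sig_res <- repeated_binary_classification(x, y_true, per_group_train_n = 30,
                                            n_reps = 10, seed = 2,
                                            protocol = desk_protocol())
  optimal <- pnorm(1 / sqrt(2))  # best attainable AUC at unit-variance gap 1
  expect_lt(sig_res$summary[["median"]], optimal + 0.05)
  expect_gt(sig_res$summary[["median"]], optimal - 0.15)
})

test_that("composite SUVR is the volume-weighted mean, bounded by member values", {
  rs <- list(name = "braak12", regions = c("A", "B"), volumes = c(1, 3))
  expect_equal(composite_suvr(c(A = 1, B = 3, C = 9), rs), 2.5)
  expect_equal(composite_suvr(c(A = 2, B = 2), rs), 2)
  single <- list(name = "s", regions = "B", volumes = 5)
  expect_equal(composite_suvr(c(A = 1, B = 3), single), 3)
  expect_error(composite_suvr(c(A = 1), rs), "missing member")
  set.seed(4)
  scan <- setNames(runif(5, 1, 3), LETTERS[1:5])
  rs2 <- list(name = "r", regions = LETTERS[1:5], volumes = runif(5, 1, 10))
  v <- composite_suvr(scan, rs2)
  expect_true(v >= min(scan) && v <= max(scan))
})

test_that("permutation paired comparison behaves at the extremes and under the null", {
  a <- c(1, 2, 3, 4, 5)
  expect_gte(model_comparison(a, a, n_perm = 99, seed = 1)$p, 0.5)
  set.seed(5)
  b <- rnorm(40)
  big <- b + 1
  expect_equal(model_comparison(big, b, n_perm = 199, seed = 1)$p, 1 / 200)
  expect_error(model_comparison(1:3, 1:4), "length")
  # calibration: under exchangeable pairs the p-value is ~uniform on the
  # add-one permutation grid (checked at several thresholds)
  set.seed(6)
  ps <- replicate(200, {
    d1 <- rnorm(15); d2 <- rnorm(15)
    model_comparison(d1, d2, n_perm = 99)$p
  })
  for (a in c(0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(ps <= a) - a), 3 * sqrt(a * (1 - a) / 200) + 0.01)
  }
  expect_lt(abs(mean(ps) - 0.5), 0.07)
})

test_that("FDR correction reproduces hand-run Benjamini-Hochberg", {
  res <- fdr_correct(c(0.01, 0.02, 0.04), q = 0.05)
  # step-up: 0.04*3/3, min(0.04*.., 0.02*3/2), min(.., 0.01*3/1)
  expect_equal(res$adjusted, c(0.03, 0.03, 0.04))
  expect_true(all(res$reject))
  expect_equal(fdr_correct(0.2)$adjusted, 0.2)
  expect_true(all(fdr_correct(rep(0, 4))$reject))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("scan-to-examination matching takes the nearest exam in the window, earlier on ties", {
  exams <- c(0, 100, 400)
  expect_equal(match_nearest_exam(c(10, 120, 500), exams), c(1L, 2L, 3L))
  expect_equal(match_nearest_exam(50, exams), 1L)  # tie 0 vs 100: earlier
  expect_true(is.na(match_nearest_exam(900, exams)))
  expect_equal(match_nearest_exam(283, exams, window_days = 183), 3L)
  expect_true(is.na(match_nearest_exam(283, exams, window_days = 100)))
})

test_that("cognitive prediction recovers a linear age effect and stays null on noise", {
  set.seed(7)
  n <- 500
  bench <- data.frame(age = rnorm(n, 72, 6), sex = rbinom(n, 1, 0.5),
                      education = rnorm(n, 16, 2),
                      diagnosis = sample(c("CN", "MCI", "AD"), n, TRUE))
  train <- 1:350; test <- 351:n
  lin <- 2 * bench$age + rnorm(n, 0, 0.5)
  res <- cognition_prediction(bench, lin, train, test,
                              protocol = desk_protocol(), seed = 1)
  expect_gt(res$benchmark$r, 0.95)
  noise <- rnorm(n)
  res0 <- cognition_prediction(bench, noise, train, test,
                               protocol = desk_protocol(), seed = 1)
  expect_lt(abs(res0$benchmark$r), 0.1)
  expect_error(cognition_prediction(bench, c(lin[1:355], rep(NA, n - 355)),
                                    train, test), "fewer than 10")
})

test_that("an added feature that drives the outcome improves test-set correlation", {
  better <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 240
    bench <- data.frame(age = rnorm(n, 72, 6), sex = rbinom(n, 1, 0.5),
                        education = rnorm(n, 16, 2),
                        diagnosis = sample(c("CN", "MCI", "AD"), n, TRUE))
    alt <- runif(n)
    outcome <- 0.05 * bench$age + 8 * alt + rnorm(n, 0, 0.5)
    res <- cognition_prediction(bench, outcome, 1:160, 161:n, added = alt,
                                protocol = desk_protocol(), seed = s)
    res$augmented$r > res$benchmark$r
  }, TRUE)
  expect_true(all(better))
})
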
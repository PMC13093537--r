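#' Repeated binary diagnostic classification
#'
#' The repeated split/train/test protocol for a pair of diagnostic groups:
#' per repetition a stratified draw of `per_group_train_n` scans per class
#' forms the training set, the remainder the test set; a binary gradient tree
#' boosting model is fitted under the protocol and its AUC measured on the
#' test set by the rank identity. Reported are all AUC samples, the median and
#' 95% interval, a per-repetition ROC curve, and the one-sided sign test of
#' the AUC samples against the chance level 0.5.
#'
#' @param features numeric matrix (scans x features) or a vector (a single
#'   scalar feature such as an alteration score or composite SUVR).
#' @param labels two-level factor/character vector; the second level sorted
#'   last is taken as the positive class.
#' @param per_group_train_n training scans drawn per class per repetition.
#' @param n_reps repetitions (full-scale default 1000).
#' @param seed base seed; repetition r uses `seed + r`.
#' @param protocol a [boost_protocol()].
#' @param keep_roc keep per-repetition ROC curves (memory; default TRUE).
#' @return Object of class `classification_experiment`: list with `pair`,
#'   `auc_samples`, `summary` (median, lo95, hi95), `sign_test_p`
#'   (one-sided vs 0.5), `roc_curves`, `n_reps`, `per_group_train_n`.
#' @export
repeated_binary_classification <- function(features, labels,
                                           per_group_train_n, n_reps = 1000,
                                           seed = 1,
                                           protocol = boost_protocol(),
                                           keep_roc = TRUE) {
  withr::local_preserve_seed()
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  counts <- table(labels)
  if (any(counts <= per_group_train_n)) {
    stop("class(es) too small for the split: ",
         paste(names(counts)[counts <= per_group_train_n], collapse = ", "))
  }
  y <- as.integer(labels) - 1L
  auc <- numeric(n_reps)
  rocs <- if (keep_roc) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    train <- unlist(lapply(split(seq_along(y), labels),
                           function(i) sample(i, per_group_train_n)))
    test <- setdiff(seq_along(y), train)
    fit <- boost_fit(x[train, , drop = FALSE], y[train],
                     "binary:logistic", protocol)
    p <- boost_predict(fit, x[test, , drop = FALSE])
    auc[r] <- rank_auc(p, y[test])
    if (keep_roc) rocs[[r]] <- roc_points(p, y[test])
  }
  structure(
    list(pair = paste(levels(labels), collapse = " vs "),
         auc_samples = auc,
         summary = c(median = stats::median(auc),
                     lo95 = unname(stats::quantile(auc, 0.025)),
                     hi95 = unname(stats::quantile(auc, 0.975))),
         sign_test_p = sign_test(auc, mu = 0.5, alternative = "greater"),
         roc_curves = rocs, n_reps = n_reps,
         per_group_train_n = per_group_train_n),
    class = "classification_experiment"
  )
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat(sprintf(
    "%s: median AUC %.4f (95%% interval %.4f-%.4f) over %d repetitions\n",
    x$pair, x$summary["median"], x$summary["lo95"], x$summary["hi95"],
    x$n_reps
  ))
  cat(sprintf("One-sided sign test vs 0.5: p = %.3g\n", x$sign_test_p))
  invisible(x)
}

## One-sided sign test of a sample against mu (exact binomial, zeros dropped).
sign_test <- function(x, mu = 0, alternative = "greater") {
  x <- x[x != mu]
  if (!length(x)) return(1)
  stats::binom.test(sum(x > mu), length(x), p = 0.5,
                    alternative = alternative)$p.value
}

#' Volume-weighted composite SUVR
#'
#' The volume-weighted average SUVR of a composite region set:
#' \eqn{\sum_r v_r \cdot SUVR_r / \sum_r v_r}.
#'
#' @param scan named numeric vector of regional SUVR values, or a
#'   [suvr_table()] (then a value per scan is returned).
#' @param region_set list with `name`, `regions` (labels) and `volumes`
#'   (positive weights), as read by [read_region_sets()].
#' @return Scalar (or vector over scans).
#' @export
composite_suvr <- function(scan, region_set) {
  if (is.null(region_set$regions) || is.null(region_set$volumes)) {
    stop("region_set needs 'regions' and 'volumes'")
  }
  if (length(region_set$regions) != length(region_set$volumes)) {
    stop("regions and volumes differ in length")
  }
  if (any(region_set$volumes <= 0)) stop("volumes must be positive")
  w <- region_set$volumes / sum(region_set$volumes)
  if (inherits(scan, "suvr_table")) {
    missing_r <- setdiff(region_set$regions, scan$region_order)
    if (length(missing_r)) {
      stop("missing member region(s): ", paste(missing_r, collapse = ", "))
    }
    return(drop(scan$suvr[, region_set$regions, drop = FALSE] %*% w))
  }
  missing_r <- setdiff(region_set$regions, names(scan))
  if (length(missing_r)) {
    stop("missing member region(s): ", paste(missing_r, collapse = ", "))
  }
  sum(scan[region_set$regions] * w)
}

#' Read composite-region definitions from YAML
#'
#' Expected layout: a top-level list of sets, each with `name`, `regions`
#' (list of atlas labels) and `volumes` (matching positive volumes, mm^3 or
#' relative weights).
#'
#' @param path YAML file.
#' @return Named list of region sets usable with [composite_suvr()].
#' @export
read_region_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s) {
    list(name = s$name, regions = as.character(unlist(s$regions)),
         volumes = as.numeric(unlist(s$volumes)))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Permutation-calibrated one-sided paired comparison
#'
#' One-sided paired t statistic for "a exceeds b", with significance
#' calibrated by random sign flips of the paired differences:
#' p = (1 + #\{permuted t >= observed t\}) / (n_perm + 1).
#'
#' @param metric_a,metric_b equal-length paired performance vectors (e.g.,
#'   AUC across repetitions for two models).
#' @param n_perm number of sign-flip permutations (full-scale default 10000).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   preserved.
#' @return List with `t`, `p`, `n_perm`, `mean_diff`.
#' @export
model_comparison <- function(metric_a, metric_b, n_perm = 10000, seed = NULL) {
  if (length(metric_a) != length(metric_b)) stop("paired vectors differ in length")
  d <- metric_a - metric_b
  tobs <- paired_t(d)
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  n <- length(d)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    if (paired_t(d * flips) >= tobs) exceed <- exceed + 1L
  }
  list(t = tobs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
       mean_diff = mean(d))
}

paired_t <- function(d) {
  s <- stats::sd(d)
  if (s == 0) return(0)
  mean(d) / (s / sqrt(length(d)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with rejection flags at level `q`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and `reject`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Match scans to the nearest cognitive examination
#'
#' For each scan time, finds the nearest examination within the matching
#' window (183 days by default); ties between an earlier and a later
#' examination go to the earlier one. Scans without an examination in the
#' window get `NA`.
#'
#' @param scan_days scan times (days, any common origin).
#' @param exam_days examination times (same origin).
#' @param window_days maximal |scan - exam| allowed (default 183, ~6 months).
#' @return Integer vector: index into `exam_days` per scan, or `NA`.
#' @export
match_nearest_exam <- function(scan_days, exam_days, window_days = 183) {
  vapply(scan_days, function(s) {
    d <- abs(exam_days - s)
    ok <- which(d <= window_days)
    if (!length(ok)) return(NA_integer_)
    best <- ok[d[ok] == min(d[ok])]
    if (length(best) > 1) best <- best[which.min(exam_days[best])]
    as.integer(best[1])
  }, integer(1))
}

#' Benchmark-plus-feature cognitive prediction
#'
#' Trains a gradient-boosted regression of a cognitive outcome on the
#' benchmark features (age, sex, education, and one-hot dementia status) using
#' the baseline scans, evaluates on the follow-up scans, and optionally
#' repeats with one added scalar feature (an alteration score or composite
#' SUVR). Accuracy is the Pearson correlation between predicted and true
#' outcomes on the test set, alongside MSE and MAE. Missing outcome values
#' are excluded per outcome.
#'
#' @param benchmark data.frame of per-scan benchmark covariates: `age`, `sex`,
#'   `education`, `diagnosis` (factor; one-hot encoded internally).
#' @param outcome numeric outcome per scan (NAs allowed).
#' @param train_idx,test_idx row indices of baseline (train) and follow-up
#'   (test) scans.
#' @param added optional numeric per-scan feature to add to the benchmark.
#' @param protocol a [boost_protocol()].
#' @param seed integer seed.
#' @return List with `benchmark` and (when `added` is given) `augmented`,
#'   each holding `r`, `mse`, `mae`, `n_test`, plus `predicted` test values.
#' @export
cognition_prediction <- function(benchmark, outcome, train_idx, test_idx,
                                 added = NULL, protocol = boost_protocol(),
                                 seed = 1) {
  withr::local_preserve_seed()
  x <- benchmark_design(benchmark)
  run <- function(xmat) {
    tr <- intersect(train_idx, which(!is.na(outcome)))
    te <- intersect(test_idx, which(!is.na(outcome)))
    if (length(te) < 10) stop("fewer than 10 non-missing test outcomes")
    set.seed(seed)
    fit <- boost_fit(xmat[tr, , drop = FALSE], outcome[tr],
                     "reg:squarederror", protocol)
    pred <- boost_predict(fit, xmat[te, , drop = FALSE])
    list(r = stats::cor(pred, outcome[te]),
         mse = mean((pred - outcome[te])^2),
         mae = mean(abs(pred - outcome[te])),
         n_test = length(te), predicted = pred)
  }
  out <- list(benchmark = run(x))
  if (!is.null(added)) {
    out$augmented <- run(cbind(x, added = as.numeric(added)))
  }
  out
}

benchmark_design <- function(benchmark) {
  needed <- c("age", "sex", "education", "diagnosis")
  missing_c <- setdiff(needed, names(benchmark))
  if (length(missing_c)) {
    stop("benchmark missing column(s): ", paste(missing_c, collapse = ", "))
  }
  dx <- factor(benchmark$diagnosis)
  onehot <- stats::model.matrix(~ dx - 1)
  colnames(onehot) <- paste0("dx_", levels(dx))
  cbind(age = as.numeric(benchmark$age), sex = as.numeric(benchmark$sex),
        education = as.numeric(benchmark$education), onehot)
}
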
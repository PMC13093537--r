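#' Permutation-calibrated group difference tests
#'
#' Cross-sectional comparison of alteration scores across diagnostic groups:
#' a Kruskal-Wallis omnibus test whose significance is calibrated by
#' permuting group labels, followed by one-sided post hoc Wilcoxon rank-sum
#' tests in the a-priori disease-severity direction (later group > earlier
#' group in `order`), also permutation-calibrated, with Benjamini-Hochberg
#' correction across the post hoc tests. Permutation p-values use the
#' add-one estimator and therefore lie in `[1/(n_perm+1), 1]`.
#'
#' @param scores numeric scores, one per scan/subject.
#' @param groups group label per score.
#' @param n_perm label permutations (full-scale default 10000).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   preserved.
#' @param order group labels from least to most severe; post hoc tests run
#'   for every ordered pair (later > earlier).
#' @return List of class `group_difference_tests`: `H` (Kruskal-Wallis
#'   statistic), `df`, `p_perm`, `p_classical`, and `pairwise` (data.frame:
#'   pair, statistic, p_perm, p_adj).
#' @export
group_difference_tests <- function(scores, groups, n_perm = 10000,
                                   seed = NULL,
                                   order = c("CN", "MCI", "AD")) {
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(seed)
  }
  groups <- as.character(groups)
  present <- order[order %in% unique(groups)]
  if (length(present) < 2) stop("need at least 2 groups")
  counts <- table(groups)
  if (any(counts < 3)) {
    stop("group(s) with fewer than 3 members: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  g <- factor(groups, levels = present)
  kw <- stats::kruskal.test(scores, g)
  hobs <- kw$statistic
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    hb <- stats::kruskal.test(scores, sample(g))$statistic
    if (hb >= hobs) exceed <- exceed + 1L
  }
  pairs <- utils::combn(present, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    hi <- scores[g == pr[2]]; lo <- scores[g == pr[1]]
    wobs <- stats::wilcox.test(hi, lo, alternative = "greater",
                               exact = FALSE)$statistic
    pooled <- c(hi, lo)
    nh <- length(hi)
    ex <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample(length(pooled), nh)
      wb <- stats::wilcox.test(pooled[idx], pooled[-idx],
                               alternative = "greater",
                               exact = FALSE)$statistic
      if (wb >= wobs) ex <- ex + 1L
    }
    data.frame(pair = paste(pr[2], ">", pr[1]), statistic = unname(wobs),
               p_perm = (1 + ex) / (n_perm + 1), stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- stats::p.adjust(pw$p_perm, method = "BH")
  structure(
    list(H = unname(hobs), df = unname(kw$parameter),
         p_perm = (1 + exceed) / (n_perm + 1),
         p_classical = kw$p.value, pairwise = pw, n_perm = n_perm),
    class = "group_difference_tests"
  )
}

#' @export
print.group_difference_tests <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f (df = %d), permutation p = %.4g\n",
              x$H, x$df, x$p_perm))
  cat("Post hoc one-sided rank-sum tests (BH-corrected):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Longitudinal mixed-effects model of alteration scores
#'
#' Models alteration over time since the first scan with subject-specific
#' random intercepts and slopes. Within-group form:
#' `score ~ time + (time | subject)`; across groups (`interaction = TRUE`):
#' `score ~ group * time + (time | subject)`, reporting the group x time
#' interaction. Estimation is by REML; fixed-effect p-values use the
#' Satterthwaite approximation. When the random-slope fit is singular or
#' fails to converge (e.g., no within-subject time variation), the model
#' falls back to random intercepts only and flags it.
#'
#' @param records data.frame with columns `subject_id`, `time` (years since
#'   first scan), `score`, and (for `interaction = TRUE`) `group`.
#' @param interaction fit the across-group model with group and group x time.
#' @param group_order factor order for `group` (first level = reference).
#' @param conf_grid number of time points for the fitted line and its 95%
#'   band (fixed-effects band).
#' @return Object of class `lmm_fit`: list with `model` (lmerMod), `slopes`
#'   (data.frame: term, estimate, se, df, p), `singular_fallback`, `fitted`
#'   (data.frame: time[, group], fit, lo, hi).
#' @export
lmm_fit <- function(records, interaction = FALSE,
                    group_order = c("CN", "MCI", "AD"), conf_grid = 50) {
  needed <- c("subject_id", "time", "score", if (interaction) "group")
  missing_c <- setdiff(needed, names(records))
  if (length(missing_c)) {
    stop("records missing column(s): ", paste(missing_c, collapse = ", "))
  }
  if (any(records$time < 0)) stop("time must be >= 0")
  if (interaction) {
    records$group <- factor(records$group,
                            levels = group_order[group_order %in% records$group])
  }
  form <- if (interaction) {
    score ~ group * time + (time | subject_id)
  } else {
    score ~ time + (time | subject_id)
  }
  fallback <- FALSE
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = records, REML = TRUE)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    fallback <- TRUE
    form2 <- if (interaction) {
      score ~ group * time + (1 | subject_id)
    } else {
      score ~ time + (1 | subject_id)
    }
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(form2, data = records, REML = TRUE)
    ))
  }
  coefs <- as.data.frame(summary(fit)$coefficients)
  names(coefs) <- c("estimate", "se", "df", "t", "p")
  slopes <- cbind(term = rownames(coefs), coefs[, c("estimate", "se", "df", "p")])
  rownames(slopes) <- NULL
  keep <- grepl("time", slopes$term)
  fitted <- lmm_fixed_band(fit, records, interaction, conf_grid)
  structure(
    list(model = fit, slopes = slopes[keep | slopes$term == "(Intercept)", ],
         all_terms = slopes, singular_fallback = fallback, fitted = fitted,
         interaction = interaction),
    class = "lmm_fit"
  )
}

## Fixed-effect fitted line and 95% band over a time grid (per group when the
## interaction model was fitted).
lmm_fixed_band <- function(fit, records, interaction, conf_grid) {
  tgrid <- seq(min(records$time), max(records$time), length.out = conf_grid)
  newdata <- if (interaction) {
    expand.grid(time = tgrid, group = levels(records$group))
  } else {
    data.frame(time = tgrid)
  }
  tt <- stats::terms(fit)
  x <- stats::model.matrix(stats::delete.response(tt), newdata)
  beta <- lme4::fixef(fit)
  x <- x[, names(beta), drop = FALSE]
  pred <- drop(x %*% beta)
  se <- sqrt(rowSums((x %*% as.matrix(stats::vcov(fit))) * x))
  cbind(newdata, fit = pred, lo = pred - 1.96 * se, hi = pred + 1.96 * se)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed-effects model (%s%s)\n",
              if (x$interaction) "group * time" else "time only",
              if (x$singular_fallback) "; random-intercept fallback" else ""))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}
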
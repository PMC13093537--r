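#' Per-edge contributions to diagnostic discrimination
#'
#' Estimates each connection's aggregate contribution to discriminating the
#' three diagnostic groups. Per repetition, a balanced subsample
#' (`per_group_n` connectomes per class) is drawn, a multiclass gradient tree
#' boosting model is fitted under the standard protocol, and the per-edge
#' importance (gain by default) is extracted and normalized to sum to 1 over
#' the upper triangle (edges never split on get 0). Contributions are averaged
#' over repetitions and renormalized. Repetition r uses deterministic seed
#' `seed + r`, so long runs are reproducible and extensible.
#'
#' @param connectomes list of `individual_connectome` objects.
#' @param labels factor/character diagnosis per connectome
#'   (levels `CN`, `MCI`, `AD`).
#' @param n_reps number of subsampling repetitions (full-scale default 1000;
#'   pass less for desk-scale runs).
#' @param per_group_n training connectomes drawn per class each repetition.
#' @param seed base integer seed.
#' @param protocol a [boost_protocol()].
#' @param importance importance type: `"Gain"` (default), `"Cover"` or
#'   `"Frequency"`.
#' @return Object of class `contribution_matrix`: list with `contribution`
#'   (symmetric region x region matrix, non-negative, upper triangle summing
#'   to 1), `n_repetitions`, `model_spec`, `region_order`.
#' @export
edge_contributions <- function(connectomes, labels, n_reps = 1000,
                               per_group_n = 100, seed = 1,
                               protocol = boost_protocol(),
                               importance = "Gain") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  withr::local_preserve_seed()
  labels <- factor(as.character(labels), levels = c("CN", "MCI", "AD"))
  labels <- droplevels(labels)
  counts <- table(labels)
  if (any(counts < per_group_n)) {
    stop("class(es) smaller than per_group_n: ",
         paste(names(counts)[counts < per_group_n], collapse = ", "))
  }
  x <- edge_matrix(connectomes)
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("non-finite edge values")
  y <- as.integer(labels) - 1L
  acc <- numeric(ncol(x))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx <- unlist(lapply(split(seq_along(y), labels),
                         function(i) sample(i, per_group_n)))
    fit <- boost_fit(x[idx, , drop = FALSE], y[idx], "multi:softprob",
                     protocol, num_class = nlevels(labels))
    acc <- acc + boost_importance(fit, colnames(x), importance)
  }
  contrib <- acc / n_reps
  if (sum(contrib) > 0) contrib <- contrib / sum(contrib)
  regions <- connectomes[[1]]$region_order
  structure(
    list(contribution = from_upper_triangle(contrib, regions),
         n_repetitions = n_reps,
         model_spec = c(protocol[c("nrounds", "early_stopping_rounds",
                                   "nfold", "eta")],
                        list(importance = importance,
                             per_group_n = per_group_n, seed = seed)),
         region_order = regions),
    class = "contribution_matrix"
  )
}

#' @export
print.contribution_matrix <- function(x, ...) {
  v <- upper_triangle(x$contribution)
  cat(sprintf(
    "Contribution matrix: %d regions (%d edges), %d repetitions\n",
    length(x$region_order), length(v), x$n_repetitions
  ))
  cat(sprintf("Top edge carries %.2f%% of total contribution; %d edges at 0\n",
              100 * max(v), sum(v == 0)))
  invisible(x)
}

#' Raw connectome alteration
#'
#' The unweighted alteration of one individual connectome: the sum over
#' upper-triangle edges of squared strength times that edge's contribution to
#' diagnostic discrimination.
#'
#' @param connectome an `individual_connectome` (or a symmetric strength
#'   matrix).
#' @param contributions a `contribution_matrix` from [edge_contributions()]
#'   (or a symmetric matrix of edge weights).
#' @return Non-negative scalar.
#' @export
raw_alteration <- function(connectome, contributions) {
  s <- if (inherits(connectome, "individual_connectome")) {
    connectome$strength
  } else {
    as.matrix(connectome)
  }
  w <- if (inherits(contributions, "contribution_matrix")) {
    contributions$contribution
  } else {
    as.matrix(contributions)
  }
  if (!identical(dim(s), dim(w))) stop("strength/contribution shape mismatch")
  if (inherits(connectome, "individual_connectome") &&
      inherits(contributions, "contribution_matrix") &&
      !identical(connectome$region_order, contributions$region_order)) {
    stop("region order mismatch between connectome and contributions")
  }
  sum(upper_triangle(s)^2 * upper_triangle(w))
}

## Box-Cox profile log-likelihood for a positive sample at exponent lambda
## (one-sample model: transformed values ~ N(mu, sigma^2)).
boxcox_loglik <- function(y, lambda) {
  n <- length(y)
  z <- boxcox_transform(y, lambda)
  -n / 2 * log(sum((z - mean(z))^2) / n) + (lambda - 1) * sum(log(y))
}

#' Box-Cox transform and maximum-likelihood exponent
#'
#' `boxcox_lambda()` fits the exponent by one-dimensional profile maximum
#' likelihood on a positive batch; `boxcox_transform()` applies
#' \eqn{(y^\lambda - 1)/\lambda} (natural log at \eqn{\lambda = 0}).
#'
#' @param y positive numeric vector.
#' @param lambda Box-Cox exponent.
#' @param interval search interval for the exponent.
#' @return `boxcox_lambda()`: scalar lambda; `boxcox_transform()`: transformed
#'   vector.
#' @export
boxcox_lambda <- function(y, interval = c(-5, 5)) {
  if (any(y <= 0)) stop("Box-Cox requires positive values")
  if (length(y) < 3) stop("need at least 3 values to fit lambda")
  stats::optimize(function(l) boxcox_loglik(y, l), interval,
                  maximum = TRUE)$maximum
}

#' @rdname boxcox_lambda
#' @export
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Alteration scores for a batch of scans
#'
#' Turns raw alterations (from [raw_alteration()]) into the reported score:
#' a single Box-Cox exponent is fitted by profile maximum likelihood across
#' the batch (toward normality), and the transformed values are min-max
#' normalized to `[0, 1]` over the batch. Both transforms are monotone, so the
#' rank order of raw values is preserved. Raw values of exactly 0 (a null
#' subject) are offset by half the smallest positive raw value in the batch
#' before the Box-Cox step; the offset used is recorded on the result.
#'
#' @param raw_values non-negative numeric vector, one per scan (length >= 3).
#' @param scan_id optional identifiers.
#' @return A data.frame of class `alteration_scores` with columns `scan_id`,
#'   `raw`, `transformed`, `normalized`, and attributes `lambda` and `offset`.
#' @export
alteration_scores <- function(raw_values, scan_id = NULL) {
  if (length(raw_values) < 3) stop("batch size must be >= 3")
  if (any(raw_values < 0)) stop("raw alterations must be >= 0")
  if (max(raw_values) == min(raw_values)) {
    stop("zero range: all raw alterations equal, cannot normalize")
  }
  offset <- 0
  y <- raw_values
  if (any(y == 0)) {
    offset <- min(y[y > 0]) / 2
    y <- y + offset
  }
  lambda <- boxcox_lambda(y)
  z <- boxcox_transform(y, lambda)
  norm <- (z - min(z)) / (max(z) - min(z))
  out <- data.frame(
    scan_id = if (is.null(scan_id)) seq_along(raw_values) else scan_id,
    raw = raw_values, transformed = z, normalized = norm,
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- lambda
  attr(out, "offset") <- offset
  class(out) <- c("alteration_scores", "data.frame")
  out
}

#' @export
print.alteration_scores <- function(x, ...) {
  cat(sprintf("Alteration scores: %d scans, lambda = %.3f%s\n",
              nrow(x), attr(x, "lambda"),
              if (attr(x, "offset") > 0)
                sprintf(" (zero-offset %.3g)", attr(x, "offset")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
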
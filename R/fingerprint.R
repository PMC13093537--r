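#' Identify subjects by connectome correlation
#'
#' Connectome fingerprinting: for each query connectome, the best-matching
#' candidate is the one whose upper-triangle edge vector has the highest
#' Pearson correlation with the query's. An identification succeeds when the
#' best match carries the same subject identity. Ties in the argmax (measure
#' zero for continuous data) are broken by the smallest candidate index and
#' reported via a message.
#'
#' @param queries list of `individual_connectome` objects (one per subject).
#' @param candidates list of `individual_connectome` objects containing every
#'   query subject exactly once.
#' @param direction label stored on the result (e.g. `"baseline->followup"`).
#' @return Object of class `identification_result`: list with `matches`
#'   (data.frame: query_scan, query_subject, match_scan, match_subject,
#'   correlation, success), `n_success`, `n_total`, `accuracy`, `direction`.
#' @export
match_identity <- function(queries, candidates,
                           direction = "baseline->followup") {
  qmat <- edge_matrix(queries)
  cmat <- edge_matrix(candidates)
  if (ncol(qmat) != ncol(cmat)) {
    stop("query and candidate connectomes have different region sets")
  }
  csub <- vapply(candidates, function(x) x$subject_id, "")
  qsub <- vapply(queries, function(x) x$subject_id, "")
  if (anyDuplicated(csub)) stop("candidate set repeats a subject")
  if (!all(qsub %in% csub)) {
    stop("candidate set missing query subject(s): ",
         paste(setdiff(qsub, csub), collapse = ", "))
  }
  sds_q <- apply(qmat, 1, stats::sd)
  sds_c <- apply(cmat, 1, stats::sd)
  if (any(sds_q == 0) || any(sds_c == 0)) {
    stop("undefined correlation: constant edge vector in ",
         paste(c(
           vapply(queries[sds_q == 0], function(x) x$scan_id, ""),
           vapply(candidates[sds_c == 0], function(x) x$scan_id, "")
         ), collapse = ", "))
  }
  rmat <- stats::cor(t(qmat), t(cmat))
  best <- apply(rmat, 1, function(row) {
    top <- which(row == max(row))
    if (length(top) > 1) message("tie in best match; keeping smallest index")
    top[1]
  })
  matches <- data.frame(
    query_scan = vapply(queries, function(x) x$scan_id, ""),
    query_subject = qsub,
    match_scan = vapply(candidates[best], function(x) x$scan_id, ""),
    match_subject = csub[best],
    correlation = rmat[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE
  )
  matches$success <- matches$query_subject == matches$match_subject
  structure(
    list(matches = matches, n_success = sum(matches$success),
         n_total = nrow(matches),
         accuracy = sum(matches$success) / nrow(matches),
         direction = direction),
    class = "identification_result"
  )
}

edge_matrix <- function(connectomes) {
  stopifnot(length(connectomes) >= 1)
  t(vapply(connectomes, upper_triangle,
           numeric(length(upper_triangle(connectomes[[1]])))))
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("Identification (%s): %d/%d correct, accuracy %.3f\n",
              x$direction, x$n_success, x$n_total, x$accuracy))
  invisible(x)
}

#' Bidirectional fingerprinting accuracy
#'
#' Runs [match_identity()] from baseline to follow-up and in the reversed
#' direction, and pools: accuracy = total successes / (2n).
#'
#' @param baseline,followup lists of `individual_connectome`, one per subject,
#'   the same subjects in both.
#' @return List with `forward`, `reverse` (identification_result) and
#'   `pooled_accuracy`.
#' @export
bidirectional_accuracy <- function(baseline, followup) {
  fwd <- match_identity(baseline, followup, "baseline->followup")
  rev <- match_identity(followup, baseline, "followup->baseline")
  structure(
    list(forward = fwd, reverse = rev,
         pooled_accuracy = (fwd$n_success + rev$n_success) /
           (fwd$n_total + rev$n_total)),
    class = "fingerprint_result"
  )
}

#' @export
print.fingerprint_result <- function(x, ...) {
  print(x$forward); print(x$reverse)
  cat(sprintf("Pooled accuracy: %.3f\n", x$pooled_accuracy))
  invisible(x)
}

#' Within-group fingerprinting
#'
#' Splits baseline and follow-up connectomes by a grouping label (typically the
#' diagnostic group, mirroring within-group identification) and computes the
#' bidirectional accuracy inside each group. Subjects with more than one
#' follow-up should be reduced to their first follow-up scan upstream.
#'
#' @param baseline,followup lists of `individual_connectome`.
#' @param groups named character vector mapping subject_id to group label.
#' @return Named list of [bidirectional_accuracy()] results, one per group,
#'   plus an `overall` pooled accuracy across groups.
#' @export
fingerprint_by_group <- function(baseline, followup, groups) {
  bsub <- vapply(baseline, function(x) x$subject_id, "")
  fsub <- vapply(followup, function(x) x$subject_id, "")
  res <- lapply(split(seq_along(baseline), groups[bsub]), function(bi) {
    fi <- which(fsub %in% bsub[bi])
    bidirectional_accuracy(baseline[bi], followup[fi])
  })
  succ <- sum(vapply(res, function(r) r$forward$n_success + r$reverse$n_success, 0))
  tot <- sum(vapply(res, function(r) r$forward$n_total + r$reverse$n_total, 0))
  c(res, list(overall = succ / tot))
}
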
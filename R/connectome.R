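#' SUVR scan table
#'
#' Container for regional PET standardized uptake value ratios (SUVR), one row
#' per scan, together with the scan-level metadata every downstream stage needs
#' (subject identity, time since the subject's first scan, diagnostic group,
#' amyloid status). The region ordering of the `suvr` matrix is frozen at
#' construction and carried into every derived artifact; mismatched orderings
#' are an error downstream, never silently realigned.
#'
#' @param scan_id character vector of unique scan identifiers.
#' @param subject_id character vector of subject identifiers (repeated across
#'   a subject's scans).
#' @param time_years numeric, years since the subject's first scan (>= 0).
#' @param diagnosis factor/character in `c("CN", "MCI", "AD")`.
#' @param amyloid_status factor/character in `c("neg", "pos")`.
#' @param suvr numeric matrix, scans x regions, column names = region labels.
#' @return An object of class `suvr_table`: a list with elements `meta`
#'   (data.frame) and `suvr` (matrix), plus `region_order`.
#' @export
suvr_table <- function(scan_id, subject_id, time_years, diagnosis,
                       amyloid_status, suvr) {
  suvr <- as.matrix(suvr)
  if (is.null(colnames(suvr))) {
    stop("suvr matrix must carry region labels as column names")
  }
  n <- length(scan_id)
  if (nrow(suvr) != n) stop("suvr must have one row per scan")
  if (anyDuplicated(scan_id)) {
    stop("duplicate scan_id: ", paste(unique(scan_id[duplicated(scan_id)]),
                                      collapse = ", "))
  }
  if (any(!is.finite(suvr))) stop("missing or non-finite SUVR values")
  if (any(suvr <= 0)) stop("SUVR values must be positive")
  if (any(time_years < 0)) stop("time_years must be >= 0")
  diagnosis <- as.character(diagnosis)
  amyloid_status <- as.character(amyloid_status)
  bad <- setdiff(unique(diagnosis), c("CN", "MCI", "AD"))
  if (length(bad)) stop("unknown diagnosis level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(amyloid_status), c("neg", "pos"))
  if (length(bad)) stop("unknown amyloid_status level(s): ", paste(bad, collapse = ", "))
  meta <- data.frame(
    scan_id = as.character(scan_id),
    subject_id = as.character(subject_id),
    time_years = as.numeric(time_years),
    diagnosis = diagnosis,
    amyloid_status = amyloid_status,
    stringsAsFactors = FALSE
  )
  rownames(suvr) <- meta$scan_id
  structure(
    list(meta = meta, suvr = suvr, region_order = colnames(suvr)),
    class = "suvr_table"
  )
}

#' @export
print.suvr_table <- function(x, ...) {
  cat(sprintf(
    "SUVR table: %d scans, %d subjects, %d regions\n",
    nrow(x$meta), length(unique(x$meta$subject_id)), length(x$region_order)
  ))
  tab <- table(x$meta$diagnosis, x$meta$amyloid_status)
  print(tab)
  invisible(x)
}

#' Subset the scans of a SUVR table
#'
#' @param x a `suvr_table`.
#' @param i logical or integer index over scans (rows).
#' @param ... unused.
#' @return A `suvr_table` with the selected scans.
#' @export
subset_scans <- function(x, i, ...) {
  stopifnot(inherits(x, "suvr_table"))
  suvr_table(x$meta$scan_id[i], x$meta$subject_id[i], x$meta$time_years[i],
             x$meta$diagnosis[i], x$meta$amyloid_status[i],
             x$suvr[i, , drop = FALSE])
}

## Residualize columns of y on [1, covariate matrix]; returns residual matrix.
residualize <- function(y, z) {
  x <- cbind(`(Intercept)` = 1, z)
  qr.resid(qr(x), y)
}

## Partial Pearson correlation of the columns of `values`, controlling for
## the columns of `covar` (NULL => plain Pearson).
partial_cor <- function(values, covar = NULL) {
  res <- if (is.null(covar) || ncol(as.matrix(covar)) == 0) {
    scale(values, scale = FALSE)
  } else {
    residualize(values, as.matrix(covar))
  }
  sds <- apply(res, 2, stats::sd)
  if (any(sds <= .Machine$double.eps^0.5 * max(sds, 1))) {
    bad <- colnames(values)[sds <= .Machine$double.eps^0.5 * max(sds, 1)]
    stop("degenerate correlation: region(s) constant after residualization: ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(res)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

## Extract and order the covariate rows for the given subjects; errors on
## missing subjects or missing values among the used covariates.
covariate_rows <- function(covariates, subject_id, covariate_names) {
  if (length(covariate_names) == 0) {
    return(NULL)
  }
  if (!is.data.frame(covariates) || is.null(covariates$subject_id)) {
    stop("covariates must be a data.frame with a subject_id column")
  }
  missing_cov <- setdiff(covariate_names, names(covariates))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  }
  idx <- match(subject_id, covariates$subject_id)
  if (anyNA(idx)) {
    stop("covariates missing for subject(s): ",
         paste(unique(subject_id[is.na(idx)]), collapse = ", "))
  }
  z <- as.matrix(covariates[idx, covariate_names, drop = FALSE])
  storage.mode(z) <- "double"
  if (anyNA(z)) stop("missing values among used covariates")
  z
}

#' Reference molecular connectome
#'
#' Builds the normative partial-correlation connectome over a reference group
#' (typically cognitively normal, amyloid-negative subjects): the partial
#' Pearson correlation between the SUVR values of every pair of regions,
#' controlling for the named subject-level covariates (default age, sex and
#' education). With an empty covariate list this is the plain Pearson
#' correlation matrix.
#'
#' @param normative a [suvr_table()] with one scan per subject.
#' @param covariates data.frame keyed by `subject_id` holding covariate columns.
#' @param covariate_names character vector of covariate columns to control for.
#' @return An object of class `reference_connectome`: list with `ppc`
#'   (symmetric region x region matrix, unit diagonal), `n_reference`,
#'   `covariate_spec`, `region_order`.
#' @export
reference_connectome <- function(normative, covariates = NULL,
                                 covariate_names = character(0)) {
  stopifnot(inherits(normative, "suvr_table"))
  if (anyDuplicated(normative$meta$subject_id)) {
    stop("reference group must contain one scan per subject")
  }
  n <- nrow(normative$suvr)
  if (n < length(covariate_names) + 3) {
    stop("reference group too small: need at least ",
         length(covariate_names) + 3, " subjects")
  }
  z <- covariate_rows(covariates, normative$meta$subject_id, covariate_names)
  ppc <- partial_cor(normative$suvr, z)
  structure(
    list(ppc = ppc, n_reference = n,
         covariate_spec = as.character(covariate_names),
         region_order = normative$region_order),
    class = "reference_connectome"
  )
}

#' @export
print.reference_connectome <- function(x, ...) {
  cat(sprintf(
    "Reference connectome: %d regions, N = %d reference subjects\n",
    length(x$region_order), x$n_reference
  ))
  cat("Covariates: ",
      if (length(x$covariate_spec)) paste(x$covariate_spec, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Individual molecular connectome of one scan
#'
#' Adds a single target scan to the normative group, recomputes the partial
#' Pearson correlation over the N+1 subjects (the perturbed connectome), and
#' expresses the change at every edge in units of the reference correlation's
#' sampling standard deviation:
#' \deqn{Strength(i,j) = \frac{PPC_{N+1}(i,j) - PPC_N(i,j)}
#'   {\sqrt{(1 - PPC_N(i,j)^2)/(N-1)}}}
#' where N is the reference group size. The covariate regression is refit on
#' the N+1 sample. The sign of an edge indicates the direction in which the
#' perturbed correlation deviates from the reference one, not a rise or fall
#' of the subject's own regional signal.
#'
#' @param normative reference-group [suvr_table()] (one scan per subject).
#' @param covariates covariate data.frame keyed by `subject_id`, covering the
#'   reference subjects and the target subject.
#' @param new_scan named numeric vector of SUVR values for the target scan, in
#'   the reference region order.
#' @param covariate_names covariates to control for.
#' @param scan_id,subject_id identifiers recorded on the result.
#' @param clip if `TRUE`, reference edges with |r| = 1 are clipped to
#'   1 - 1e-12 instead of raising (intended for degenerate synthetic inputs);
#'   a message is emitted when clipping fires.
#' @return Object of class `individual_connectome`: list with `strength`
#'   (symmetric matrix, zero diagonal), `scan_id`, `subject_id`,
#'   `n_reference`, `region_order`.
#' @export
individual_connectome <- function(normative, covariates = NULL, new_scan,
                                  covariate_names = character(0),
                                  scan_id = "scan", subject_id = "subject",
                                  clip = FALSE) {
  ref <- reference_connectome(normative, covariates, covariate_names)
  perturbed_strength(ref, normative, covariates, new_scan, covariate_names,
                     scan_id, subject_id, clip)
}

## Shared worker: computes the perturbed connectome for one added scan and the
## Strength matrix against a prebuilt reference.
perturbed_strength <- function(ref, normative, covariates, new_scan,
                               covariate_names, scan_id, subject_id, clip) {
  if (is.null(names(new_scan))) {
    if (length(new_scan) != length(ref$region_order)) {
      stop("new_scan length does not match reference region count")
    }
    names(new_scan) <- ref$region_order
  }
  if (!identical(names(new_scan), ref$region_order)) {
    stop("new_scan region order does not match the reference region order")
  }
  ppc0 <- ref$ppc
  n <- ref$n_reference
  off <- upper.tri(ppc0)
  at_one <- abs(ppc0[off]) >= 1 - .Machine$double.eps * 4
  if (any(at_one)) {
    if (!clip) {
      stop("zero denominator: |reference correlation| = 1 at ",
           sum(at_one), " edge(s); set clip = TRUE to clip")
    }
    message("clipping ", sum(at_one), " reference edge(s) with |r| = 1")
    ppc0[abs(ppc0) >= 1 - 1e-12 & row(ppc0) != col(ppc0)] <-
      sign(ppc0[abs(ppc0) >= 1 - 1e-12 & row(ppc0) != col(ppc0)]) * (1 - 1e-12)
  }
  values1 <- rbind(normative$suvr, new_scan)
  z1 <- covariate_rows(covariates,
                       c(normative$meta$subject_id, subject_id),
                       covariate_names)
  ppc1 <- partial_cor(values1, z1)
  strength <- (ppc1 - ppc0) / sqrt((1 - ppc0^2) / (n - 1))
  diag(strength) <- 0
  strength <- (strength + t(strength)) / 2
  structure(
    list(strength = strength, scan_id = scan_id, subject_id = subject_id,
         n_reference = n, region_order = ref$region_order),
    class = "individual_connectome"
  )
}

#' Individual connectomes for every scan of a target table
#'
#' Convenience wrapper computing [individual_connectome()] for each scan in
#' `targets` against the same normative group. The reference connectome and
#' its covariate design are built once.
#'
#' @inheritParams individual_connectome
#' @param targets a [suvr_table()] of target scans (e.g., all amyloid-positive
#'   scans).
#' @return List of `individual_connectome` objects, named by scan_id.
#' @export
individual_connectomes <- function(normative, covariates = NULL, targets,
                                   covariate_names = character(0),
                                   clip = FALSE) {
  stopifnot(inherits(targets, "suvr_table"))
  if (!identical(targets$region_order, normative$region_order)) {
    stop("target region order does not match the normative region order")
  }
  ref <- reference_connectome(normative, covariates, covariate_names)
  out <- lapply(seq_len(nrow(targets$meta)), function(i) {
    perturbed_strength(ref, normative, covariates,
                       targets$suvr[i, ], covariate_names,
                       scan_id = targets$meta$scan_id[i],
                       subject_id = targets$meta$subject_id[i],
                       clip = clip)
  })
  names(out) <- targets$meta$scan_id
  out
}

#' @export
print.individual_connectome <- function(x, ...) {
  s <- upper_triangle(x$strength)
  cat(sprintf(
    "Individual connectome: scan %s (subject %s), %d regions, N_ref = %d\n",
    x$scan_id, x$subject_id, length(x$region_order), x$n_reference
  ))
  cat(sprintf("Edge strength range [%.3f, %.3f], mean |strength| %.3f\n",
              min(s), max(s), mean(abs(s))))
  invisible(x)
}

#' Strict upper-triangle edge vector
#'
#' Flattens the strict upper triangle of a square symmetric matrix in
#' row-major order: (1,2), (1,3), ..., (1,R), (2,3), ... For R regions the
#' result has length R(R-1)/2 (561 for 34 regions, 2278 for 68).
#'
#' @param m square matrix (or an `individual_connectome`).
#' @return Numeric vector of length `R(R-1)/2`, named `"i|j"` when the matrix
#'   has dimnames.
#' @seealso [from_upper_triangle()] for the inverse.
#' @export
upper_triangle <- function(m) {
  if (inherits(m, "individual_connectome")) m <- m$strength
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  v <- m[idx]
  if (!is.null(rownames(m))) {
    names(v) <- paste(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]], sep = "|")
  }
  v
}

#' Rebuild a symmetric matrix from an upper-triangle edge vector
#'
#' Inverse of [upper_triangle()]: places the edge vector back into a symmetric
#' R x R matrix with the given diagonal.
#'
#' @param v edge vector of length R(R-1)/2 in row-major upper-triangle order.
#' @param regions region labels (length R).
#' @param diag_value value for the diagonal (default 0).
#' @return Symmetric matrix with dimnames `regions`.
#' @export
from_upper_triangle <- function(v, regions, diag_value = 0) {
  r <- length(regions)
  if (length(v) != r * (r - 1) / 2) {
    stop("edge vector length ", length(v), " does not match ",
         r, " regions (expected ", r * (r - 1) / 2, ")")
  }
  m <- matrix(diag_value, r, r, dimnames = list(regions, regions))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- v
  m[idx[, c(2, 1), drop = FALSE]] <- v
  m
}
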
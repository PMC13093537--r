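#' Read and write SUVR scan tables
#'
#' The on-disk format is one row per scan: columns `scan_id`, `subject_id`,
#' `time_years`, `diagnosis`, `amyloid_status`, then one numeric column per
#' region (header = region label, order preserved). Separator is inferred
#' from the extension (`.tsv` = tab, otherwise comma). Writing then reading a
#' table is the identity.
#'
#' @param path file path.
#' @return [read_suvr_table()]: a [suvr_table()].
#' @export
read_suvr_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("scan_id", "subject_id", "time_years", "diagnosis",
                 "amyloid_status")
  missing_c <- setdiff(meta_cols, names(df))
  if (length(missing_c)) {
    stop("SUVR table missing column(s): ", paste(missing_c, collapse = ", "))
  }
  region_cols <- setdiff(names(df), meta_cols)
  if (!length(region_cols)) stop("SUVR table has no region columns")
  suvr <- as.matrix(df[, region_cols, drop = FALSE])
  if (!is.numeric(suvr)) {
    bad <- region_cols[!vapply(df[region_cols], is.numeric, TRUE)]
    stop("non-numeric SUVR column(s): ", paste(bad, collapse = ", "))
  }
  suvr_table(df$scan_id, df$subject_id, df$time_years, df$diagnosis,
             df$amyloid_status, suvr)
}

#' @rdname read_suvr_table
#' @param x a [suvr_table()].
#' @export
write_suvr_table <- function(x, path) {
  stopifnot(inherits(x, "suvr_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(x$meta, as.data.frame(x$suvr, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write covariate tables
#'
#' CSV keyed by `subject_id`, one row per subject.
#'
#' @param path file path.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$subject_id)) stop("covariate table missing subject_id")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in covariates")
  df
}

#' @rdname read_covariates
#' @param x covariate data.frame.
#' @export
write_covariates <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read labeled square matrices with a JSON sidecar
#'
#' Connectome-like matrices are stored as TSV with region labels as header
#' and first column; provenance (class, identifiers, reference size,
#' covariates) goes to a `.json` sidecar next to the matrix.
#'
#' @param m matrix, or a `reference_connectome` / `individual_connectome` /
#'   `contribution_matrix`.
#' @param path `.tsv` path; the sidecar is written at `path` with `.json`
#'   appended.
#' @param sidecar named list written as the JSON sidecar (filled
#'   automatically for known classes).
#' @export
write_matrix_tsv <- function(m, path, sidecar = NULL) {
  if (inherits(m, "reference_connectome")) {
    sidecar <- c(list(kind = "reference_connectome",
                      n_reference = m$n_reference,
                      covariate_spec = m$covariate_spec), sidecar)
    m <- m$ppc
  } else if (inherits(m, "individual_connectome")) {
    sidecar <- c(list(kind = "individual_connectome", scan_id = m$scan_id,
                      subject_id = m$subject_id,
                      n_reference = m$n_reference), sidecar)
    m <- m$strength
  } else if (inherits(m, "contribution_matrix")) {
    sidecar <- c(list(kind = "contribution_matrix",
                      n_repetitions = m$n_repetitions,
                      model_spec = m$model_spec), sidecar)
    m <- m$contribution
  }
  df <- data.frame(region = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(m, "sidecar") <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  m
}

#' Read and write gene x region expression matrices
#'
#' TSV with a header row of region labels and gene identifiers in the first
#' column.
#'
#' @param path file path.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' @rdname read_expression
#' @param x genes x regions matrix.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT dialect: one set per line, tab-separated `name`,
#' `description`, then member identifiers. Duplicate members within a set are
#' deduplicated; empty member lists are allowed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    stop("malformed GMT line(s) with < 2 fields: line ",
         paste(which(nfield < 2), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description per-set description strings (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML with paths, atlas labels, covariate names, repetition and permutation
#' counts, seeds, and the enrichment thresholds. Defaults are filled for
#' absent entries (`n_reps` 1000, `n_perm` 10000, overlap bounds 10/200,
#' fold thresholds 2/0.5).
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_reps = 1000, n_perm = 10000, seed = 1,
                   covariate_names = c("age", "sex", "education"),
                   min_overlap = 10, max_overlap = 200,
                   enriched_above = 2, unrelated_below = 0.5)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (cfg$n_reps < 1 || cfg$n_perm < 1) stop("counts must be >= 1")
  cfg
}

## Provenance record for CLI runs: config hash, seed, versions, input digests.
run_log <- function(config, seed, inputs = character(0)) {
  digest <- function(path) {
    if (!file.exists(path)) return(NA_character_)
    sprintf("size:%d;mtime:%s", file.size(path),
            format(file.mtime(path), "%Y-%m-%dT%H:%M:%S"))
  }
  list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("imconn")),
    inputs = lapply(stats::setNames(inputs, inputs), digest)
  )
}
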
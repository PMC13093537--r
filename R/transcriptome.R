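#' Reference transcription network
#'
#' Region x region Pearson correlation of regional expression profiles,
#' computed across all genes of an expression matrix.
#'
#' @param expr numeric matrix genes x regions (rownames = gene ids, colnames
#'   = region labels), no missing values.
#' @return Object of class `transcription_network`: list with `pc`
#'   (symmetric, unit diagonal), `n_genes`, `region_order`.
#' @export
reference_transcription_network <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3 || ncol(expr) < 3) stop("need >= 3 genes and >= 3 regions")
  if (any(!is.finite(expr))) stop("missing or non-finite expression values")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate correlation: constant region profile(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  }
  pc <- stats::cor(expr)
  pc[pc > 1] <- 1; pc[pc < -1] <- -1
  diag(pc) <- 1
  structure(
    list(pc = (pc + t(pc)) / 2, n_genes = nrow(expr),
         region_order = colnames(expr)),
    class = "transcription_network"
  )
}

#' @export
print.transcription_network <- function(x, ...) {
  cat(sprintf("Reference transcription network: %d regions over %d genes\n",
              length(x$region_order), x$n_genes))
  invisible(x)
}

## Leave-one-gene-out Pearson correlations by sufficient-statistic downdate.
## Returns for gene g (row) the edge vector (upper triangle, row-major) of
## the perturbed correlation computed over the remaining N-1 genes.
loo_edge_correlations <- function(expr) {
  n <- nrow(expr)
  s <- colSums(expr)
  q <- colSums(expr^2)
  cp <- crossprod(expr)
  idx <- which(upper.tri(cp), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  m <- n - 1
  xi <- expr[, i, drop = FALSE]   # genes x edges (region i values)
  xj <- expr[, j, drop = FALSE]
  sc <- sweep(-(xi * xj), 2, cp[idx], "+")                  # C' per gene/edge
  si <- sweep(-xi, 2, s[i], "+"); sj <- sweep(-xj, 2, s[j], "+")
  qi <- sweep(-xi^2, 2, q[i], "+"); qj <- sweep(-xj^2, 2, q[j], "+")
  num <- m * sc - si * sj
  den <- sqrt(pmax(m * qi - si^2, 0) * pmax(m * qj - sj^2, 0))
  r <- num / den
  r[r > 1] <- 1; r[r < -1] <- -1
  rownames(r) <- rownames(expr)
  colnames(r) <- paste(colnames(expr)[i], colnames(expr)[j], sep = "|")
  r
}

#' Gene-specific transcription network
#'
#' Leaves one gene out, recomputes the region x region Pearson correlation
#' over the remaining N-1 genes (the perturbed network), and scores each edge
#' as the normalized difference
#' \deqn{(PC_N - PC_{N-1}) / \sqrt{(1 - PC_N^2)/(N-1)}}
#' with N the full gene count. Note the sign convention: reference minus
#' perturbed, the mirror image of the subject-level connectome (which uses
#' perturbed minus reference); a positive edge means the gene's presence
#' raises that correlation.
#'
#' @param expr genes x regions expression matrix.
#' @param gene_id rowname of the gene to leave out.
#' @return Object of class `gene_network`: list with `gene_id`, `strength`
#'   (symmetric matrix, zero diagonal), `region_order`, `n_genes`.
#' @export
gene_specific_network <- function(expr, gene_id) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 4) stop("need at least 4 genes")
  if (!gene_id %in% rownames(expr)) stop("gene not found: ", gene_id)
  ref <- reference_transcription_network(expr)
  pc0 <- upper_triangle(ref$pc)
  if (any(abs(pc0) >= 1 - .Machine$double.eps * 4)) {
    stop("zero denominator: |reference correlation| = 1 at some edge")
  }
  sub <- expr[setdiff(rownames(expr), gene_id), , drop = FALSE]
  pc1 <- upper_triangle(stats::cor(sub))
  strength <- (pc0 - pc1) / sqrt((1 - pc0^2) / (ref$n_genes - 1))
  structure(
    list(gene_id = gene_id,
         strength = from_upper_triangle(strength, ref$region_order),
         region_order = ref$region_order, n_genes = ref$n_genes),
    class = "gene_network"
  )
}

#' All gene-specific networks as an edge matrix
#'
#' Computes the [gene_specific_network()] strength for every gene at once by
#' sufficient-statistic downdating (no per-gene recomputation), returning a
#' genes x edges matrix whose columns follow the [upper_triangle()] order.
#'
#' @param expr genes x regions expression matrix.
#' @return Numeric matrix genes x edges with attribute `region_order`.
#' @export
gene_network_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 4) stop("need at least 4 genes")
  ref <- reference_transcription_network(expr)
  pc0 <- upper_triangle(ref$pc)
  if (any(abs(pc0) >= 1 - .Machine$double.eps * 4)) {
    stop("zero denominator: |reference correlation| = 1 at some edge")
  }
  pc1 <- loo_edge_correlations(expr)
  strength <- sweep(-pc1, 2, pc0, "+") /
    rep(sqrt((1 - pc0^2) / (ref$n_genes - 1)), each = nrow(pc1))
  attr(strength, "region_order") <- ref$region_order
  strength
}

#' Connectome susceptibility map
#'
#' Per-edge susceptibility to disease-driven alteration: the common logarithm
#' of each edge's contribution to diagnostic discrimination, restricted to a
#' region subset (e.g., the left-hemisphere regions covered by the expression
#' atlas). Zero contributions are floored at one decade below the smallest
#' positive contribution so the map stays finite.
#'
#' @param contributions a `contribution_matrix` (or symmetric matrix).
#' @param regions region subset to keep (default: all).
#' @return Object of class `susceptibility_map`: list with `values` (named
#'   edge vector, log10 scale), `region_order`, `floor_value`.
#' @export
susceptibility_map <- function(contributions, regions = NULL) {
  w <- if (inherits(contributions, "contribution_matrix")) {
    contributions$contribution
  } else {
    as.matrix(contributions)
  }
  if (is.null(regions)) regions <- rownames(w)
  if (length(regions) < 2) stop("region subset must contain >= 2 regions")
  missing_r <- setdiff(regions, rownames(w))
  if (length(missing_r)) {
    stop("contributions missing region(s): ", paste(missing_r, collapse = ", "))
  }
  v <- upper_triangle(w[regions, regions, drop = FALSE])
  if (all(v == 0)) stop("all contributions zero on the region subset")
  floor_value <- log10(min(v[v > 0])) - 1
  out <- ifelse(v > 0, log10(pmax(v, .Machine$double.xmin)), floor_value)
  structure(
    list(values = stats::setNames(out, names(v)), region_order = regions,
         floor_value = floor_value),
    class = "susceptibility_map"
  )
}

#' Predict edge susceptibility from gene-specific networks
#'
#' Repeated train/test regression of the susceptibility map on the gene
#' networks: edges are the samples, each edge's feature vector is its strength
#' across all gene-specific transcription networks. Per repetition, `train_n`
#' edges are drawn for training, the remainder tests; a boosted regression is
#' fitted under the protocol; accuracy is the Pearson correlation between
#' predicted and true susceptibilities. Per-gene contributions (gain) are
#' averaged over repetitions.
#'
#' @param gene_networks genes x edges matrix from [gene_network_matrix()].
#' @param target a `susceptibility_map` (or numeric edge vector in the same
#'   edge order).
#' @param train_n training edges per repetition (561-edge maps use 500).
#' @param n_reps repetitions (full-scale default 1000).
#' @param seed base seed; repetition r uses `seed + r`.
#' @param protocol a [boost_protocol()].
#' @return Object of class `susceptibility_prediction`: list with `train_r`,
#'   `test_r` (per-rep Pearson R), `summary` (medians), `sign_test_p`
#'   (one-sided, test R > 0), `gene_contributions` (named, sums to 1).
#' @export
susceptibility_prediction <- function(gene_networks, target, train_n,
                                      n_reps = 1000, seed = 1,
                                      protocol = boost_protocol()) {
  withr::local_preserve_seed()
  y <- if (inherits(target, "susceptibility_map")) target$values else target
  x <- t(gene_networks)                       # edges x genes
  if (length(y) != nrow(x)) stop("edge count mismatch between networks and target")
  if (stats::sd(y) == 0) stop("undefined correlation: constant target")
  if (ncol(x) < 2) stop("need at least 2 genes")
  if (train_n >= nrow(x)) stop("train_n must leave at least one test edge")
  genes <- colnames(x) <- rownames(gene_networks)
  train_r <- test_r <- numeric(n_reps)
  contrib <- numeric(ncol(x))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    tr <- sample(nrow(x), train_n)
    te <- setdiff(seq_len(nrow(x)), tr)
    fit <- boost_fit(x[tr, , drop = FALSE], y[tr], "reg:squarederror", protocol)
    train_r[r] <- suppressWarnings(
      stats::cor(boost_predict(fit, x[tr, , drop = FALSE]), y[tr]))
    test_r[r] <- suppressWarnings(
      stats::cor(boost_predict(fit, x[te, , drop = FALSE]), y[te]))
    contrib <- contrib + boost_importance(fit, genes)
  }
  test_r[is.na(test_r)] <- 0
  contrib <- contrib / n_reps
  if (sum(contrib) > 0) contrib <- contrib / sum(contrib)
  structure(
    list(train_r = train_r, test_r = test_r,
         summary = c(median_train_r = stats::median(train_r, na.rm = TRUE),
                     median_test_r = stats::median(test_r)),
         sign_test_p = sign_test(test_r, mu = 0, alternative = "greater"),
         gene_contributions = stats::setNames(contrib, genes),
         n_reps = n_reps, train_n = train_n),
    class = "susceptibility_prediction"
  )
}

#' @export
print.susceptibility_prediction <- function(x, ...) {
  cat(sprintf(
    "Susceptibility prediction: median test R %.3f (train %.3f) over %d reps\n",
    x$summary["median_test_r"], x$summary["median_train_r"], x$n_reps
  ))
  cat(sprintf("Sign test (test R > 0): p = %.3g\n", x$sign_test_p))
  invisible(x)
}

#' Filter gene sets by overlap with the gene universe
#'
#' Keeps sets whose overlap with the universe (exact identifier match) lies
#' in `[min_overlap, max_overlap]`; sets with overlap below 10 or above 200
#' are excluded by default.
#'
#' @param collection named list of character vectors (gene sets), as read by
#'   [read_gmt()].
#' @param universe character vector of gene ids.
#' @param min_overlap,max_overlap inclusive retention bounds.
#' @return The retained collection, with an `overlap` attribute (named counts
#'   for all input sets).
#' @export
filter_gene_sets <- function(collection, universe, min_overlap = 10,
                             max_overlap = 200) {
  if (!length(universe)) stop("universe must be non-empty")
  ov <- vapply(collection, function(s) length(intersect(s, universe)), 0L)
  keep <- ov >= min_overlap & ov <= max_overlap
  out <- collection[keep]
  attr(out, "overlap") <- ov
  out
}

#' Gene-set fold enrichment of predictive contribution
#'
#' A set's share of the total per-gene predictive contribution divided by its
#' share of the gene universe. Scores above `enriched_above` mark the set as
#' enriched for predicting the susceptibilities; scores below
#' `unrelated_below` mark it unrelated.
#'
#' @param set character vector of gene ids (one gene set).
#' @param contributions named numeric per-gene contributions over the
#'   universe (e.g., `gene_contributions` from
#'   [susceptibility_prediction()]).
#' @param universe gene universe (default: names of `contributions`).
#' @param enriched_above,unrelated_below category thresholds (2 and 0.5).
#' @return List with `score`, `overlap`, `category`
#'   (`"enriched"`/`"unrelated"`/`"intermediate"`).
#' @export
fold_enrichment <- function(set, contributions, universe = names(contributions),
                            enriched_above = 2, unrelated_below = 0.5) {
  total <- sum(contributions[universe])
  if (!isTRUE(total > 0)) stop("zero total contribution over the universe")
  inside <- intersect(set, universe)
  if (!length(inside)) {
    return(list(score = 0, overlap = 0L, category = "unrelated"))
  }
  share_contrib <- sum(contributions[inside]) / total
  share_genes <- length(inside) / length(universe)
  score <- share_contrib / share_genes
  list(score = score, overlap = length(inside),
       category = if (score > enriched_above) "enriched"
                  else if (score < unrelated_below) "unrelated"
                  else "intermediate")
}

#' Fold enrichment over a whole collection, two modalities
#'
#' Applies [filter_gene_sets()] then [fold_enrichment()] per retained set for
#' the tau and amyloid contribution vectors, and combines the per-modality
#' calls into the four categories tau-enriched / amyloid-enriched / both /
#' neither.
#'
#' @param collection named list of gene sets.
#' @param contrib_tau,contrib_amyloid named per-gene contribution vectors
#'   over the same universe.
#' @param universe gene universe.
#' @param ... passed to [filter_gene_sets()] and [fold_enrichment()].
#' @return data.frame: set, overlap, fold_tau, fold_amyloid, category.
#' @export
enrichment_table <- function(collection, contrib_tau, contrib_amyloid,
                             universe = names(contrib_tau), ...) {
  kept <- filter_gene_sets(collection, universe, ...)
  rows <- lapply(names(kept), function(nm) {
    ft <- fold_enrichment(kept[[nm]], contrib_tau, universe)
    fa <- fold_enrichment(kept[[nm]], contrib_amyloid, universe)
    data.frame(set = nm, overlap = ft$overlap,
               fold_tau = ft$score, fold_amyloid = fa$score,
               category = if (ft$category == "enriched" &&
                              fa$category == "enriched") "both"
                          else if (ft$category == "enriched") "tau"
                          else if (fa$category == "enriched") "amyloid"
                          else "neither",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Categorize genes by above-average contribution
#'
#' Labels each gene by whether its contribution to predicting tau and/or
#' amyloid susceptibility exceeds the average level (1/number of genes when
#' contributions are normalized to sum to 1; the vectors are renormalized so
#' the two readings coincide).
#'
#' @param contrib_tau,contrib_amyloid per-gene contribution vectors over the
#'   same genes.
#' @return Factor per gene with levels `both`, `tau`, `amyloid`, `neither`.
#' @export
categorize_genes <- function(contrib_tau, contrib_amyloid) {
  if (length(contrib_tau) != length(contrib_amyloid)) {
    stop("contribution vectors differ in length")
  }
  ta <- contrib_tau / sum(contrib_tau)
  am <- contrib_amyloid / sum(contrib_amyloid)
  avg <- 1 / length(ta)
  hi_t <- ta > avg; hi_a <- am > avg
  factor(ifelse(hi_t & hi_a, "both",
                ifelse(hi_t, "tau", ifelse(hi_a, "amyloid", "neither"))),
         levels = c("both", "tau", "amyloid", "neither"))
}
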
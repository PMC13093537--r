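test_that("the reference transcription network is the gene-wise Pearson matrix", {
  expr <- cbind(A = c(1, 2, 3, 4, 5), B = c(1, 2, 3, 4, 5) * 2,
                C = c(2, 1, 4, 3, 5))
  rownames(expr) <- paste0("g", 1:5)
  net <- reference_transcription_network(expr)
  expect_equal(net$pc["A", "B"], 1)
  expect_true(isSymmetric(net$pc))
  expect_equal(unname(diag(net$pc)), rep(1, 3))
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expect_equal(net$pc[pr[1], pr[2]], cor(expr[, pr[1]], expr[, pr[2]]),
                 tolerance = 1e-12)
  }
  expr2 <- expr; expr2[, 2] <- 3
  expect_error(reference_transcription_network(expr2), "constant")
})

test_that("the leave-one-gene-out network reproduces the hand-worked three-gene case", {
  # profiles A = (1,2,3), B = (1,3,2): PC_3 = 0.5; dropping gene 1 leaves
  # (2,3) vs (3,2): PC_2 = -1; strength = 1.5 / sqrt(0.375)
  expr <- cbind(A = c(1, 2, 3), B = c(1, 3, 2), C = c(2, 1, 3))
  rownames(expr) <- paste0("g", 1:3)
  expect_equal(cor(expr[, "A"], expr[, "B"]), 0.5)
  expr4 <- rbind(expr, g4 = c(2.5, 2.0, 1.5))  # need >= 4 genes
  net <- gene_specific_network(expr4, "g1")
  pc_all <- cor(expr4[, "A"], expr4[, "B"])
  pc_loo <- cor(expr4[-1, "A"], expr4[-1, "B"])
  expect_equal(net$strength["A", "B"],
               (pc_all - pc_loo) / sqrt((1 - pc_all^2) / 3),
               tolerance = 1e-12)
  expect_equal(unname(diag(net$strength)), rep(0, 3))
})

test_that("the downdated all-genes network matrix matches per-gene brute force", {
  expr <- synth_expression(20, 10, rank = 2, noise_sd = 1, seed = 5)
  gn <- gene_network_matrix(expr)
  expect_equal(dim(gn), c(20, 45))
  for (g in rownames(expr)[c(1, 7, 20)]) {
    brute <- gene_specific_network(expr, g)
    expect_lt(max(abs(gn[g, ] - upper_triangle(brute$strength))), 1e-12)
  }
  # no conservation across genes, but the mean strength is small relative
  # to its spread
  expect_lt(abs(mean(gn)), sd(gn))
})

test_that("a planted driver gene dominates its target edge", {
  expr <- synth_expression(60, 8, rank = 2, noise_sd = 1, seed = 7,
                           driver = list(edge = c(2, 5), magnitude = 25))
  gn <- gene_network_matrix(expr)
  edge_name <- "R02|R05"
  expect_equal(rownames(expr)[which.max(abs(gn[, edge_name]))],
               rownames(expr)[1])
})

test_that("susceptibility maps are log10 contributions with the floor rule", {
  regions <- c("A", "B", "C")
  w <- from_upper_triangle(c(1, 0.01, 0), regions)
  sm <- susceptibility_map(w)
  expect_equal(unname(sm$values[1]), 0)
  expect_equal(unname(sm$values[2]), -2)
  # zero contribution floored one decade below the smallest positive one
  expect_equal(unname(sm$values[3]), log10(0.01) - 1)
  expect_equal(sm$floor_value, -3)
  wc <- from_upper_triangle(rep(0.25, 3), regions)
  expect_equal(unname(susceptibility_map(wc)$values), rep(log10(0.25), 3))
  expect_error(susceptibility_map(w, regions = c("A", "Z")), "missing region")
  expect_error(susceptibility_map(from_upper_triangle(rep(0, 3), regions)),
               "all contributions zero")
})

test_that("susceptibility prediction finds a planted driving gene and stays null otherwise", {
  expr <- synth_expression(80, 12, rank = 2, noise_sd = 1, seed = 9)
  gn <- gene_network_matrix(expr)
  set.seed(4)
  target <- gn[25, ] + rnorm(ncol(gn), 0, 0.05 * sd(gn[25, ]))
  res <- susceptibility_prediction(gn, target, train_n = 50, n_reps = 4,
                                   seed = 2, protocol = desk_protocol())
  expect_equal(names(which.max(res$gene_contributions)), rownames(expr)[25])
  expect_gt(res$summary[["median_test_r"]], 0.9)
  expect_lt(res$sign_test_p, 0.10)
  null_target <- rnorm(ncol(gn))
  res0 <- susceptibility_prediction(gn, null_target, train_n = 50, n_reps = 6,
                                    seed = 3, protocol = desk_protocol())
  expect_lt(abs(res0$summary[["median_test_r"]]), 0.35)
  expect_gt(res0$sign_test_p, 0.05)
  expect_error(susceptibility_prediction(gn, rep(1, ncol(gn)), train_n = 50),
               "constant target")
})

test_that("gene-set filtering keeps overlaps in [10, 200] inclusive", {
  universe <- paste0("g", 1:300)
  sets <- list(s9 = paste0("g", 1:9), s10 = paste0("g", 1:10),
               s200 = paste0("g", 1:200), s201 = paste0("g", 1:201),
               out = paste0("x", 1:12), empty = character(0),
               part = c(paste0("g", 1:8), paste0("y", 1:4)))
  kept <- filter_gene_sets(sets, universe)
  expect_setequal(names(kept), c("s10", "s200"))
  ov <- attr(kept, "overlap")
  expect_equal(unname(ov[c("s9", "s201", "part", "empty")]), c(9L, 201L, 8L, 0L))
  expect_error(filter_gene_sets(sets, character(0)), "non-empty")
})

test_that("fold enrichment matches hand arithmetic and its conservation laws", {
  universe <- paste0("g", 1:10)
  contrib <- setNames(rep(0.1, 10), universe)
  # uniform contributions: every set scores exactly 1
  for (k in c(2, 5, 9)) {
    expect_equal(fold_enrichment(universe[1:k], contrib)$score, 1,
                 tolerance = 1e-12)
  }
  expect_equal(fold_enrichment(universe, contrib)$score, 1)
  # 2-gene set holding 0.6 of the total: (0.6)/(0.2) = 3 -> enriched
  c2 <- setNames(c(0.3, 0.3, rep(0.4 / 8, 8)), universe)
  fe <- fold_enrichment(universe[1:2], c2)
  expect_equal(fe$score, 3)
  expect_equal(fe$category, "enriched")
  # invariance to global rescaling
  expect_equal(fold_enrichment(universe[1:2], 7 * c2)$score, 3)
  # weighted mean of fold scores over a partition equals 1
  set.seed(6)
  c3 <- setNames(runif(10), universe)
  parts <- list(universe[1:3], universe[4:7], universe[8:10])
  scores <- vapply(parts, function(s) fold_enrichment(s, c3)$score, 0)
  wts <- vapply(parts, length, 0L) / 10
  expect_equal(sum(scores * wts), 1, tolerance = 1e-12)
  expect_error(fold_enrichment(universe[1:2], setNames(rep(0, 10), universe)),
               "zero total")
})

test_that("two-modality enrichment tables and planted gene sets behave as constructed", {
  set.seed(8)
  universe <- paste0("g", 1:150)
  contrib_tau <- setNames(rexp(150)^2, universe)
  contrib_tau <- contrib_tau / sum(contrib_tau)
  contrib_amy <- setNames(rexp(150)^2, universe)
  contrib_amy <- contrib_amy / sum(contrib_amy)
  sets <- synth_gene_sets(universe, n_sets = 20, size_range = c(10, 30),
                          planted = contrib_tau, planted_size = 12, seed = 2)
  tab <- enrichment_table(sets, contrib_tau, contrib_amy)
  expect_true(all(c("set", "overlap", "fold_tau", "fold_amyloid",
                    "category") %in% names(tab)))
  expect_gt(tab$fold_tau[tab$set == "planted"], 2)
  expect_true(tab$category[tab$set == "planted"] %in% c("tau", "both"))
})

test_that("gene categorization by above-average contribution has four levels with heavy-tail scarcity", {
  set.seed(9)
  ta <- rexp(500)^3
  am <- rexp(500)^3
  cats <- categorize_genes(ta, am)
  expect_setequal(levels(cats), c("both", "tau", "amyloid", "neither"))
  # heavy-tailed vectors: well under half the genes sit above the mean
  expect_lt(mean(cats %in% c("both", "tau")), 0.5)
  expect_lt(mean(cats %in% c("both", "amyloid")), 0.5)
  expect_error(categorize_genes(ta, am[1:10]), "length")
})
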
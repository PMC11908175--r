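test_that("a single cluster yields an empty marker table", {
  atlas <- normalize_atlas(make_atlas(matrix(rpois(40, 2), 10, 4)))
  expect_equal(nrow(find_all_markers(atlas)), 0)
})

test_that("rank-sum p-values agree with wilcox.test on a small instance", {
  set.seed(21)
  counts <- matrix(rpois(20 * 10, 2), 20, 10)
  atlas <- normalize_atlas(make_atlas(counts,
                                      cluster = rep(c("a", "b"), each = 10)))
  mk <- find_all_markers(atlas, only_pos = FALSE, min_pct = 0,
                         min_log2fc = 0)
  in_a <- atlas$cell_meta$cluster == "a"
  for (i in seq_len(nrow(mk))) {
    rec <- mk[i, ]
    grp1 <- if (rec$cluster == "a") in_a else !in_a
    oracle <- suppressWarnings(stats::wilcox.test(
      atlas$lognorm[grp1, rec$gene], atlas$lognorm[!grp1, rec$gene],
      exact = FALSE, correct = TRUE))$p.value
    expect_equal(rec$p_value, oracle, tolerance = 1e-10)
  }
})

test_that("planted markers are recovered as significant positive markers", {
  sim <- shared_sim()
  hits <- dplyr::filter(sim$markers, p_adj < 0.05, direction == "up")
  recovery <- mapply(function(cl, genes) {
    mean(genes %in% hits$gene[hits$cluster == cl])
  }, names(sim$truth$marker_genes), sim$truth$marker_genes)
  expect_gte(mean(recovery), 0.9)
})

test_that("a gene with identical normalised expression is excluded by the prefilter", {
  set.seed(14)
  de_gene <- rpois(12, 2) + c(rep(8, 6), rep(0, 6))
  # filler keeps every cell at equal depth, so the constant gene stays
  # constant after normalisation
  counts <- cbind(rep(3, 12), de_gene, max(de_gene) + 5 - de_gene)
  colnames(counts) <- NULL
  atlas <- normalize_atlas(make_atlas(counts,
                                      cluster = rep(c("a", "b"), each = 6)))
  mk <- find_all_markers(atlas, only_pos = FALSE)
  expect_false("g001" %in% mk$gene)
  expect_true("g002" %in% mk$gene)
})

test_that("marker table respects its invariants", {
  mk <- shared_sim()$markers
  expect_true(all(mk$p_adj >= mk$p_value - 1e-12))
  expect_true(all(mk$pct_in >= 0 & mk$pct_in <= 1))
  expect_true(all(mk$pct_out >= 0 & mk$pct_out <= 1))
  expect_true(all(mk$direction == "up"))  # only_pos default
})

test_that("tiny clusters are skipped with a warning", {
  counts <- matrix(rpois(22 * 4, 2), 22, 4)
  atlas <- normalize_atlas(make_atlas(counts,
                                      cluster = c(rep("a", 20), "b", "b")))
  expect_warning(find_all_markers(atlas), "skipped")
})

test_that("cluster_profile matches first-principles recomputation", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  cl <- sim$atlas$cell_meta$cluster
  g <- sample(colnames(sim$atlas$lognorm), 5)
  for (gene in g) {
    means <- tapply(sim$atlas$lognorm[, gene], cl, mean)
    expect_equal(unname(prof$mean_lognorm[names(means), gene]),
                 as.numeric(means))
    s <- stats::sd(means)
    expected <- if (s == 0) rep(0, length(means)) else (means - mean(means)) / s
    expect_equal(unname(prof$scaled_avg[names(means), gene]),
                 as.numeric(expected), tolerance = 1e-10)
  }
  # unit variance across clusters for non-degenerate genes
  v <- apply(prof$scaled_avg, 2, stats::var)
  nz <- apply(prof$mean_lognorm, 2, stats::sd) > 0
  expect_true(all(abs(v[nz] - 1) < 1e-8))
})

test_that("cluster_profile degenerate cases: antisymmetry and all-zero", {
  counts <- rbind(c(4, 1), c(4, 1), c(0, 1), c(0, 1))
  atlas <- normalize_atlas(make_atlas(counts,
                                      cluster = c("a", "a", "b", "b")))
  prof <- cluster_profile(atlas)
  # two clusters: z-scores are +-1/sqrt(2) and antisymmetric
  expect_equal(unname(prof$scaled_avg[, "g001"]),
               c(1, -1) / sqrt(2), tolerance = 1e-10)
  expect_equal(sum(prof$scaled_avg[, "g001"]), 0)
})

test_that("top_markers orders by fold-change with deterministic ties", {
  tbl <- tibble::tibble(
    cluster = "a",
    gene = c("gB", "gA", "gC", "gD"),
    log2fc = c(2, 2, 3, 1),
    pct_in = 1, pct_out = 0,
    p_value = c(0.001, 0.001, 0.001, 0.2),
    p_adj = c(0.01, 0.01, 0.01, 0.4),
    direction = "up")
  top <- top_markers(tbl, n = 10)
  # gD fails alpha; tie between gA/gB broken lexicographically
  expect_equal(top$gene, c("gC", "gA", "gB"))
  expect_equal(nrow(top_markers(tbl, n = 2)), 2)
})

test_that("top_markers returns the n largest of 12 graded fold-changes", {
  # construction oracle: a cluster with 12 significant markers of graded
  # fold-change; top_markers(10) must return the 10 largest, in order
  tbl <- tibble::tibble(
    cluster = "a",
    gene = sprintf("g%03d", 1:12),
    log2fc = 0.25 * (1:12),
    pct_in = 1, pct_out = 0,
    p_value = 1e-6, p_adj = 1e-5,
    direction = "up")
  top <- top_markers(tbl[sample(12), ], n = 10)
  expect_equal(top$gene, sprintf("g%03d", 12:3))
  expect_equal(top$rank, 1:10)
})

test_that("permuted cluster labels give nominal raw-p calibration", {
  sim <- shared_sim()
  atlas <- sim$atlas
  set.seed(202)
  atlas$cell_meta$cluster <- sample(atlas$cell_meta$cluster)
  mk <- find_all_markers(atlas, only_pos = FALSE, min_pct = 0,
                         min_log2fc = 0)
  frac <- mean(mk$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(mk))
  expect_lt(abs(frac - 0.05), 3 * se)
})
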
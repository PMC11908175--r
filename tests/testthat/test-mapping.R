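synthetic_bulk <- function(atlas, noise_sd = 0.3, seed = 99,
                           prefix = "type_") {
  set.seed(seed)
  cl <- atlas$cell_meta$cluster
  bulk <- t(rowsum(as.matrix(atlas$counts), cl) / as.vector(table(cl)))
  bulk <- bulk * matrix(exp(rnorm(length(bulk), 0, noise_sd)), nrow(bulk))
  colnames(bulk) <- paste0(prefix, colnames(bulk))
  bulk
}

test_that("a bulk profile copied from a cluster maps back with r = 1", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  bulk <- cbind(copy_c001 = expm1(prof$mean_lognorm["c001", ]),
                flat = rep(1, ncol(prof$mean_lognorm)))
  mp <- bulk_correlation_map(prof, bulk, method = "spearman")
  expect_equal(unname(mp$matrix["copy_c001", "c001"]), 1)
  asg <- dplyr::filter(mp$result, cluster == "c001", assigned)
  expect_equal(asg$cell_type, "copy_c001")
  # constant profile: r = 0 everywhere by the zero-variance convention
  expect_true(all(mp$matrix["flat", ] == 0))
})

test_that("noisy synthetic bulk profiles re-identify >=90% of clusters", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  mp <- bulk_correlation_map(prof, synthetic_bulk(sim$atlas))
  asg <- dplyr::filter(mp$result, assigned)
  expect_gte(mean(asg$cell_type == paste0("type_", asg$cluster)), 0.9)
  # exactly one assignment per cluster
  expect_equal(nrow(asg), length(prof$clusters))
  expect_equal(anyDuplicated(asg$cluster), 0)
})

test_that("too few shared genes is an error reporting the count", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  small <- synthetic_bulk(sim$atlas)[1:5, , drop = FALSE]
  expect_error(bulk_correlation_map(prof, small), "5 genes")
  expect_error(bulk_correlation_map(prof, -synthetic_bulk(sim$atlas)),
               "non-negative")
})

test_that("correlation is invariant to the expected bulk rescalings", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  bulk <- synthetic_bulk(sim$atlas)
  # spearman: per-cell-type monotone transformation
  sp1 <- bulk_correlation_map(prof, bulk, method = "spearman")
  sp2 <- bulk_correlation_map(prof, bulk^2, method = "spearman")
  expect_equal(sp1$matrix, sp2$matrix, tolerance = 1e-12)
  # pearson works on log1p(bulk); an affine transformation of that log
  # vector (injected by inverting the log1p) leaves r exactly unchanged
  v <- log1p(bulk)
  pe1 <- bulk_correlation_map(prof, bulk)
  pe2 <- bulk_correlation_map(prof, expm1(2 * v + 1))
  expect_equal(pe1$matrix, pe2$matrix, tolerance = 1e-10)
  # hvg gene set runs and keeps coefficients in range
  hv <- bulk_correlation_map(prof, bulk, gene_set = "hvg", n_hvg = 100)
  expect_true(all(hv$matrix >= -1 & hv$matrix <= 1))
})

test_that("enhancer-gene assignment requires all genes positive", {
  prof <- structure(list(
    mean_lognorm = matrix(0, 2, 2, dimnames = list(c("c1", "c2"),
                                                   c("A", "B"))),
    scaled_avg = rbind(c1 = c(A = 1.2, B = 0.3),
                       c2 = c(A = 0.8, B = -0.1)),
    clusters = c("c1", "c2")), class = "cluster_profile")
  drv <- tibble::tibble(driver = "SS1", cell_type = "P-FN",
                        genes = list(c("A", "B")))
  res <- enhancer_gene_assignment(prof, drv)
  expect_equal(res$cluster, "c1")
  expect_equal(res$score, 2)
  expect_error(enhancer_gene_assignment(
    prof, tibble::tibble(driver = "x", cell_type = "y",
                         genes = list(character(0)))), "empty")
  expect_error(enhancer_gene_assignment(
    prof, tibble::tibble(driver = "x", cell_type = "y",
                         genes = list("ZZZ"))), "ZZZ")
})

test_that("a planted enhancer-gene pair singles out its cluster", {
  sim <- shared_sim()
  prof <- cluster_profile(sim$atlas)
  genes <- sim$truth$marker_genes$c005[1:2]
  res <- enhancer_gene_assignment(
    prof, tibble::tibble(driver = "SSx", cell_type = "CX-type",
                         genes = list(genes)))
  expect_true("c005" %in% res$cluster)
  # planted markers are near-background elsewhere, so few other clusters
  # can show positive scaled average for both genes at once
  expect_lte(nrow(res), 5)
})

test_that("marker logic recovers planted predicates and degenerate cases", {
  sim <- shared_sim()
  zf <- sim$truth$tf_code$zinc_finger
  off_tf <- colnames(zf)[zf["c004", ] == 0][1]
  pred <- tibble::tibble(gene = c("mk_c004_1", off_tf),
                         state = c("positive", "negative"))
  res <- marker_logic_assignment(sim$atlas, pred)
  expect_true(res$assigned[res$cluster == "c004"])
  # dropping one condition returns a superset
  relax <- marker_logic_assignment(sim$atlas, pred[1, ])
  expect_true(all(res$cluster[res$assigned] %in%
                    relax$cluster[relax$assigned]))
  # contradictory predicate is unsatisfiable
  contra <- tibble::tibble(gene = c("mk_c004_1", "mk_c004_1"),
                           state = c("positive", "negative"))
  expect_error(marker_logic_assignment(sim$atlas, contra), "twice")
  both <- marker_logic_assignment(
    sim$atlas, c(mk_c004_1 = "+", mk_c004_2 = "-"))
  expect_equal(sum(both$assigned), 0)
})
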
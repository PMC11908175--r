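nt_fixture_atlas <- function(counts, clusters) {
  gene_class <- ifelse(colnames(counts) %in% nt_genes(), "nt_pathway",
                       "other")
  normalize_atlas(make_atlas(counts, cluster = clusters,
                             gene_class = gene_class))
}

test_that("all-zero expression classifies every cell as negative", {
  counts <- matrix(0, 5, 8)
  colnames(counts) <- c(nt_genes(), "bg1")
  counts[, "bg1"] <- 3  # depth so normalisation is defined
  atlas <- nt_fixture_atlas(counts, rep("a", 5))
  res <- classify_neurotransmitters(atlas)
  expect_equal(res$summary$pct_negative, 100)
  expect_equal(res$summary$fractions[["negative"]], 1)
})

test_that("single/multi/negative fractions partition the cells exactly", {
  sim <- shared_sim()
  res <- classify_neurotransmitters(sim$atlas)
  f <- res$summary$fractions
  expect_equal(f[["single"]] + f[["multi"]] + f[["negative"]], 1)
  expect_equal(sum(res$summary$combinations$count), n_cells(sim$atlas))
})

test_that("classification is monotone in the threshold", {
  sim <- shared_sim()
  counts_at <- function(th) {
    res <- classify_neurotransmitters(sim$atlas, threshold = th)
    res$summary$per_gene$n_cells
  }
  lo <- counts_at(1); mid <- counts_at(2); hi <- counts_at(3)
  expect_true(all(lo >= mid) && all(mid >= hi))
})

test_that("planted NT programmes are recovered per cell", {
  sim <- shared_sim()
  res <- classify_neurotransmitters(sim$atlas, layer = "lognorm",
                                    threshold = 2)
  bits <- as.matrix(res$profiles[, nt_genes()])
  truth <- t(vapply(sim$truth$nt_labels, function(s) nt_genes() %in% s,
                    logical(7)))
  expect_gte(mean(bits == truth), 0.95)
  # partition structure: single, 2-3 class and negative cells all present
  expect_true(all(c(any(res$profiles$n_classes == 1),
                    any(res$profiles$n_classes %in% 2:3),
                    any(res$profiles$n_classes == 0))))
  expect_error(classify_neurotransmitters(sim$atlas, genes = c("VGlut", "xx")),
               "xx")
})

test_that("upset_counts enumerates combinations exactly", {
  profiles <- tibble::tibble(
    VAChT = c(TRUE, TRUE, FALSE, FALSE),
    Gad1 = c(FALSE, TRUE, FALSE, FALSE))
  res <- upset_counts(profiles)
  expect_equal(res$count[res$combination == "VAChT"], 1)
  expect_equal(res$count[res$combination == "VAChT+Gad1"], 1)
  expect_equal(res$count[res$combination == "none"], 2)
  expect_equal(sum(res$count), 4)
  # planted combinations on a larger random instance are exact
  set.seed(12)
  bits <- matrix(runif(1000 * 3) < 0.3, 1000, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  res2 <- upset_counts(tibble::as_tibble(bits))
  expect_equal(sum(res2$count), 1000)
  key <- apply(bits, 1, function(b) {
    if (!any(b)) "none" else paste(c("A", "B", "C")[b], collapse = "+")
  })
  expect_equal(res2$count[match(names(table(key)), res2$combination)],
               unname(as.integer(table(key))))
})

test_that("cluster-defining neuropeptides recover the planted restriction", {
  sim <- shared_sim()
  res <- cluster_defining_neuropeptides(sim$atlas, markers = sim$markers)
  planted <- sim$truth$np_clusters
  for (np in names(planted)) {
    row <- dplyr::filter(res, neuropeptide == np)
    expect_equal(nrow(row), 1, info = np)
    expect_setequal(row$clusters[[1]], planted[[np]])
  }
})

test_that("a uniformly expressed neuropeptide is not cluster-defining", {
  set.seed(5)
  counts <- matrix(rpois(200 * 10, 2), 200, 10)
  colnames(counts) <- c(sprintf("bg%d", 1:9), "np_uniform")
  atlas <- make_atlas(counts, cluster = rep(c("a", "b", "c", "d"), each = 50),
                      gene_class = c(rep("other", 9), "neuropeptide"))
  atlas <- normalize_atlas(atlas)
  res <- cluster_defining_neuropeptides(atlas)
  expect_false("np_uniform" %in% res$neuropeptide)
  expect_warning(
    cluster_defining_neuropeptides(atlas, np_genes = c("np_uniform", "gone")),
    "gone")
})

test_that("many-to-many neuropeptide/cluster structure is representable", {
  # two neuropeptides planted in the same two clusters
  spec <- synthetic_spec(
    n_clusters = 6, n_cells_per_cluster = 60, n_genes_background = 60,
    n_glial_clusters = 0, n_np_genes = 6, n_np_restricted = 2,
    np_assignment = list(np01 = c("c001", "c002"),
                         np02 = c("c001", "c002")),
    seed = 17)
  sim <- simulate_atlas(spec)
  atlas <- normalize_atlas(sim$atlas)
  res <- cluster_defining_neuropeptides(atlas)
  expect_setequal(res$clusters[[which(res$neuropeptide == "np01")]],
                  c("c001", "c002"))
  expect_setequal(res$clusters[[which(res$neuropeptide == "np02")]],
                  c("c001", "c002"))
})

test_that("tf_np_correlation matches the direct formula and conventions", {
  set.seed(9)
  counts <- matrix(rpois(50 * 6, 3), 50, 6)
  counts[, 4] <- counts[, 1]          # np identical to tf
  counts[, 5] <- 2                    # constant gene
  atlas <- make_atlas(counts,
                      gene_class = c("tf", "tf", "tf", "neuropeptide",
                                     "neuropeptide", "neuropeptide"))
  atlas <- normalize_atlas(atlas)
  # identical column: coefficient 1 against itself-by-another-name
  res <- tf_np_correlation(atlas, tf_genes = "g001",
                           np_genes = c("g004", "g005"))
  expect_equal(unname(res$matrix["g001", "g004"]), 1)
  # constant gene: 0 by convention (its lognorm can still vary with depth,
  # so test a truly constant lognorm by zeroing the column)
  atlas2 <- atlas
  atlas2$lognorm[, "g005"] <- 1
  res2 <- tf_np_correlation(atlas2, tf_genes = "g001", np_genes = "g005")
  expect_equal(unname(res2$matrix["g001", "g005"]), 0)
  # brute-force oracle over all pairs
  full <- tf_np_correlation(atlas)
  for (tf in c("g001", "g002", "g003")) {
    for (np in c("g004", "g006")) {
      x <- atlas$lognorm[, tf]; y <- atlas$lognorm[, np]
      oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(unname(full$matrix[tf, np]), oracle, tolerance = 1e-12)
    }
  }
})

test_that("correlation matrix is invariant to cell order and ranks top-k", {
  sim <- shared_sim()
  res <- tf_np_correlation(sim$atlas, top_k = 5)
  perm <- sample(n_cells(sim$atlas))
  shuffled <- subset_cells(sim$atlas, perm)
  res_p <- tf_np_correlation(shuffled, top_k = 5)
  expect_equal(res$matrix, res_p$matrix, tolerance = 1e-12)
  # top lists are sorted descending with 5 TFs per neuropeptide
  by_np <- split(res$top, res$top$neuropeptide)
  expect_true(all(vapply(by_np, function(d) {
    nrow(d) == 5 && !is.unsorted(rev(d$coefficient))
  }, logical(1))))
  expect_true(all(res$matrix >= -1 & res$matrix <= 1))
})
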
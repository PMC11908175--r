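test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_spec(n_clusters = 4, n_cells_per_cluster = 20,
                         n_genes_background = 30, seed = 5)
  a <- simulate_atlas(spec)
  b <- simulate_atlas(spec)
  expect_identical(as.matrix(a$atlas$counts), as.matrix(b$atlas$counts))
  expect_identical(a$truth$cell_lineage, b$truth$cell_lineage)
  expect_identical(a$truth$tf_code, b$truth$tf_code)
})

test_that("t2_fraction = 0 yields no T2 cells and all-zero transgenes", {
  spec <- synthetic_spec(n_clusters = 3, n_cells_per_cluster = 15,
                         n_genes_background = 20, t2_fraction = 0, seed = 2)
  sim <- simulate_atlas(spec)
  expect_true(all(sim$truth$cell_lineage == "T1"))
  expect_equal(sum(sim$atlas$counts[, c("FLP", "GFP", "RFP")]), 0)
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(synthetic_spec(t2_fraction = 1.5), "t2_fraction")
  expect_error(synthetic_spec(n_glial_clusters = 30, n_clusters = 10),
               "n_glial_clusters")
  expect_error(synthetic_spec(mito_fraction_range = c(0.5, 0.2)),
               "mito_fraction_range")
  expect_error(
    synthetic_spec(n_clusters = 4,
                   planted_codes = list(zinc_finger = matrix(1, 3, 8))),
    "planted_codes")
  expect_error(synthetic_spec(nt_assignment = list(zzz = "VGlut")),
               "nt_assignment")
})

test_that("ground truth respects the generator's structural invariants", {
  spec <- synthetic_spec(n_clusters = 5, n_cells_per_cluster = 25,
                         n_glial_clusters = 2, n_genes_background = 30,
                         seed = 8)
  sim <- simulate_atlas(spec)
  # cell counts per cluster match the spec
  expect_true(all(table(sim$truth$cluster_of_cell) == 25))
  # every T2 cell expresses >= 1 transgene before dropout
  is_t2 <- sim$truth$cell_lineage == "T2"
  expect_true(all(sim$truth$t2_pre_dropout[is_t2]))
  # glial clusters express repo at cluster-defining levels
  glia <- sim$truth$glial_clusters
  expect_length(glia, 2)
  repo_frac <- tapply(as.numeric(sim$atlas$counts[, "repo"] >= 1),
                      sim$truth$cluster_of_cell, mean)
  expect_true(all(repo_frac[glia] > 0.5))
  expect_true(all(repo_frac[setdiff(names(repo_frac), glia)] < 0.5))
})

test_that("T2 assignment is monotone in the transgene detection rate", {
  n_t2 <- vapply(c(0.2, 0.5, 0.8, 1.0), function(rate) {
    spec <- synthetic_spec(n_clusters = 4, n_cells_per_cluster = 50,
                           n_genes_background = 20, t2_fraction = 0.3,
                           transgene_detection_rate = rate, seed = 31)
    sim <- simulate_atlas(spec)
    atlas <- assign_lineage(sim$atlas)
    sum(atlas$cell_meta$lineage == "T2")
  }, numeric(1))
  expect_true(all(diff(n_t2) >= 0))
})

test_that("write/read round-trips counts and metadata exactly", {
  sim <- simulate_atlas(synthetic_spec(n_clusters = 3,
                                       n_cells_per_cluster = 10,
                                       n_genes_background = 15, seed = 4))
  dir <- withr::local_tempdir()
  manifest <- write_atlas_dataset(sim$atlas, file.path(dir, "ds"),
                                  truth = sim$truth)
  expect_tibble(manifest)
  back <- read_atlas_dataset(file.path(dir, "ds"))
  expect_equal(as.matrix(back$counts), as.matrix(sim$atlas$counts))
  expect_identical(back$cell_meta$cluster, sim$atlas$cell_meta$cluster)
  expect_identical(back$gene_meta$gene_class, sim$atlas$gene_meta$gene_class)
})

test_that("two writes of the same dataset have identical checksums", {
  sim <- simulate_atlas(synthetic_spec(n_clusters = 2,
                                       n_cells_per_cluster = 8,
                                       n_genes_background = 10, seed = 9))
  dir <- withr::local_tempdir()
  m1 <- write_atlas_dataset(sim$atlas, file.path(dir, "a"))
  m2 <- write_atlas_dataset(sim$atlas, file.path(dir, "b"))
  expect_identical(m1$md5, m2$md5)
})

test_that("writing refuses a non-empty directory without overwrite", {
  sim <- simulate_atlas(synthetic_spec(n_clusters = 2,
                                       n_cells_per_cluster = 5,
                                       n_genes_background = 10, seed = 3))
  dir <- withr::local_tempdir()
  write_atlas_dataset(sim$atlas, file.path(dir, "ds"))
  expect_error(write_atlas_dataset(sim$atlas, file.path(dir, "ds")),
               "not empty")
  expect_silent(write_atlas_dataset(sim$atlas, file.path(dir, "ds"),
                                    overwrite = TRUE))
})

test_that("an empty (0-cell) matrix writes and reads back as valid files", {
  sim <- simulate_atlas(synthetic_spec(n_clusters = 2,
                                       n_cells_per_cluster = 5,
                                       n_genes_background = 10, seed = 3))
  empty <- subset_cells(sim$atlas, integer(0))
  dir <- withr::local_tempdir()
  write_atlas_dataset(empty, file.path(dir, "ds"))
  back <- read_atlas_dataset(file.path(dir, "ds"))
  expect_equal(n_cells(back), 0)
  expect_equal(n_genes(back), n_genes(sim$atlas))
})
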
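# shared simulated dataset (defaults of synthetic_spec), normalised, lineage
# assigned, markers computed once; memoised so every test file reuses it
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- simulate_atlas(synthetic_spec(seed = 101))
      s$atlas <- assign_lineage(normalize_atlas(s$atlas))
      s$markers <- find_all_markers(s$atlas)
      cache <<- s
    }
    cache
  }
})

# hand-built atlas from a plain counts matrix
make_atlas <- function(counts, cluster = rep("c1", nrow(counts)),
                       sex = rep("mixed", nrow(counts)),
                       sample = rep("s1", nrow(counts)),
                       gene_class = rep("other", ncol(counts)),
                       tf_class = rep("none", ncol(counts))) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  atlas_experiment(
    counts,
    tibble::tibble(cell_id = rownames(counts), sample = sample, sex = sex,
                   cluster = cluster, lineage = "unassigned"),
    tibble::tibble(gene_id = colnames(counts), gene_class = gene_class,
                   tf_class = tf_class))
}

# binary matrix with n rows of which exactly n_singletons occur once;
# the remaining rows are duplicated within groups of two (one group of
# three when the remainder is odd)
make_code_matrix <- function(n, n_singletons) {
  n_dup <- n - n_singletons
  stopifnot(n_dup == 0 || n_dup >= 2)
  sizes <- integer(0)
  if (n_dup > 0) {
    sizes <- rep(2L, n_dup %/% 2)
    if (n_dup %% 2 == 1) sizes[length(sizes)] <- 3L
  }
  width <- ceiling(log2(n_singletons + length(sizes) + 2))
  as_bits <- function(i) as.integer(intToBits(i)[seq_len(width)])
  codes <- c(lapply(seq_len(n_singletons), as_bits),
             unlist(lapply(seq_along(sizes), function(g) {
               rep(list(as_bits(n_singletons + g)), sizes[g])
             }), recursive = FALSE))
  m <- do.call(rbind, codes)
  rownames(m) <- sprintf("cl%03d", seq_len(nrow(m)))
  m
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
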
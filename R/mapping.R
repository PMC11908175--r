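#' Map clusters to cell types by correlation with bulk profiles
#'
#' Correlates each cluster's mean log-normalised expression vector with each
#' bulk-profiled cell type's log-transformed expression vector over the
#' shared gene set, and assigns every cluster to the cell type with the
#' highest coefficient. The full coefficient matrix is returned for heatmap
#' rendering; ties at the maximum are broken lexicographically and flagged.
#'
#' @param profile a [cluster_profile()].
#' @param bulk a genes x cell-type matrix (or data frame with gene
#'   rownames / a `gene` column) of non-negative bulk expression values;
#'   log1p is applied internally.
#' @param method `"pearson"` or `"spearman"`.
#' @param gene_set `"intersection"` (all shared genes) or `"hvg"` (the
#'   `n_hvg` shared genes most variable across clusters).
#' @param n_hvg number of variable genes for `gene_set = "hvg"`.
#' @return a `mapping_result`: list with `result`, a tibble (`cluster`,
#'   `cell_type`, `method`, `score`, `assigned`, `tied`), and `matrix`,
#'   the cell-type x cluster coefficient matrix.
#' @export
bulk_correlation_map <- function(profile, bulk,
                                 method = c("pearson", "spearman"),
                                 gene_set = c("intersection", "hvg"),
                                 n_hvg = 500) {
  method <- match.arg(method)
  gene_set <- match.arg(gene_set)
  stopifnot(inherits(profile, "cluster_profile"))
  if (is.data.frame(bulk)) {
    bulk <- tibble::as_tibble(bulk)
    if ("gene" %in% names(bulk)) {
      genes <- bulk$gene
      bulk <- as.matrix(bulk[setdiff(names(bulk), "gene")])
      rownames(bulk) <- genes
    } else {
      bulk <- as.matrix(bulk)
    }
  }
  if (any(bulk < 0)) stop("bulk profiles must be non-negative", call. = FALSE)
  shared <- intersect(colnames(profile$mean_lognorm), rownames(bulk))
  if (length(shared) < 10) {
    stop(sprintf("only %d genes shared between atlas and bulk profiles (need >= 10)",
                 length(shared)), call. = FALSE)
  }
  if (gene_set == "hvg") {
    v <- apply(profile$mean_lognorm[, shared, drop = FALSE], 2, stats::var)
    shared <- shared[order(-v, shared)][seq_len(min(n_hvg, length(shared)))]
  }
  sc <- t(profile$mean_lognorm[, shared, drop = FALSE])   # genes x clusters
  bk <- log1p(bulk[shared, , drop = FALSE])               # genes x cell types
  r <- suppressWarnings(stats::cor(bk, sc, method = method))
  r[is.na(r)] <- 0                                        # zero-variance rule
  result <- purrr::map_dfr(colnames(sc), function(cl) {
    scores <- r[, cl]
    best <- max(scores)
    winners <- sort(names(scores)[scores == best])
    tibble::tibble(cluster = cl, cell_type = names(scores),
                   method = "bulk_correlation", score = unname(scores),
                   assigned = names(scores) == winners[1],
                   tied = names(scores) %in% winners & length(winners) > 1)
  })
  structure(list(result = result, matrix = r, cor_method = method,
                 n_genes = length(shared)),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %d clusters x %d cell types (%s, %d genes)\n",
              ncol(x$matrix), nrow(x$matrix), x$cor_method, x$n_genes))
  print(dplyr::filter(x$result, .data$assigned))
  invisible(x)
}

#' @export
tidy.mapping_result <- function(x, ...) x$result

#' Assign clusters by split-driver enhancer-gene expression
#'
#' A cluster qualifies for a split-Gal4 driver (and thereby its labelled
#' neuron type) when the scaled average expression of *every* enhancer gene
#' of that driver is positive, i.e. above the cross-cluster mean. Several
#' clusters may qualify for one driver and one cluster for several drivers;
#' all qualifying combinations are reported.
#'
#' @param profile a [cluster_profile()].
#' @param driver_table a data frame with columns `driver`, `cell_type` and
#'   `genes` (a list-column of enhancer gene IDs), or a named list
#'   `driver -> list(cell_type =, genes =)`.
#' @return a tibble (`driver`, `cell_type`, `cluster`, `method`, `score`,
#'   `assigned`): one row per qualifying (driver, cluster) pair, `score`
#'   the number of enhancer genes with positive scaled average (equal to
#'   the gene-list length for qualifying rows).
#' @export
enhancer_gene_assignment <- function(profile, driver_table) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (!is.data.frame(driver_table)) {
    driver_table <- purrr::imap_dfr(driver_table, function(d, nm) {
      tibble::tibble(driver = nm, cell_type = d$cell_type,
                     genes = list(d$genes))
    })
  }
  driver_table <- tibble::as_tibble(driver_table)
  for (i in seq_len(nrow(driver_table))) {
    genes <- driver_table$genes[[i]]
    if (!length(genes)) {
      stop(sprintf("driver '%s' has an empty enhancer gene list",
                   driver_table$driver[i]), call. = FALSE)
    }
    absent <- setdiff(genes, colnames(profile$scaled_avg))
    if (length(absent)) {
      stop(sprintf("driver '%s': enhancer gene(s) absent from profile: %s",
                   driver_table$driver[i], paste(absent, collapse = ", ")),
           call. = FALSE)
    }
  }
  purrr::pmap_dfr(driver_table, function(driver, cell_type, genes, ...) {
    sa <- profile$scaled_avg[, genes, drop = FALSE]
    n_pos <- rowSums(sa > 0)
    tibble::tibble(driver = driver, cell_type = cell_type,
                   cluster = rownames(sa), method = "enhancer_genes",
                   score = unname(n_pos),
                   assigned = unname(n_pos == length(genes)))
  }) |>
    dplyr::filter(.data$assigned)
}

#' Assign clusters by boolean marker logic
#'
#' Evaluates a marker predicate — a list of genes each required positive or
#' negative — against every cluster. A positive gene passes when at least
#' `min_frac_pos` of the cluster's cells have counts >= 1; a negative gene
#' when at most `max_frac_neg` do. A cluster is returned when every
#' condition passes (e.g. a `toy`+ `run`- predicate picking out PF-R-like
#' clusters).
#'
#' @param atlas an [atlas_experiment()].
#' @param predicate a data frame (`gene`, `state` in `"positive"` /
#'   `"negative"`), or a named character vector like
#'   `c(toy = "+", run = "-")`.
#' @param min_frac_pos detection-fraction threshold for positive genes.
#' @param max_frac_neg detection-fraction ceiling for negative genes.
#' @return a tibble (`cluster`, `n_satisfied`, `assigned`) with one row per
#'   cluster, `assigned` marking the clusters matching the full predicate.
#' @export
marker_logic_assignment <- function(atlas, predicate, min_frac_pos = 0.5,
                                    max_frac_neg = 0.1) {
  if (!is.data.frame(predicate)) {
    predicate <- tibble::tibble(
      gene = names(predicate),
      state = ifelse(predicate %in% c("+", "positive"), "positive",
                     "negative"))
  }
  predicate <- tibble::as_tibble(predicate)
  if (!nrow(predicate)) stop("empty predicate", call. = FALSE)
  if (anyDuplicated(predicate$gene)) {
    stop("a gene appears twice in the predicate", call. = FALSE)
  }
  absent <- setdiff(predicate$gene, atlas$gene_meta$gene_id)
  if (length(absent)) {
    stop("predicate gene(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  det <- atlas$counts[, predicate$gene, drop = FALSE] >= 1
  frac <- rowsum(as.matrix(det) * 1, atlas$cell_meta$cluster)
  frac <- frac / as.vector(table(atlas$cell_meta$cluster)[rownames(frac)])
  pass <- matrix(FALSE, nrow(frac), nrow(predicate),
                 dimnames = list(rownames(frac), predicate$gene))
  for (i in seq_len(nrow(predicate))) {
    pass[, i] <- if (predicate$state[i] == "positive") {
      frac[, i] >= min_frac_pos
    } else {
      frac[, i] <= max_frac_neg
    }
  }
  tibble::tibble(cluster = rownames(frac),
                 n_satisfied = rowSums(pass),
                 assigned = rowSums(pass) == nrow(predicate)) |>
    dplyr::arrange(.data$cluster)
}
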
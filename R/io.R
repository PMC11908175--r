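#' Read a dataset written by [write_atlas_dataset()]
#'
#' Expects `matrix.mtx` plus `genes.tsv` and `cells.tsv` in `dir`. Cluster
#' labels are consumed from the `true_cluster` (or `cluster`) column of
#' `cells.tsv`; no normalisation is applied.
#'
#' @param dir directory containing the dataset.
#' @return an [atlas_experiment()] with the counts layer only.
#' @export
read_atlas_dataset <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing dataset files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  counts <- Matrix::readMM(paths[1])
  genes <- readr::read_tsv(paths[2], col_types = readr::cols(
    .default = readr::col_character()))
  cells <- readr::read_tsv(paths[3], col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(genes) != ncol(counts)) {
    stop(sprintf("genes.tsv has %d rows but matrix.mtx declares %d genes",
                 nrow(genes), ncol(counts)), call. = FALSE)
  }
  if (nrow(cells) != nrow(counts)) {
    stop(sprintf("cells.tsv has %d rows but matrix.mtx declares %d cells",
                 nrow(cells), nrow(counts)), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("genes.tsv contains duplicated gene_id values", call. = FALSE)
  }
  if ("true_cluster" %in% names(cells) && !"cluster" %in% names(cells)) {
    cells$cluster <- cells$true_cluster
    cells$true_cluster <- NULL
  }
  atlas_experiment(counts, cells, genes)
}

#' Quality-control filter on detected genes and mitochondrial fraction
#'
#' Retains cells with a detected-gene count within `[min_genes, max_genes]`
#' (inclusive) and a mitochondrial read fraction no greater than `max_mito`.
#' The defaults encode the standard thresholds for adult fly brain nuclei:
#' cells with fewer than 200 or more than 2,500 genes expressed, or more
#' than 5% mitochondrial RNA, are removed. Mitochondrial genes are the rows
#' of `gene_meta` with `gene_class == "mito"`; if none are annotated the
#' mito criterion is skipped with a warning and recorded in the report.
#'
#' A cell failing several criteria is tallied under its first failure, in
#' the order low-genes, high-genes, mito.
#'
#' @param atlas an [atlas_experiment()].
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito maximum mitochondrial read fraction.
#' @return a list with `atlas` (the filtered experiment) and `report`, a
#'   `qc_report` with [generics::tidy()] and [generics::glance()] methods.
#' @export
qc_filter <- function(atlas, min_genes = 200, max_genes = 2500,
                      max_mito = 0.05) {
  counts <- atlas$counts
  detected <- Matrix::rowSums(counts > 0)
  mito_genes <- atlas$gene_meta$gene_id[atlas$gene_meta$gene_class == "mito"]
  mito_skipped <- length(mito_genes) == 0
  if (mito_skipped) {
    warning("no mitochondrial genes annotated; mito criterion skipped")
    mito_frac <- rep(0, nrow(counts))
  } else {
    depth <- Matrix::rowSums(counts)
    mito_frac <- ifelse(depth > 0,
                        Matrix::rowSums(counts[, mito_genes, drop = FALSE]) /
                          pmax(depth, 1), 0)
  }
  fail_low <- detected < min_genes
  fail_high <- !fail_low & detected > max_genes
  fail_mito <- !fail_low & !fail_high & mito_frac > max_mito
  keep <- !(fail_low | fail_high | fail_mito)
  report <- structure(
    list(n_input_cells = nrow(counts),
         n_pass = sum(keep),
         n_fail_low_genes = sum(fail_low),
         n_fail_high_genes = sum(fail_high),
         n_fail_mito = sum(fail_mito),
         mito_skipped = mito_skipped,
         thresholds = c(min_genes = min_genes, max_genes = max_genes,
                        max_mito_fraction = max_mito)),
    class = "qc_report")
  list(atlas = subset_cells(atlas, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d cells in, %d pass; removed: %d low-genes, %d high-genes, %d mito%s\n",
    x$n_input_cells, x$n_pass, x$n_fail_low_genes, x$n_fail_high_genes,
    x$n_fail_mito, if (x$mito_skipped) " (mito criterion skipped)" else ""))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(
    criterion = c("pass", "low_genes", "high_genes", "mito"),
    n_cells = c(x$n_pass, x$n_fail_low_genes, x$n_fail_high_genes,
                x$n_fail_mito))
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_input_cells = x$n_input_cells, n_pass = x$n_pass,
                 min_genes = x$thresholds[["min_genes"]],
                 max_genes = x$thresholds[["max_genes"]],
                 max_mito_fraction = x$thresholds[["max_mito_fraction"]],
                 mito_skipped = x$mito_skipped)
}

#' Depth-normalise and z-scale an expression matrix
#'
#' Computes `lognorm[i, j] = log(1 + scale_factor * counts[i, j] / depth_i)`
#' where `depth_i` is the cell's total counts, then `scaled` as the per-gene
#' z-score of `lognorm` across cells (sample SD; genes with zero variance
#' map to 0). Cells with zero depth get a zero `lognorm` row with a warning.
#'
#' @param atlas an [atlas_experiment()].
#' @param scale_factor target depth per cell before the log1p.
#' @return the atlas with `lognorm` and `scaled` layers attached.
#' @export
normalize_atlas <- function(atlas, scale_factor = 1e4) {
  counts <- atlas$counts
  depth <- Matrix::rowSums(counts)
  if (any(depth == 0)) {
    warning(sum(depth == 0), " cell(s) with zero depth; lognorm rows set to 0")
  }
  safe_depth <- ifelse(depth == 0, 1, depth)
  lognorm <- as.matrix(log1p(scale_factor * counts / safe_depth))
  mu <- colMeans(lognorm)
  sd <- apply(lognorm, 2, stats::sd)
  scaled <- sweep(lognorm, 2, mu, "-")
  scaled <- sweep(scaled, 2, ifelse(sd > 0, sd, 1), "/")
  scaled[, sd == 0] <- 0
  atlas$lognorm <- lognorm
  atlas$scaled <- scaled
  atlas
}

#' Assign lineage from lineage-tracing transgene expression
#'
#' Cells with at least `min_counts` reads of any lineage-tracing transgene
#' (by default `FLP`, `GFP`, `RFP`) are assigned to the T2 lineage; all
#' triple-negative cells are assigned T1. The partition is exhaustive:
#' every cell receives exactly one of the two labels.
#'
#' @param atlas an [atlas_experiment()].
#' @param transgenes transgene gene IDs.
#' @param min_counts positivity threshold in raw counts.
#' @return the atlas with `cell_meta$lineage` filled in.
#' @export
assign_lineage <- function(atlas, transgenes = c("FLP", "GFP", "RFP"),
                           min_counts = 1) {
  absent <- setdiff(transgenes, atlas$gene_meta$gene_id)
  if (length(absent)) {
    stop("transgene gene(s) absent from the atlas: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pos <- Matrix::rowSums(
    atlas$counts[, transgenes, drop = FALSE] >= min_counts) > 0
  atlas$cell_meta$lineage <- ifelse(pos, "T2", "T1")
  atlas
}

#' Subset clusters by expression of a single gene
#'
#' Retains the cells of every cluster in which the fraction of cells with at
#' least one count of `gene` reaches `min_frac_pos` — the rule used to pull
#' out glial clusters by the pan-glial marker `repo`. Set
#' `complement = TRUE` to retrieve the remaining cells instead (e.g. to
#' filter the glial clusters out and keep a neuronal atlas).
#'
#' @param atlas an [atlas_experiment()].
#' @param gene a gene ID present in the atlas.
#' @param min_frac_pos minimum fraction of cluster cells with counts >= 1.
#' @param complement return the cells of the non-qualifying clusters.
#' @return an [atlas_experiment()]; empty (with a warning) if no cluster
#'   qualifies.
#' @export
subset_by_cluster_gene <- function(atlas, gene, min_frac_pos = 0.5,
                                   complement = FALSE) {
  if (!gene %in% atlas$gene_meta$gene_id) {
    stop(sprintf("gene '%s' not present in the atlas", gene), call. = FALSE)
  }
  pos <- as.numeric(atlas$counts[, gene] >= 1)
  frac <- tapply(pos, atlas$cell_meta$cluster, mean)
  qualifying <- names(frac)[frac >= min_frac_pos]
  if (!length(qualifying) && !complement) {
    warning(sprintf("no cluster reaches %.0f%% positivity for '%s'",
                    100 * min_frac_pos, gene))
  }
  keep <- atlas$cell_meta$cluster %in% qualifying
  if (complement) keep <- !keep
  subset_cells(atlas, keep)
}

#' Sum cell-count bookkeeping tables
#'
#' Atlas assembly bookkeeping: given a table with one row per input batch,
#' sample or lineage stratum and a count column, returns per-group totals
#' and the overall total. Used to check that published partition counts add
#' up (e.g. per-sample nucleus counts against an atlas total).
#'
#' @param tbl a data frame.
#' @param count column holding the counts (default `n`).
#' @param ... optional grouping columns (tidy-select); with no groups a
#'   single overall row is returned.
#' @return a tibble with the grouping columns and `total`.
#' @export
composition_totals <- function(tbl, ..., count = "n") {
  tbl <- tibble::as_tibble(tbl)
  if (!count %in% names(tbl)) {
    stop(sprintf("count column '%s' not found", count), call. = FALSE)
  }
  groups <- rlang::enquos(...)
  if (length(groups)) {
    tbl |>
      dplyr::group_by(!!!groups) |>
      dplyr::summarise(total = sum(.data[[count]]), .groups = "drop")
  } else {
    tibble::tibble(total = sum(tbl[[count]]))
  }
}

#' Tally lineage composition of an atlas
#'
#' @param atlas an [atlas_experiment()] with lineage assigned.
#' @return a tibble (`lineage`, `n`) plus an attached total attribute.
#' @export
lineage_composition <- function(atlas) {
  out <- atlas$cell_meta |>
    dplyr::count(.data$lineage) |>
    dplyr::arrange(.data$lineage)
  attr(out, "n_total") <- nrow(atlas$cell_meta)
  out
}
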
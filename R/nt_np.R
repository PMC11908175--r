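#' Classify cells by fast-acting neurotransmitter expression
#'
#' Marks a cell positive for a neurotransmitter pathway gene when its
#' expression in the chosen layer exceeds `threshold`, then partitions the
#' cells into single-class, multi-class (two or more transmitters) and
#' transmitter-negative groups. The default is the z-scaled layer with
#' threshold 2; the log-normalised layer is available through `layer`
#' because both conventions are in use for this classification and they are
#' not equivalent — the choice is surfaced rather than silently resolved.
#'
#' @param atlas a normalised [atlas_experiment()].
#' @param genes the neurotransmitter pathway genes (default [nt_genes()]).
#' @param threshold positivity threshold on the chosen layer.
#' @param layer `"scaled"` or `"lognorm"`.
#' @return a list with `profiles` (tibble: `cell_id`, one logical column per
#'   gene, `n_classes`) and `summary`, an `nt_summary` object carrying
#'   per-gene positivity counts/percentages, UpSet-style combination counts,
#'   and the single/multi/negative percentages (reported to one decimal;
#'   exact fractions kept alongside).
#' @export
classify_neurotransmitters <- function(atlas, genes = nt_genes(),
                                       threshold = 2,
                                       layer = c("scaled", "lognorm")) {
  layer <- match.arg(layer)
  absent <- setdiff(genes, atlas$gene_meta$gene_id)
  if (length(absent)) {
    stop("neurotransmitter gene(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  X <- atlas_layer(atlas, layer)[, genes, drop = FALSE]
  pos <- X > threshold
  profiles <- tibble::as_tibble(pos)
  profiles <- dplyr::mutate(profiles,
                            cell_id = atlas$cell_meta$cell_id,
                            n_classes = rowSums(pos), .before = 1)
  summary <- summarize_nt_profiles(profiles, genes,
                                   threshold = threshold, layer = layer)
  list(profiles = profiles, summary = summary)
}

summarize_nt_profiles <- function(profiles, genes, threshold = NA,
                                  layer = NA) {
  n <- nrow(profiles)
  per_gene <- tibble::tibble(
    gene = genes,
    n_cells = vapply(genes, function(g) sum(profiles[[g]]), integer(1)),
    pct = round_half_up(100 * .data$n_cells / max(n, 1), 1))
  frac <- c(single = mean(profiles$n_classes == 1),
            multi = mean(profiles$n_classes >= 2),
            negative = mean(profiles$n_classes == 0))
  structure(
    list(n_cells = n,
         per_gene = per_gene,
         combinations = upset_counts(profiles),
         fractions = frac,
         pct_single = round_half_up(100 * frac[["single"]], 1),
         pct_multi = round_half_up(100 * frac[["multi"]], 1),
         pct_negative = round_half_up(100 * frac[["negative"]], 1),
         threshold = threshold, layer = layer),
    class = "nt_summary")
}

#' @export
print.nt_summary <- function(x, ...) {
  cat(sprintf(
    "<nt_summary> %d cells (layer %s > %s): %.1f%% single, %.1f%% multi, %.1f%% negative\n",
    x$n_cells, x$layer, format(x$threshold), x$pct_single, x$pct_multi,
    x$pct_negative))
  print(x$per_gene)
  invisible(x)
}

#' @export
tidy.nt_summary <- function(x, ...) x$combinations

#' @export
glance.nt_summary <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, pct_single = x$pct_single,
                 pct_multi = x$pct_multi, pct_negative = x$pct_negative,
                 threshold = x$threshold, layer = x$layer)
}

#' UpSet-style combination counts
#'
#' Counts cells per observed positivity combination. Combination labels
#' join the positive genes with `+` in the input gene-column order;
#' all-negative cells are labelled `"none"`. Counts sum to the number of
#' cells.
#'
#' @param profiles the `profiles` tibble from
#'   [classify_neurotransmitters()] (logical gene columns).
#' @return a tibble (`combination`, `n_positive`, `count`) sorted by
#'   decreasing count.
#' @export
upset_counts <- function(profiles) {
  genes <- names(profiles)[vapply(profiles, is.logical, logical(1))]
  bits <- as.matrix(profiles[, genes, drop = FALSE])
  combo <- apply(bits, 1, function(b) {
    if (!any(b)) "none" else paste(genes[b], collapse = "+")
  })
  tibble::tibble(combination = combo, n_positive = rowSums(bits)) |>
    dplyr::count(.data$combination, .data$n_positive, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$combination)
}

#' Identify cluster-defining neuropeptides
#'
#' A neuropeptide gene is cluster-defining when it is a significant positive
#' marker (per [find_all_markers()] at `alpha`) in at least one and at most
#' `max_clusters` clusters — i.e. its expression is enriched in a limited
#' number of clusters, making it usable as a cluster marker. The mapping is
#' many-to-many: one cluster may carry several defining neuropeptides and
#' one neuropeptide may define several clusters.
#'
#' @param atlas a normalised [atlas_experiment()].
#' @param np_genes neuropeptide gene IDs (default: `gene_meta` rows with
#'   `gene_class == "neuropeptide"`). Genes absent from the atlas are
#'   skipped with a warning.
#' @param max_clusters maximum number of clusters a defining neuropeptide
#'   may mark.
#' @param alpha adjusted-p threshold for marker significance.
#' @param markers optional precomputed `marker_table` over the same
#'   clusters (saves recomputation); must include the neuropeptide genes.
#' @return a tibble (`neuropeptide`, `n_clusters`, `clusters` list-column)
#'   with one row per qualifying neuropeptide. The `max_clusters` and
#'   `alpha` used are attached as attributes.
#' @export
cluster_defining_neuropeptides <- function(atlas, np_genes = NULL,
                                           max_clusters = 4, alpha = 0.05,
                                           markers = NULL) {
  if (is.null(np_genes)) {
    np_genes <- atlas$gene_meta$gene_id[
      atlas$gene_meta$gene_class == "neuropeptide"]
  }
  absent <- setdiff(np_genes, atlas$gene_meta$gene_id)
  if (length(absent)) {
    warning("neuropeptide gene(s) absent, skipped: ",
            paste(absent, collapse = ", "))
    np_genes <- setdiff(np_genes, absent)
  }
  if (is.null(markers)) {
    markers <- find_all_markers(atlas, only_pos = TRUE, genes = np_genes)
  }
  out <- markers |>
    tibble::as_tibble() |>
    dplyr::filter(.data$gene %in% np_genes, .data$direction == "up",
                  .data$p_adj < alpha) |>
    dplyr::group_by(neuropeptide = .data$gene) |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(.data$cluster),
                     clusters = list(sort(unique(.data$cluster))),
                     .groups = "drop") |>
    dplyr::filter(.data$n_clusters >= 1, .data$n_clusters <= max_clusters)
  attr(out, "max_clusters") <- max_clusters
  attr(out, "alpha") <- alpha
  out
}

#' Correlate transcription factors with neuropeptides across cells
#'
#' Computes the correlation of every (TF, neuropeptide) gene pair across all
#' cells on the log-normalised layer and ranks, per neuropeptide, the
#' `top_k` most strongly correlated TFs. Zero-variance genes yield a
#' coefficient of 0 by convention; ties in the ranking are broken by
#' lexicographic TF ID. Single-cell correlations on sparse counts are
#' descriptive: they suggest candidate regulators, they do not establish
#' regulation.
#'
#' @param atlas a normalised [atlas_experiment()] with >= 3 cells.
#' @param tf_genes,np_genes gene-ID vectors (defaults: `gene_meta` classes
#'   `"tf"` and `"neuropeptide"`).
#' @param method `"pearson"` or `"spearman"`.
#' @param top_k TFs to rank per neuropeptide.
#' @return an `np_correlation`: list with `matrix` (TFs x neuropeptides)
#'   and `top`, a tibble (`neuropeptide`, `rank`, `tf`, `coefficient`).
#' @export
tf_np_correlation <- function(atlas, tf_genes = NULL, np_genes = NULL,
                              method = c("pearson", "spearman"),
                              top_k = 5) {
  method <- match.arg(method)
  if (n_cells(atlas) < 3) stop("need at least 3 cells", call. = FALSE)
  if (is.null(tf_genes)) {
    tf_genes <- atlas$gene_meta$gene_id[atlas$gene_meta$gene_class == "tf"]
  }
  if (is.null(np_genes)) {
    np_genes <- atlas$gene_meta$gene_id[
      atlas$gene_meta$gene_class == "neuropeptide"]
  }
  X <- atlas_layer(atlas, "lognorm")
  cors <- suppressWarnings(
    stats::cor(X[, tf_genes, drop = FALSE], X[, np_genes, drop = FALSE],
               method = method))
  cors[is.na(cors)] <- 0
  top <- purrr::map_dfr(np_genes, function(np) {
    ord <- order(-cors[, np], tf_genes)
    k <- min(top_k, length(tf_genes))
    tibble::tibble(neuropeptide = np, rank = seq_len(k),
                   tf = tf_genes[ord[seq_len(k)]],
                   coefficient = cors[ord[seq_len(k)], np])
  })
  structure(list(matrix = cors, top = top, method = method),
            class = "np_correlation")
}

#' @export
print.np_correlation <- function(x, ...) {
  cat(sprintf("<np_correlation> %d TFs x %d neuropeptides (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$method))
  print(x$top)
  invisible(x)
}

#' @export
tidy.np_correlation <- function(x, ...) x$top
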
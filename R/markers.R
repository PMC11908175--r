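#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, tests each gene's log-normalised expression in the
#' cluster against all remaining cells with a two-sided Wilcoxon rank-sum
#' test (tie-corrected normal approximation with continuity correction,
#' equivalent to `wilcox.test(exact = FALSE, correct = TRUE)`). Genes whose
#' detection fraction is below `min_pct` in both groups, or whose absolute
#' log2 fold-change is below `min_log2fc`, are excluded before testing;
#' Benjamini-Hochberg adjustment is applied per cluster over the tested set.
#'
#' The fold-change follows the single-cell convention
#' `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` on the
#' log-normalised layer, so results are directly comparable with the usual
#' cluster-marker tables of the field.
#'
#' @param atlas an [atlas_experiment()] with the `lognorm` layer and at
#'   least two clusters.
#' @param only_pos keep only up-regulated (positive) markers.
#' @param min_pct minimum detection fraction in at least one group.
#' @param min_log2fc minimum absolute log2 fold-change.
#' @param genes optional gene-ID subset to test (default: all genes).
#' @return a `marker_table` tibble with columns `cluster`, `gene`,
#'   `log2fc`, `pct_in`, `pct_out`, `p_value`, `p_adj`, `direction`.
#'   Clusters with fewer than 3 cells are skipped with a warning.
#' @export
find_all_markers <- function(atlas, only_pos = TRUE, min_pct = 0.1,
                             min_log2fc = 0.25, genes = NULL) {
  if (is.null(atlas$lognorm)) {
    stop("lognorm layer missing; run normalize_atlas() first", call. = FALSE)
  }
  clusters <- sort(unique(atlas$cell_meta$cluster))
  if (length(clusters) < 2) {
    return(empty_marker_table(clusters))
  }
  X <- atlas$lognorm
  if (!is.null(genes)) X <- X[, intersect(colnames(X), genes), drop = FALSE]
  detected <- atlas$counts[, colnames(X), drop = FALSE] > 0
  n <- nrow(X)

  # one-vs-rest ranks are over all cells, so rank once per gene
  ranks <- apply(X, 2, rank)
  tie_term <- apply(X, 2, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  expm1_X <- expm1(X)

  res <- purrr::map_dfr(clusters, function(cl) {
    idx <- atlas$cell_meta$cluster == cl
    n1 <- sum(idx)
    if (n1 < 3) {
      warning(sprintf("cluster '%s' has %d cells (<3); skipped", cl, n1))
      return(NULL)
    }
    n2 <- n - n1
    pct_in <- Matrix::colMeans(detected[idx, , drop = FALSE])
    pct_out <- Matrix::colMeans(detected[!idx, , drop = FALSE])
    mean_in <- colMeans(expm1_X[idx, , drop = FALSE])
    mean_out <- colMeans(expm1_X[!idx, , drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    test <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(log2fc) >= min_log2fc
    if (!any(test)) return(NULL)
    U <- colSums(ranks[idx, test, drop = FALSE]) - n1 * (n1 + 1) / 2
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - tie_term[test] / (n * (n - 1)))
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- ifelse(sigma2 <= 0, 1, pmin(1, 2 * stats::pnorm(-abs(z))))
    lfc_tested <- unname(log2fc[test])
    tibble::tibble(
      cluster = cl,
      gene = colnames(X)[test],
      log2fc = lfc_tested,
      pct_in = unname(pct_in[test]),
      pct_out = unname(pct_out[test]),
      p_value = unname(p),
      p_adj = stats::p.adjust(unname(p), method = "BH"),
      direction = ifelse(lfc_tested > 0, "up", "down"))
  })
  if (!nrow(res)) return(empty_marker_table(clusters))
  if (only_pos) res <- dplyr::filter(res, .data$direction == "up")
  new_marker_table(res, clusters)
}

empty_marker_table <- function(clusters) {
  new_marker_table(
    tibble::tibble(cluster = character(), gene = character(),
                   log2fc = double(), pct_in = double(), pct_out = double(),
                   p_value = double(), p_adj = double(),
                   direction = character()),
    clusters)
}

new_marker_table <- function(tbl, clusters) {
  attr(tbl, "clusters") <- clusters
  class(tbl) <- c("marker_table", class(tbl))
  tbl
}

#' Per-cluster expression profiles with scaled averages
#'
#' Averages the log-normalised layer within each cluster, then z-scores
#' every gene's cluster means across clusters (sample SD; zero-variance
#' genes map to 0). The z-scored matrix is the "scaled average expression"
#' used for marker heatmaps and enhancer-gene scoring.
#'
#' @param atlas an [atlas_experiment()] with `lognorm` and cluster labels.
#' @return a `cluster_profile`: list with matrices `mean_lognorm` and
#'   `scaled_avg` (clusters x genes) and the cluster label vector.
#' @export
cluster_profile <- function(atlas) {
  if (is.null(atlas$lognorm)) {
    stop("lognorm layer missing; run normalize_atlas() first", call. = FALSE)
  }
  cl <- factor(atlas$cell_meta$cluster)
  mean_ln <- rowsum(atlas$lognorm, cl) / as.vector(table(cl))
  sd <- apply(mean_ln, 2, stats::sd)
  scaled <- sweep(sweep(mean_ln, 2, colMeans(mean_ln), "-"),
                  2, ifelse(sd > 0, sd, 1), "/")
  scaled[, sd == 0 | is.na(sd)] <- 0
  structure(list(mean_lognorm = mean_ln, scaled_avg = scaled,
                 clusters = levels(cl)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d clusters x %d genes\n",
              nrow(x$mean_lognorm), ncol(x$mean_lognorm)))
  invisible(x)
}

#' @export
tidy.cluster_profile <- function(x, ...) {
  tibble::as_tibble(x$mean_lognorm, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "gene",
                        values_to = "mean_lognorm") |>
    dplyr::left_join(
      tibble::as_tibble(x$scaled_avg, rownames = "cluster") |>
        tidyr::pivot_longer(-"cluster", names_to = "gene",
                            values_to = "scaled_avg"),
      by = c("cluster", "gene"))
}

#' Top markers per cluster
#'
#' For each cluster, the `n` up-regulated markers with the largest log2
#' fold-change among records with `p_adj < alpha`; ties are broken by
#' smaller adjusted p-value, then lexicographic gene ID. Clusters with
#' fewer than `n` qualifying genes return all of them.
#'
#' @param table a `marker_table` from [find_all_markers()].
#' @param n markers to keep per cluster.
#' @param alpha adjusted-p significance threshold.
#' @return a tibble with the selected `marker_table` rows plus `rank`.
#' @export
top_markers <- function(table, n = 10, alpha = 0.05) {
  table |>
    tibble::as_tibble() |>
    dplyr::filter(.data$direction == "up", .data$p_adj < alpha) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$log2fc), .data$p_adj,
                   .data$gene) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_head(n = n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
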
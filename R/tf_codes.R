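#' Binarise TF markers into a combinatorial-code matrix
#'
#' Builds the clusters-by-TFs 0/1 matrix for one DNA-binding-domain class:
#' entry (c, t) is 1 exactly when TF t is a significant up-regulated marker
#' of cluster c (`p_adj < alpha` in the supplied marker table). TFs that are
#' a marker in no cluster are dropped (all-zero columns removed); clusters
#' with no significant TF keep an all-zero row.
#'
#' @param table a `marker_table` from [find_all_markers()].
#' @param gene_meta the atlas gene metadata (`gene_id`, `tf_class`).
#' @param tf_class one of [tf_classes()].
#' @param alpha adjusted-p significance threshold.
#' @param clusters cluster label set for the rows; defaults to the cluster
#'   set the marker table was computed on.
#' @return a `binary_code_matrix`: list with the 0/1 `matrix`, `tf_class`
#'   and `source_alpha`.
#' @export
binarize_tf_markers <- function(table, gene_meta, tf_class, alpha = 0.05,
                                clusters = NULL) {
  tf_class <- match.arg(tf_class, tf_classes())
  tfs <- gene_meta$gene_id[gene_meta$tf_class == tf_class]
  if (!length(tfs)) {
    stop(sprintf("no genes annotated with tf_class '%s'", tf_class),
         call. = FALSE)
  }
  if (is.null(clusters)) clusters <- attr(table, "clusters")
  if (is.null(clusters)) clusters <- sort(unique(table$cluster))
  hits <- table |>
    tibble::as_tibble() |>
    dplyr::filter(.data$gene %in% tfs, .data$direction == "up",
                  .data$p_adj < alpha)
  m <- matrix(0L, length(clusters), length(tfs),
              dimnames = list(clusters, sort(tfs)))
  if (nrow(hits)) m[cbind(hits$cluster, hits$gene)] <- 1L
  m <- m[, colSums(m) > 0, drop = FALSE]
  structure(list(matrix = m, tf_class = tf_class, source_alpha = alpha),
            class = "binary_code_matrix")
}

#' @export
print.binary_code_matrix <- function(x, ...) {
  cat(sprintf("<binary_code_matrix> %s: %d clusters x %d TFs (alpha = %g)\n",
              x$tf_class, nrow(x$matrix), ncol(x$matrix), x$source_alpha))
  invisible(x)
}

#' @export
tidy.binary_code_matrix <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "tf", values_to = "bit") |>
    dplyr::mutate(tf_class = x$tf_class, .before = 1)
}

#' Uniqueness statistics of a binary code matrix
#'
#' A cluster's code is "unique" when no other cluster has an identical row
#' (the all-zero code included: two codeless clusters are mutual
#' duplicates). The percentage of unique clusters is rounded half-up to one
#' decimal.
#'
#' @param codes a `binary_code_matrix` (or a plain 0/1 matrix with cluster
#'   rownames).
#' @return a `code_stats`: list with `n_clusters`, `n_unique`,
#'   `pct_unique` and `duplicate_groups` (list of cluster-label vectors
#'   sharing a code).
#' @export
unique_code_stats <- function(codes) {
  m <- if (inherits(codes, "binary_code_matrix")) codes$matrix else codes
  if (!nrow(m)) stop("code matrix has no clusters", call. = FALSE)
  key <- apply(m, 1, paste, collapse = "")
  tab <- table(key)
  unique_keys <- names(tab)[tab == 1]
  dup_keys <- names(tab)[tab > 1]
  groups <- lapply(dup_keys, function(k) rownames(m)[key == k])
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  structure(
    list(n_clusters = nrow(m),
         n_unique = sum(key %in% unique_keys),
         pct_unique = round_half_up(100 * sum(key %in% unique_keys) /
                                      nrow(m), 1),
         duplicate_groups = groups,
         tf_class = if (inherits(codes, "binary_code_matrix"))
           codes$tf_class else NA_character_),
    class = "code_stats")
}

#' @export
print.code_stats <- function(x, ...) {
  cat(sprintf("<code_stats>%s %d/%d clusters unique (%.1f%%), %d duplicate group(s)\n",
              if (is.na(x$tf_class)) "" else paste0(" ", x$tf_class, ":"),
              x$n_unique, x$n_clusters, x$pct_unique,
              length(x$duplicate_groups)))
  invisible(x)
}

#' @export
tidy.code_stats <- function(x, ...) {
  if (!length(x$duplicate_groups)) {
    return(tibble::tibble(group = integer(), cluster = character()))
  }
  tibble::tibble(group = seq_along(x$duplicate_groups),
                 cluster = x$duplicate_groups) |>
    tidyr::unnest("cluster")
}

#' @export
glance.code_stats <- function(x, ...) {
  tibble::tibble(tf_class = x$tf_class, n_clusters = x$n_clusters,
                 n_unique = x$n_unique, pct_unique = x$pct_unique,
                 n_duplicate_groups = length(x$duplicate_groups))
}

#' Jaccard similarity and ordering of cluster codes
#'
#' Computes the pairwise Jaccard index between cluster rows of a binary
#' code matrix — `J(a, b) = |a AND b| / |a OR b|`, with `J = 0` when both
#' rows are all-zero so that codeless clusters never drive the ordering —
#' and sorts the clusters from most to least similar by the leaf order of
#' average-linkage hierarchical clustering on distance `1 - J`. Rows are
#' processed in lexicographic cluster-label order, which fixes tie-breaking
#' and makes the ordering deterministic.
#'
#' @param codes a `binary_code_matrix` (or a plain 0/1 matrix with cluster
#'   rownames).
#' @param order_method `"average_linkage"` (leaf order of average-linkage
#'   clustering) or `"greedy_chain"` (start at the pair with highest J,
#'   repeatedly append the cluster most similar to the last one).
#' @return a `jaccard_ordering`: list with the symmetric `similarity`
#'   matrix (original row order) and `order`, the cluster-label
#'   permutation.
#' @export
jaccard_ordering <- function(codes,
                             order_method = c("average_linkage",
                                              "greedy_chain")) {
  order_method <- match.arg(order_method)
  m <- if (inherits(codes, "binary_code_matrix")) codes$matrix else codes
  if (!nrow(m)) stop("code matrix has no clusters", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  inter <- m %*% t(m)
  size <- rowSums(m)
  union <- outer(size, size, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  diag(J) <- ifelse(size > 0, 1, 0)
  dimnames(J) <- list(rownames(m), rownames(m))
  if (nrow(m) == 1) {
    ord <- rownames(m)
  } else if (order_method == "average_linkage") {
    hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
    ord <- rownames(m)[hc$order]
  } else {
    labs <- rownames(m)
    Jw <- J; diag(Jw) <- -Inf
    start <- arrayInd(which.max(Jw), dim(Jw))[1, ]
    ord <- labs[start]
    remaining <- setdiff(labs, ord)
    while (length(remaining)) {
      sims <- J[ord[length(ord)], remaining]
      nxt <- remaining[order(-sims, remaining)][1]
      ord <- c(ord, nxt)
      remaining <- setdiff(remaining, nxt)
    }
  }
  structure(list(similarity = J, order = ord, method = order_method),
            class = "jaccard_ordering")
}

#' @export
print.jaccard_ordering <- function(x, ...) {
  cat(sprintf("<jaccard_ordering> %d clusters (%s)\n",
              nrow(x$similarity), x$method))
  invisible(x)
}

#' @export
tidy.jaccard_ordering <- function(x, ...) {
  tibble::as_tibble(x$similarity, rownames = "cluster_a") |>
    tidyr::pivot_longer(-"cluster_a", names_to = "cluster_b",
                        values_to = "jaccard")
}
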
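# two-sided tie-corrected normal-approximation rank-sum p-values for each
# column of X, group 1 vs the rest (matches wilcox.test(exact = FALSE))
ranksum_p <- function(X, idx) {
  n <- nrow(X)
  n1 <- sum(idx)
  n2 <- n - n1
  ranks <- apply(X, 2, rank)
  tie_term <- apply(X, 2, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  U <- colSums(ranks[idx, , drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  ifelse(sigma2 <= 0, 1, pmin(1, 2 * stats::pnorm(-abs(z))))
}

#' Detect sex-biased clusters
#'
#' Compares each cluster's sex composition against the overall composition
#' of the sexed cells. Cells from mixed-sex samples are excluded — their
#' sex of origin cannot be determined — and testing each cluster against
#' the global female fraction is what normalises for unequal female and
#' male sample inputs: under the null a cluster draws its cells from the
#' input pool in proportion.
#'
#' Per cluster, a two-sided binomial test of the female count against the
#' expected female fraction; Benjamini-Hochberg adjustment over clusters.
#' A cluster is called biased when `p_adj < alpha` and the absolute log2
#' odds ratio (observed vs expected, with a 0.5 continuity correction on
#' the observed counts) reaches `min_log2_ratio`.
#'
#' @param atlas an [atlas_experiment()] whose `cell_meta$sex` has at least
#'   one female and one male cell outside mixed samples.
#' @param alpha adjusted-p threshold.
#' @param min_log2_ratio effect-size floor on the |log2 odds ratio|.
#' @return a `sex_bias_report` tibble with one row per cluster: `cluster`,
#'   `n_female`, `n_male`, `expected_female_frac`, `observed_female_frac`,
#'   `log2_ratio`, `p_value`, `p_adj`, `biased` in
#'   `{"female", "male", "none"}`. Excluded (mixed) samples and the
#'   thresholds used are attached as attributes.
#' @export
detect_sex_biased_clusters <- function(atlas, alpha = 0.05,
                                       min_log2_ratio = 1.0) {
  meta <- atlas$cell_meta
  excluded <- unique(meta$sample[meta$sex == "mixed"])
  sexed <- dplyr::filter(meta, .data$sex %in% c("female", "male"))
  if (!nrow(sexed) || dplyr::n_distinct(sexed$sex) < 2) {
    stop("need at least one female and one male cell outside mixed samples",
         call. = FALSE)
  }
  expected <- mean(sexed$sex == "female")
  out <- sexed |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_female = sum(.data$sex == "female"),
                     n_male = sum(.data$sex == "male"), .groups = "drop") |>
    dplyr::mutate(
      expected_female_frac = expected,
      observed_female_frac = .data$n_female / (.data$n_female + .data$n_male),
      log2_ratio = log2(((.data$n_female + 0.5) / (.data$n_male + 0.5)) /
                          (expected / (1 - expected))),
      p_value = purrr::map2_dbl(.data$n_female, .data$n_male, function(f, m) {
        stats::binom.test(f, f + m, p = expected)$p.value
      }),
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      biased = dplyr::case_when(
        .data$p_adj < alpha & .data$log2_ratio >= min_log2_ratio ~ "female",
        .data$p_adj < alpha & .data$log2_ratio <= -min_log2_ratio ~ "male",
        TRUE ~ "none"))
  attr(out, "excluded_samples") <- excluded
  attr(out, "alpha") <- alpha
  attr(out, "min_log2_ratio") <- min_log2_ratio
  class(out) <- c("sex_bias_report", class(out))
  out
}

#' Pseudobulk differential expression between sexes
#'
#' Aggregates counts into pseudobulk units — one per sample for the global
#' scope, one per (sample, cluster) for the per-cluster scope — excludes
#' mixed-sex samples, converts units to log2 CPM (with a pseudocount of 1),
#' and compares female against male units per gene with a two-sided
#' Wilcoxon rank-sum test, Benjamini-Hochberg adjusted per scope.
#'
#' When a side has fewer than two units the replicate-based test is
#' impossible; the function then falls back to a per-cell rank-sum on the
#' log-normalised layer, records the fallback in the output provenance,
#' and warns.
#'
#' @param atlas a normalised [atlas_experiment()].
#' @param scope `"global"` or `"per_cluster"`.
#' @param method `"auto"` (units when >= 2 per sex, else cells),
#'   `"units"`, or `"cells"`.
#' @return a `pseudobulk_de` tibble: `gene`, `log2fc_male_vs_female`,
#'   `p_value`, `p_adj`, `scope`; a provenance tibble (`scope`,
#'   `method_used`, unit counts) is attached as attribute `"provenance"`.
#' @export
pseudobulk_de <- function(atlas, scope = c("global", "per_cluster"),
                          method = c("auto", "units", "cells")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  meta <- atlas$cell_meta
  sexed <- meta$sex %in% c("female", "male")
  if (!any(sexed) || dplyr::n_distinct(meta$sex[sexed]) < 2) {
    stop("need sexed cells of both sexes outside mixed samples",
         call. = FALSE)
  }
  scopes <- if (scope == "global") {
    list(global = rep(TRUE, nrow(meta)))
  } else {
    cls <- sort(unique(meta$cluster))
    stats::setNames(lapply(cls, function(cl) meta$cluster == cl),
                    paste0("cluster:", cls))
  }
  prov <- list()
  res <- purrr::imap_dfr(scopes, function(in_scope, scope_label) {
    keep <- in_scope & sexed
    if (!any(keep)) return(NULL)
    sub_meta <- meta[keep, ]
    counts <- atlas$counts[keep, , drop = FALSE]
    units <- sub_meta |>
      dplyr::distinct(.data$sample, .data$sex)
    n_f <- sum(units$sex == "female")
    n_m <- sum(units$sex == "male")
    use_units <- switch(method,
      units = TRUE, cells = FALSE, auto = n_f >= 2 && n_m >= 2)
    if (method == "units" && (n_f < 2 || n_m < 2)) {
      stop(sprintf("scope %s has %d female / %d male units; need >= 2 each",
                   scope_label, n_f, n_m), call. = FALSE)
    }
    if (method == "auto" && !use_units) {
      warning(sprintf(
        "scope %s: <2 pseudobulk units per sex; falling back to per-cell test",
        scope_label))
    }
    if (use_units) {
      agg <- rowsum(as.matrix(counts), sub_meta$sample)
      unit_sex <- units$sex[match(rownames(agg), units$sample)]
      cpm <- log2(1e6 * agg / pmax(rowSums(agg), 1) + 1)
      is_f <- unit_sex == "female"
      p <- ranksum_p(cpm, !is_f)
      lfc <- colMeans(cpm[!is_f, , drop = FALSE]) -
        colMeans(cpm[is_f, , drop = FALSE])
    } else {
      if (is.null(atlas$lognorm)) {
        stop("per-cell fallback needs the lognorm layer; run normalize_atlas()",
             call. = FALSE)
      }
      ln <- atlas$lognorm[keep, , drop = FALSE]
      is_f <- sub_meta$sex == "female"
      if (sum(is_f) == 0 || sum(!is_f) == 0) return(NULL)
      p <- ranksum_p(ln, !is_f)
      e <- expm1(ln)
      lfc <- log2((colMeans(e[!is_f, , drop = FALSE]) + 1) /
                    (colMeans(e[is_f, , drop = FALSE]) + 1))
    }
    prov[[scope_label]] <<- tibble::tibble(
      scope = scope_label,
      method_used = if (use_units) "units" else "cells",
      n_female_units = n_f, n_male_units = n_m)
    tibble::tibble(gene = names(p), log2fc_male_vs_female = unname(lfc),
                   p_value = unname(p),
                   p_adj = stats::p.adjust(unname(p), method = "BH"),
                   scope = scope_label)
  })
  attr(res, "provenance") <- dplyr::bind_rows(prov)
  class(res) <- c("pseudobulk_de", class(res))
  res
}
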
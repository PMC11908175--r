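default_pipeline_config <- function() {
  list(
    input = NULL,                 # dataset directory; NULL -> simulate
    out_dir = "atlas_out",
    seed = 1L,
    stages = c("qc", "lineage", "markers", "nt", "np", "tfnp", "tf_codes",
               "sex_bias", "pseudobulk", "mapping"),
    simulate = list(),            # synthetic_spec() overrides
    qc = list(min_genes = 200, max_genes = 2500, max_mito = 0.05),
    normalize = list(scale_factor = 1e4),
    lineage = list(transgenes = c("FLP", "GFP", "RFP"), min_counts = 1),
    markers = list(only_pos = TRUE, min_pct = 0.1, min_log2fc = 0.25),
    nt = list(threshold = 2, layer = "scaled"),
    np = list(max_clusters = 4, alpha = 0.05),
    tfnp = list(method = "pearson", top_k = 5),
    tf_codes = list(alpha = 0.05),
    sex_bias = list(alpha = 0.05, min_log2_ratio = 1.0),
    mapping = list(bulk_profiles = NULL, method = "pearson")
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults (which encode the
#' standard thresholds of each stage: QC bounds 200-2,500 genes and 5%
#' mitochondrial reads, marker detection at `min_pct` 0.1 and log2
#' fold-change 0.25, neurotransmitter positivity at scaled expression > 2,
#' and so on). Unknown keys, at either level, are rejected.
#'
#' @param config a named list, or a path to a YAML file holding one.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      bad <- setdiff(names(config[[key]]), names(defaults[[key]]))
      if (length(bad)) {
        stop(sprintf("unknown config key(s) under '%s': %s", key,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      defaults[[key]][names(config[[key]])] <- config[[key]]
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  cfg <- defaults
  if (cfg$qc$min_genes > cfg$qc$max_genes) {
    stop("config error: qc$min_genes exceeds qc$max_genes", call. = FALSE)
  }
  if (!all(cfg$stages %in% default_pipeline_config()$stages)) {
    stop("config error: unknown stage name(s)", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full annotation pipeline
#'
#' Executes the configured stages in order — QC, lineage assignment,
#' marker detection, neurotransmitter and neuropeptide analysis, TF-code
#' construction per DNA-binding-domain class, sex-bias detection,
#' pseudobulk differential expression, and bulk-profile mapping — writing
#' one TSV per result plus a provenance block (`provenance.json`: config,
#' config hash, seed, package and R versions) and a checksummed
#' `manifest.json`. All randomness flows from the single config seed, so a
#' rerun with the same config is byte-identical. A stage failure aborts
#' with the stage name.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisibly, a list with the output `manifest` tibble and the
#'   in-memory results of each stage.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  files <- character()
  emit <- function(tbl, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_tsv(tibble::as_tibble(tbl), path)
    files <<- c(files, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  atlas <- stage("input", {
    if (is.null(cfg$input)) {
      spec <- do.call(synthetic_spec, c(cfg$simulate,
                                        list(seed = cfg$seed)))
      sim <- simulate_atlas(spec)
      results$truth <- sim$truth
      sim$atlas
    } else {
      read_atlas_dataset(cfg$input)
    }
  })

  if ("qc" %in% cfg$stages) {
    qc <- stage("qc", do.call(qc_filter, c(list(atlas), cfg$qc)))
    atlas <- qc$atlas
    results$qc <- qc$report
    emit(tidy(qc$report), "qc_report.tsv")
  }
  atlas <- stage("normalize",
                 normalize_atlas(atlas, cfg$normalize$scale_factor))
  if ("lineage" %in% cfg$stages) {
    atlas <- stage("lineage", assign_lineage(
      atlas, cfg$lineage$transgenes, cfg$lineage$min_counts))
    results$lineage <- lineage_composition(atlas)
    emit(results$lineage, "lineage.tsv")
  }
  markers <- NULL
  if (any(c("markers", "np", "tf_codes") %in% cfg$stages)) {
    markers <- stage("markers", do.call(find_all_markers,
                                        c(list(atlas), cfg$markers)))
    results$markers <- markers
    emit(markers, "markers.tsv")
    emit(top_markers(markers), "top_markers.tsv")
  }
  if ("nt" %in% cfg$stages) {
    nt <- stage("nt", classify_neurotransmitters(
      atlas, threshold = cfg$nt$threshold, layer = cfg$nt$layer))
    results$nt <- nt$summary
    emit(glance(nt$summary), "nt_summary.tsv")
    emit(nt$summary$combinations, "nt_combinations.tsv")
  }
  if ("np" %in% cfg$stages) {
    np <- stage("np", cluster_defining_neuropeptides(
      atlas, max_clusters = cfg$np$max_clusters, alpha = cfg$np$alpha,
      markers = markers))
    results$np <- np
    emit(dplyr::mutate(np, clusters = purrr::map_chr(
      .data$clusters, paste, collapse = ",")), "neuropeptides.tsv")
  }
  if ("tfnp" %in% cfg$stages) {
    tfnp <- stage("tfnp", tf_np_correlation(
      atlas, method = cfg$tfnp$method, top_k = cfg$tfnp$top_k))
    results$tfnp <- tfnp
    emit(tfnp$top, "tfnp_top.tsv")
  }
  if ("tf_codes" %in% cfg$stages) {
    present <- intersect(tf_classes(), atlas$gene_meta$tf_class)
    codes <- stage("tf_codes", lapply(
      stats::setNames(present, present), function(cls) {
        binarize_tf_markers(markers, atlas$gene_meta, cls,
                            alpha = cfg$tf_codes$alpha)
      }))
    results$tf_codes <- codes
    stats_tbl <- purrr::map_dfr(codes, function(cd) {
      glance(unique_code_stats(cd))
    })
    results$code_stats <- stats_tbl
    emit(stats_tbl, "tf_code_stats.tsv")
    for (cls in names(codes)) {
      emit(tidy(codes[[cls]]), sprintf("tf_codes_%s.tsv", cls))
    }
  }
  if ("sex_bias" %in% cfg$stages) {
    sb <- stage("sex_bias", do.call(detect_sex_biased_clusters,
                                    c(list(atlas), cfg$sex_bias)))
    results$sex_bias <- sb
    emit(sb, "sex_bias.tsv")
  }
  if ("pseudobulk" %in% cfg$stages) {
    de <- stage("pseudobulk",
                suppressWarnings(pseudobulk_de(atlas, scope = "global")))
    results$pseudobulk <- de
    emit(de, "pseudobulk_de.tsv")
  }
  if ("mapping" %in% cfg$stages && !is.null(cfg$mapping$bulk_profiles)) {
    bulk <- stage("mapping", {
      b <- readr::read_tsv(cfg$mapping$bulk_profiles,
                           col_types = readr::cols())
      bulk_correlation_map(cluster_profile(atlas), b,
                           method = cfg$mapping$method)
    })
    results$mapping <- bulk
    emit(bulk$result, "mapping_bulk.tsv")
  }

  provenance <- list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("t2atlas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, "provenance.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
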
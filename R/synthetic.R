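#' Specify a synthetic lineage-traced brain atlas dataset
#'
#' Describes a synthetic single-nucleus RNA-seq experiment emulating an adult
#' fly central-brain atlas in which type-II (T2) neuroblast progeny carry
#' permanent lineage-tracing transgenes (FLP/GFP/RFP): negative-binomial
#' counts with planted per-cluster markers, glial clusters expressing the
#' pan-glial marker `repo`, the seven fast-acting neurotransmitter pathway
#' genes, a panel of neuropeptide genes of which a subset is
#' cluster-restricted, transcription factors in six DNA-binding-domain
#' classes with planted per-cluster binary codes, sex-specific genes
#' (`yp1/yp2/yp3` in females, `roX1/roX2` in males) and mitochondrial genes.
#'
#' @param n_cells_per_cluster cells simulated per cluster.
#' @param n_clusters total number of clusters.
#' @param n_glial_clusters number of clusters flagged glial (the last ones);
#'   these express `repo` and carry no neurotransmitter programme. Default:
#'   `min(3, n_clusters - 1)`.
#' @param n_genes_background number of unstructured background genes.
#' @param markers_per_cluster planted marker genes per cluster.
#' @param marker_log2fc log2 fold-change of planted markers (and of TF "on"
#'   states) over the background mean.
#' @param nb_dispersion negative-binomial size parameter.
#' @param base_mean mean counts of background genes.
#' @param t2_fraction fraction of cells carrying lineage-tracing transgenes.
#' @param transgene_detection_rate per-cell, per-transgene probability that a
#'   true T2 cell's transgene reads are captured (1 - dropout).
#' @param sex_design named character vector, sample ID -> sex label in
#'   `"female"`, `"male"`, `"mixed"`. The default mirrors a three-sample
#'   design with one all-female, one all-male and one mixed-sex sample.
#' @param tf_class_sizes named integer vector over the six [tf_classes()].
#' @param planted_codes optional named list: per TF class an
#'   `n_clusters x tf_class_sizes[class]` 0/1 matrix. When `NULL`, random
#'   codes (density 0.3) are drawn from the seed at generation time.
#' @param nt_assignment optional named list, cluster ID -> character subset of
#'   [nt_genes()]. When `NULL`, neuronal clusters draw a programme whose
#'   class frequencies follow the composition reported for adult central
#'   brain neurons (cholinergic most abundant, then glutamatergic and
#'   GABAergic, rare monoaminergic classes, ~12% multi-transmitter, ~40%
#'   transmitter-negative).
#' @param n_np_genes number of neuropeptide genes simulated.
#' @param n_np_restricted how many of them are cluster-restricted (planted in
#'   1-4 clusters each); the remainder are expressed diffusely at low level.
#' @param np_assignment optional named list, neuropeptide gene -> character
#'   vector of cluster IDs. Overrides the random restricted assignment.
#' @param sex_genes list with elements `female` and `male`: named numeric
#'   vectors of fold-changes for sex-specific genes.
#' @param sex_bias optional named numeric vector, cluster ID -> female
#'   fraction among sexed cells, used to plant sex-biased clusters; clusters
#'   not named are balanced 50/50.
#' @param mito_fraction_range interval in `[0,1]`; each cell's mitochondrial
#'   read fraction is drawn uniformly from it.
#' @param seed integer seed; generation is deterministic given the spec.
#'
#' @return a validated list of class `synthetic_spec`.
#' @seealso [simulate_atlas()], [write_atlas_dataset()]
#' @export
synthetic_spec <- function(n_cells_per_cluster = 100,
                           n_clusters = 20,
                           n_glial_clusters = NULL,
                           n_genes_background = 300,
                           markers_per_cluster = 5,
                           marker_log2fc = 2,
                           nb_dispersion = 2,
                           base_mean = 0.5,
                           t2_fraction = 0.1,
                           transgene_detection_rate = 0.9,
                           sex_design = c(fem_1 = "female", male_1 = "male",
                                          mix_1 = "mixed"),
                           tf_class_sizes = c(zinc_finger = 8,
                                              helix_turn_helix = 6,
                                              homeodomain = 6,
                                              basic_domain = 4,
                                              unspecified_dbd = 4,
                                              hmg = 3),
                           planted_codes = NULL,
                           nt_assignment = NULL,
                           n_np_genes = 49,
                           n_np_restricted = 13,
                           np_assignment = NULL,
                           sex_genes = list(
                             female = c(yp1 = 8, yp2 = 8, yp3 = 8),
                             male = c(roX1 = 8, roX2 = 8)),
                           sex_bias = NULL,
                           mito_fraction_range = c(0.005, 0.03),
                           seed = 1L) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid synthetic_spec field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (n_cells_per_cluster < 1) stop_field("n_cells_per_cluster", "must be >= 1")
  if (n_clusters < 1) stop_field("n_clusters", "must be >= 1")
  if (is.null(n_glial_clusters)) {
    n_glial_clusters <- min(3L, n_clusters - 1L)
  }
  if (n_glial_clusters < 0 || n_glial_clusters >= n_clusters) {
    stop_field("n_glial_clusters", "must be in [0, n_clusters)")
  }
  if (marker_log2fc <= 0) stop_field("marker_log2fc", "must be positive")
  if (nb_dispersion <= 0) stop_field("nb_dispersion", "must be positive")
  if (base_mean <= 0) stop_field("base_mean", "must be positive")
  if (t2_fraction < 0 || t2_fraction > 1) {
    stop_field("t2_fraction", "must be in [0,1]")
  }
  if (transgene_detection_rate < 0 || transgene_detection_rate > 1) {
    stop_field("transgene_detection_rate", "must be in [0,1]")
  }
  if (!all(sex_design %in% c("female", "male", "mixed")) ||
      is.null(names(sex_design)) || anyDuplicated(names(sex_design))) {
    stop_field("sex_design",
               "must be uniquely named, values in female/male/mixed")
  }
  if (!setequal(names(tf_class_sizes), tf_classes())) {
    stop_field("tf_class_sizes",
               paste("must name exactly the six classes:",
                     paste(tf_classes(), collapse = ", ")))
  }
  clusters <- sprintf("c%03d", seq_len(n_clusters))
  if (!is.null(planted_codes)) {
    for (cls in names(planted_codes)) {
      m <- planted_codes[[cls]]
      if (!cls %in% tf_classes()) stop_field("planted_codes", paste("unknown class", cls))
      if (nrow(m) != n_clusters || ncol(m) != tf_class_sizes[[cls]]) {
        stop_field("planted_codes",
                   sprintf("class %s must be %d x %d, got %d x %d",
                           cls, n_clusters, tf_class_sizes[[cls]],
                           nrow(m), ncol(m)))
      }
      if (!all(m %in% c(0, 1))) stop_field("planted_codes", "entries must be 0/1")
    }
  }
  if (!is.null(nt_assignment)) {
    if (!all(names(nt_assignment) %in% clusters)) {
      stop_field("nt_assignment", "keys must be cluster IDs")
    }
    if (!all(unlist(nt_assignment) %in% nt_genes())) {
      stop_field("nt_assignment", "values must be among the 7 NT genes")
    }
  }
  if (n_np_restricted > n_np_genes) {
    stop_field("n_np_restricted", "cannot exceed n_np_genes")
  }
  if (!is.null(np_assignment) && !all(unlist(np_assignment) %in% clusters)) {
    stop_field("np_assignment", "cluster sets must be subsets of cluster IDs")
  }
  if (!is.null(sex_bias) && !all(names(sex_bias) %in% clusters)) {
    stop_field("sex_bias", "keys must be cluster IDs")
  }
  if (length(mito_fraction_range) != 2 ||
      any(mito_fraction_range < 0) || any(mito_fraction_range >= 1) ||
      mito_fraction_range[1] > mito_fraction_range[2]) {
    stop_field("mito_fraction_range", "must be an interval within [0,1)")
  }
  structure(
    list(n_cells_per_cluster = as.integer(n_cells_per_cluster),
         n_clusters = as.integer(n_clusters),
         n_glial_clusters = as.integer(n_glial_clusters),
         n_genes_background = as.integer(n_genes_background),
         markers_per_cluster = as.integer(markers_per_cluster),
         marker_log2fc = marker_log2fc,
         nb_dispersion = nb_dispersion,
         base_mean = base_mean,
         t2_fraction = t2_fraction,
         transgene_detection_rate = transgene_detection_rate,
         sex_design = sex_design,
         tf_class_sizes = tf_class_sizes[tf_classes()],
         planted_codes = planted_codes,
         nt_assignment = nt_assignment,
         n_np_genes = as.integer(n_np_genes),
         n_np_restricted = as.integer(n_np_restricted),
         np_assignment = np_assignment,
         sex_genes = sex_genes,
         sex_bias = sex_bias,
         mito_fraction_range = mito_fraction_range,
         seed = as.integer(seed),
         clusters = clusters),
    class = "synthetic_spec"
  )
}

# NT programme frequencies used for the default cluster assignment; these
# mirror the reported neuronal composition of the adult central brain
# (cholinergic 21%, glutamatergic 12%, GABAergic 9%, tyraminergic 2.6%,
# dopaminergic 1.2%, serotonergic 1.2%, octopaminergic 0.7%, ~12% multi,
# remainder transmitter-negative).
default_nt_assignment <- function(clusters, glial) {
  single <- c(VAChT = 0.21, VGlut = 0.12, Gad1 = 0.09, Tbh = 0.026,
              ple = 0.012, SerT = 0.012, Tdc2 = 0.007)
  probs <- c(single, multi = 0.12)
  probs <- c(probs, none = 1 - sum(probs))
  out <- list()
  for (cl in setdiff(clusters, glial)) {
    pick <- sample(names(probs), 1, prob = probs)
    out[[cl]] <- switch(pick,
      none = character(0),
      multi = sample(names(single), sample(2:3, 1), prob = single),
      pick)
  }
  out
}

default_np_assignment <- function(np_genes, n_restricted, clusters, glial) {
  neuronal <- setdiff(clusters, glial)
  restricted <- np_genes[seq_len(n_restricted)]
  out <- stats::setNames(vector("list", length(restricted)), restricted)
  for (np in restricted) {
    k <- sample(1:4, 1, prob = c(0.4, 0.3, 0.2, 0.1))
    out[[np]] <- sort(sample(neuronal, min(k, length(neuronal))))
  }
  out
}

#' Simulate an atlas dataset with known ground truth
#'
#' Draws a cells-by-genes count matrix from the negative-binomial model laid
#' out by a [synthetic_spec()]: cluster-specific gene means, planted markers
#' up-regulated by `marker_log2fc`, TF genes elevated where the planted
#' binary code has a 1, lineage-tracing transgene counts only in T2 cells
#' (subject to per-transgene Bernoulli dropout), `repo` in glial clusters,
#' sex-specific genes elevated in cells of the corresponding sex, and
#' per-cell mitochondrial fractions drawn uniformly from
#' `mito_fraction_range`. Library sizes vary log-normally (sigma = 0.3).
#' Cells in mixed-sex samples carry the observed sex label `"mixed"`; their
#' true sex is recorded only in the ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `atlas` (an [atlas_experiment()], counts
#'   layer only, `lineage = "unassigned"`) and `truth`, a list with per-cell
#'   `cell_lineage`, `cluster_of_cell`, `sex_of_cell`, `nt_labels`, plus
#'   `marker_genes` (per cluster), `tf_code` (per class, the planted binary
#'   matrix), `nt_assignment`, `np_clusters`, `glial_clusters`,
#'   `sex_biased_clusters`, and `t2_pre_dropout` (transgene positivity
#'   before dropout).
#' @export
simulate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(spec$seed)

  clusters <- spec$clusters
  glial <- if (spec$n_glial_clusters > 0) {
    utils::tail(clusters, spec$n_glial_clusters)
  } else character(0)
  n_cell <- spec$n_cells_per_cluster * spec$n_clusters
  cluster_of_cell <- rep(clusters, each = spec$n_cells_per_cluster)
  cell_id <- sprintf("cell%05d", seq_len(n_cell))

  ## -- gene table ----------------------------------------------------------
  bg <- sprintf("bg%04d", seq_len(spec$n_genes_background))
  mk <- as.vector(t(outer(clusters, seq_len(spec$markers_per_cluster),
                          function(c, i) sprintf("mk_%s_%d", c, i))))
  tf_abbrev <- c(zinc_finger = "zf", helix_turn_helix = "hth",
                 homeodomain = "hd", basic_domain = "bd",
                 unspecified_dbd = "udbd", hmg = "hmg")
  tf_ids <- lapply(tf_classes(), function(cls) {
    sprintf("%s%d", tf_abbrev[[cls]], seq_len(spec$tf_class_sizes[[cls]]))
  })
  names(tf_ids) <- tf_classes()
  np <- sprintf("np%02d", seq_len(spec$n_np_genes))
  transgenes <- c("FLP", "GFP", "RFP")
  mito <- c("mt:CoI", "mt:CoII", "mt:CoIII", "mt:ND1", "mt:Cyb")
  sexg <- c(names(spec$sex_genes$female), names(spec$sex_genes$male))

  gene_meta <- dplyr::bind_rows(
    tibble::tibble(gene_id = bg, gene_class = "other", tf_class = "none"),
    tibble::tibble(gene_id = mk, gene_class = "other", tf_class = "none"),
    purrr::imap_dfr(tf_ids, function(ids, cls) {
      tibble::tibble(gene_id = ids, gene_class = "tf", tf_class = cls)
    }),
    tibble::tibble(gene_id = nt_genes(), gene_class = "nt_pathway",
                   tf_class = "none"),
    tibble::tibble(gene_id = np, gene_class = "neuropeptide",
                   tf_class = "none"),
    tibble::tibble(gene_id = "repo", gene_class = "glial_marker",
                   tf_class = "none"),
    tibble::tibble(gene_id = sexg, gene_class = "sex_marker",
                   tf_class = "none"),
    tibble::tibble(gene_id = transgenes, gene_class = "transgene",
                   tf_class = "none"),
    tibble::tibble(gene_id = mito, gene_class = "mito", tf_class = "none")
  )
  n_gene <- nrow(gene_meta)

  ## -- planted structure ---------------------------------------------------
  planted_codes <- lapply(tf_classes(), function(cls) {
    m <- spec$planted_codes[[cls]]
    if (is.null(m)) {
      m <- matrix(stats::rbinom(spec$n_clusters * spec$tf_class_sizes[[cls]],
                                1, 0.3),
                  nrow = spec$n_clusters)
    }
    dimnames(m) <- list(clusters, tf_ids[[cls]])
    m
  })
  names(planted_codes) <- tf_classes()
  nt_assignment <- spec$nt_assignment
  if (is.null(nt_assignment)) {
    nt_assignment <- default_nt_assignment(clusters, glial)
  }
  np_assignment <- spec$np_assignment
  if (is.null(np_assignment)) {
    np_assignment <- default_np_assignment(np, spec$n_np_restricted,
                                           clusters, glial)
  }

  ## -- cluster-level mean matrix ------------------------------------------
  on_mean <- spec$base_mean * 2^spec$marker_log2fc
  low <- 0.01
  M <- matrix(0, spec$n_clusters, n_gene,
              dimnames = list(clusters, gene_meta$gene_id))
  M[, bg] <- spec$base_mean
  M[, mk] <- spec$base_mean
  for (cl in clusters) {
    M[cl, sprintf("mk_%s_%d", cl, seq_len(spec$markers_per_cluster))] <- on_mean
  }
  for (cls in tf_classes()) {
    M[, tf_ids[[cls]]] <- low + planted_codes[[cls]] * (on_mean - low)
  }
  M[, nt_genes()] <- low
  for (cl in names(nt_assignment)) {
    M[cl, nt_assignment[[cl]]] <- 8
  }
  M[, np] <- 0.2
  restricted <- names(np_assignment)
  M[, restricted] <- low
  for (g in restricted) M[np_assignment[[g]], g] <- 8
  M[, "repo"] <- low
  if (length(glial)) M[glial, "repo"] <- 8
  M[, sexg] <- 0.05
  # transgenes and mito handled per cell below
  M[, transgenes] <- 0
  M[, mito] <- 0

  ## -- per-cell structure --------------------------------------------------
  sample_sex <- spec$sex_design
  fem_frac <- rep(0.5, spec$n_clusters)
  names(fem_frac) <- clusters
  if (!is.null(spec$sex_bias)) fem_frac[names(spec$sex_bias)] <- spec$sex_bias
  true_sex <- ifelse(stats::runif(n_cell) < fem_frac[cluster_of_cell],
                     "female", "male")
  sample_of_cell <- vapply(true_sex, function(s) {
    ok <- names(sample_sex)[sample_sex %in% c(s, "mixed")]
    if (!length(ok)) ok <- names(sample_sex)
    if (length(ok) == 1) ok else sample(ok, 1)
  }, character(1), USE.NAMES = FALSE)
  obs_sex <- unname(sample_sex[sample_of_cell])
  lineage <- ifelse(stats::runif(n_cell) < spec$t2_fraction, "T2", "T1")
  lib <- exp(stats::rnorm(n_cell, 0, 0.3))

  mu <- M[cluster_of_cell, , drop = FALSE] * lib
  for (g in names(spec$sex_genes$female)) {
    mu[true_sex == "female", g] <- mu[true_sex == "female", g] *
      spec$sex_genes$female[[g]]
  }
  for (g in names(spec$sex_genes$male)) {
    mu[true_sex == "male", g] <- mu[true_sex == "male", g] *
      spec$sex_genes$male[[g]]
  }
  is_t2 <- lineage == "T2"
  mu[is_t2, transgenes] <- 3 * lib[is_t2]
  f_mito <- stats::runif(n_cell, spec$mito_fraction_range[1],
                         spec$mito_fraction_range[2])
  non_mito_total <- rowSums(mu)
  mu[, mito] <- f_mito / (1 - f_mito) * non_mito_total / length(mito)

  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = spec$nb_dispersion),
                   nrow = n_cell, dimnames = dimnames(mu))

  # every true T2 cell expresses at least one transgene before dropout
  t2_zero <- is_t2 & rowSums(counts[, transgenes, drop = FALSE]) == 0
  counts[t2_zero, "FLP"] <- 1
  t2_pre_dropout <- rowSums(counts[, transgenes, drop = FALSE] > 0) > 0
  drop_keep <- matrix(stats::runif(n_cell * 3) <= spec$transgene_detection_rate,
                      nrow = n_cell)
  counts[, transgenes] <- counts[, transgenes] * drop_keep
  counts[!is_t2, transgenes] <- 0

  cell_meta <- tibble::tibble(cell_id = cell_id, sample = sample_of_cell,
                              sex = obs_sex, cluster = cluster_of_cell,
                              lineage = "unassigned")
  atlas <- atlas_experiment(Matrix::Matrix(counts, sparse = TRUE),
                            cell_meta, gene_meta)
  truth <- list(
    cell_lineage = stats::setNames(lineage, cell_id),
    cluster_of_cell = stats::setNames(cluster_of_cell, cell_id),
    sex_of_cell = stats::setNames(true_sex, cell_id),
    nt_labels = stats::setNames(
      lapply(cluster_of_cell, function(cl) {
        v <- nt_assignment[[cl]]
        if (is.null(v)) character(0) else v
      }), cell_id),
    marker_genes = stats::setNames(
      lapply(clusters, function(cl) {
        sprintf("mk_%s_%d", cl, seq_len(spec$markers_per_cluster))
      }), clusters),
    tf_code = planted_codes,
    nt_assignment = nt_assignment,
    np_clusters = np_assignment,
    glial_clusters = glial,
    sex_biased_clusters = names(spec$sex_bias),
    t2_pre_dropout = stats::setNames(t2_pre_dropout, cell_id)
  )
  list(atlas = atlas, truth = truth)
}

#' Write a dataset to disk as MatrixMarket + TSV
#'
#' Writes `matrix.mtx` (cells x genes, coordinate format), `genes.tsv`
#' (`gene_id`, `gene_class`, `tf_class`), `cells.tsv` (`cell_id`, `sample`,
#' `sex`, `true_cluster`), optional ground-truth tables under `truth/`, and
#' a `manifest.json` listing every file with its MD5 checksum.
#'
#' @param atlas an [atlas_experiment()].
#' @param dir output directory.
#' @param truth optional ground-truth list from [simulate_atlas()].
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a tibble (`file`, `md5`) — the manifest.
#' @export
write_atlas_dataset <- function(atlas, dir, truth = NULL, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)) && !overwrite) {
    stop(sprintf("directory '%s' is not empty; use overwrite = TRUE", dir),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(atlas$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(atlas$gene_meta[, c("gene_id", "gene_class", "tf_class")],
                   file.path(dir, "genes.tsv"))
  cells <- atlas$cell_meta
  cells <- tibble::tibble(cell_id = cells$cell_id, sample = cells$sample,
                          sex = cells$sex, true_cluster = cells$cluster)
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  files <- c("matrix.mtx", "genes.tsv", "cells.tsv")
  if (!is.null(truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    readr::write_tsv(
      tibble::tibble(cell_id = names(truth$cell_lineage),
                     lineage = unname(truth$cell_lineage),
                     cluster = unname(truth$cluster_of_cell),
                     sex = unname(truth$sex_of_cell)),
      file.path(tdir, "cells.tsv"))
    readr::write_tsv(
      tidyr::unnest(tibble::tibble(cluster = names(truth$marker_genes),
                                   gene = truth$marker_genes),
                    "gene"),
      file.path(tdir, "markers.tsv"))
    codes <- purrr::imap_dfr(truth$tf_code, function(m, cls) {
      tibble::as_tibble(m, rownames = "cluster") |>
        tidyr::pivot_longer(-"cluster", names_to = "tf", values_to = "bit") |>
        dplyr::mutate(tf_class = cls, .before = 1)
    })
    readr::write_tsv(codes, file.path(tdir, "tf_codes.tsv"))
    files <- c(files, file.path("truth", c("cells.tsv", "markers.tsv",
                                           "tf_codes.tsv")))
  }
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
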
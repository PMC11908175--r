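#' Construct an atlas experiment
#'
#' The central data container of the package: a sparse cells-by-genes count
#' matrix plus per-cell and per-gene metadata, with optional derived layers
#' (`lognorm`, the per-cell depth-normalised log expression; `scaled`, the
#' per-gene z-score of `lognorm` across cells). Cell metadata rows align 1:1
#' with matrix rows, gene metadata with matrix columns.
#'
#' @param counts a non-negative integer matrix or sparse `Matrix`, cells in
#'   rows, genes in columns. Dimnames, if absent, are taken from the metadata.
#' @param cell_meta a data frame with at least `cell_id`; recognised columns
#'   are `sample`, `sex` (`"female"`, `"male"` or `"mixed"`), `cluster` and
#'   `lineage` (`"T1"`, `"T2"` or `"unassigned"`). Missing columns are filled
#'   with defaults.
#' @param gene_meta a data frame with at least `gene_id`; recognised columns
#'   are `gene_class` (one of `"tf"`, `"neuropeptide"`, `"nt_pathway"`,
#'   `"transgene"`, `"mito"`, `"glial_marker"`, `"sex_marker"`, `"other"`) and
#'   `tf_class` (one of [tf_classes()] or `"none"`).
#' @param lognorm,scaled optional precomputed layers with the same shape as
#'   `counts`.
#'
#' @return an object of class `atlas_experiment`.
#' @seealso [normalize_atlas()], [qc_filter()], [assign_lineage()]
#' @export
atlas_experiment <- function(counts, cell_meta, gene_meta,
                             lognorm = NULL, scaled = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  cell_meta <- tibble::as_tibble(cell_meta)
  gene_meta <- tibble::as_tibble(gene_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("cell_meta must contain a 'cell_id' column", call. = FALSE)
  }
  if (!"gene_id" %in% names(gene_meta)) {
    stop("gene_meta must contain a 'gene_id' column", call. = FALSE)
  }
  if (nrow(cell_meta) != nrow(counts)) {
    stop(sprintf("cell_meta has %d rows but counts has %d cells",
                 nrow(cell_meta), nrow(counts)), call. = FALSE)
  }
  if (nrow(gene_meta) != ncol(counts)) {
    stop(sprintf("gene_meta has %d rows but counts has %d genes",
                 nrow(gene_meta), ncol(counts)), call. = FALSE)
  }
  if (anyDuplicated(cell_meta$cell_id)) {
    stop("duplicated cell_id in cell_meta", call. = FALSE)
  }
  if (anyDuplicated(gene_meta$gene_id)) {
    stop("duplicated gene_id in gene_meta", call. = FALSE)
  }
  if (length(counts@x) && min(counts@x) < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (!"sample" %in% names(cell_meta))  cell_meta$sample  <- "sample1"
  if (!"sex" %in% names(cell_meta))     cell_meta$sex     <- "mixed"
  if (!"cluster" %in% names(cell_meta)) cell_meta$cluster <- "c1"
  if (!"lineage" %in% names(cell_meta)) cell_meta$lineage <- "unassigned"
  if (!"gene_class" %in% names(gene_meta)) gene_meta$gene_class <- "other"
  if (!"tf_class" %in% names(gene_meta))   gene_meta$tf_class   <- "none"
  cell_meta$cluster <- as.character(cell_meta$cluster)
  dimnames(counts) <- list(cell_meta$cell_id, gene_meta$gene_id)
  for (layer in list(lognorm, scaled)) {
    if (!is.null(layer) && !identical(dim(layer), dim(counts))) {
      stop("layers must have the same shape as counts", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, lognorm = lognorm, scaled = scaled,
         cell_meta = cell_meta, gene_meta = gene_meta),
    class = "atlas_experiment"
  )
}

#' @export
print.atlas_experiment <- function(x, ...) {
  cat(sprintf("<atlas_experiment> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  layers <- c("counts", if (!is.null(x$lognorm)) "lognorm",
              if (!is.null(x$scaled)) "scaled")
  cat("  layers:", paste(layers, collapse = ", "), "\n")
  cat(sprintf("  clusters: %d | samples: %d\n",
              dplyr::n_distinct(x$cell_meta$cluster),
              dplyr::n_distinct(x$cell_meta$sample)))
  lin <- table(factor(x$cell_meta$lineage, c("T1", "T2", "unassigned")))
  cat(sprintf("  lineage: T1=%d T2=%d unassigned=%d\n",
              lin[["T1"]], lin[["T2"]], lin[["unassigned"]]))
  invisible(x)
}

#' Number of cells / genes in an atlas
#' @param atlas an `atlas_experiment`.
#' @return an integer.
#' @export
n_cells <- function(atlas) nrow(atlas$counts)

#' @rdname n_cells
#' @export
n_genes <- function(atlas) ncol(atlas$counts)

#' Extract an expression layer as a base matrix
#'
#' @param atlas an `atlas_experiment`.
#' @param layer one of `"counts"`, `"lognorm"`, `"scaled"`.
#' @return a dense base matrix (cells x genes).
#' @export
atlas_layer <- function(atlas, layer = c("counts", "lognorm", "scaled")) {
  layer <- match.arg(layer)
  m <- atlas[[layer]]
  if (is.null(m)) {
    stop(sprintf("layer '%s' not computed; run normalize_atlas() first", layer),
         call. = FALSE)
  }
  as.matrix(m)
}

#' Subset an atlas to a set of cells
#'
#' Keeps layers and metadata aligned. Used internally by the QC and cluster
#' subsetting operations; exported because it is generally useful.
#'
#' @param atlas an `atlas_experiment`.
#' @param cells logical or integer index, or character cell IDs.
#' @return an `atlas_experiment` with the selected cells.
#' @export
subset_cells <- function(atlas, cells) {
  if (is.character(cells)) cells <- match(cells, atlas$cell_meta$cell_id)
  atlas_experiment(
    counts = atlas$counts[cells, , drop = FALSE],
    cell_meta = atlas$cell_meta[cells, , drop = FALSE],
    gene_meta = atlas$gene_meta,
    lognorm = if (!is.null(atlas$lognorm)) atlas$lognorm[cells, , drop = FALSE],
    scaled  = if (!is.null(atlas$scaled))  atlas$scaled[cells, , drop = FALSE]
  )
}

#' The six transcription-factor DNA-binding-domain classes
#'
#' Class labels for the TF taxonomy used throughout: zinc finger,
#' helix-turn-helix, homeodomain, basic domain, unidentified DNA-binding
#' domain, and high-mobility group.
#'
#' @return a character vector of length six.
#' @export
tf_classes <- function() {
  c("zinc_finger", "helix_turn_helix", "homeodomain",
    "basic_domain", "unspecified_dbd", "hmg")
}

#' The seven fast-acting neurotransmitter pathway genes
#'
#' `VGlut` (glutamatergic), `VAChT` (cholinergic), `Gad1` (GABAergic),
#' `Tbh` (tyraminergic), `ple` (dopaminergic), `SerT` (serotonergic),
#' `Tdc2` (octopaminergic).
#'
#' @return a character vector of length seven.
#' @export
nt_genes <- function() {
  c("VGlut", "VAChT", "Gad1", "Tbh", "ple", "SerT", "Tdc2")
}

# round half up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}
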
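#' Default ordered injury timepoints
#'
#' The experimental design has one uninjured control followed by three
#' post-injury collections (12, 24 and 48 hours after optic nerve crush).
#' @export
DEFAULT_TIMEPOINTS <- c("control", "12h", "24h", "48h")

#' Construct a labeled expression atlas
#'
#' Packs a sparse gene x cell count matrix and per-cell annotations into a
#' [SingleCellExperiment::SingleCellExperiment] and validates the invariants
#' every downstream stage relies on: unique barcodes, consistent dimensions,
#' timepoints restricted to a declared ordered set, and neuron-subclass
#' labels only on cells of the single RGC cell type.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns. Row names are gene ids, column names barcodes.
#' @param cell_meta data.frame with one row per cell: columns `barcode`,
#'   `cell_type`, `timepoint`, `sample`, and optionally `subclass` and
#'   `survival_class` (NA for non-RGC cells).
#' @param timepoints ordered character vector of allowed timepoint labels;
#'   the first entry is the uninjured control.
#' @return a `SingleCellExperiment` with a `counts` assay; atlas-level
#'   settings are kept in `metadata()`: `timepoints` and `rgc_type` (the
#'   cell type carrying subclass labels, or NA if none).
#' @export
build_atlas <- function(counts, cell_meta, timepoints = DEFAULT_TIMEPOINTS) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  need <- c("barcode", "cell_type", "timepoint", "sample")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    abort_validation("cell_meta is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"subclass" %in% names(cell_meta)) cell_meta$subclass <- NA_character_
  if (!"survival_class" %in% names(cell_meta)) cell_meta$survival_class <- NA_character_

  if (ncol(counts) != nrow(cell_meta))
    abort_validation("counts has %d cells but cell_meta has %d rows",
                     ncol(counts), nrow(cell_meta))
  if (anyDuplicated(cell_meta$barcode))
    abort_validation("duplicate barcode(s): %s",
                     paste(unique(cell_meta$barcode[duplicated(cell_meta$barcode)]),
                           collapse = ", "))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    abort_validation("counts must have unique gene-id row names")
  bad_tp <- setdiff(unique(cell_meta$timepoint), timepoints)
  if (length(bad_tp))
    abort_validation("unknown timepoint(s): %s (declared: %s)",
                     paste(bad_tp, collapse = ", "),
                     paste(timepoints, collapse = ", "))
  if (length(timepoints) < 2L)
    abort_validation("at least two timepoints (control + post-injury) are required")

  with_sub <- !is.na(cell_meta$subclass)
  rgc_type <- NA_character_
  if (any(with_sub)) {
    ct <- unique(cell_meta$cell_type[with_sub])
    if (length(ct) > 1L)
      abort_validation("subclass labels span multiple cell types (%s); only the RGC type may carry subclasses",
                       paste(ct, collapse = ", "))
    rgc_type <- ct
  }

  colnames(counts) <- cell_meta$barcode
  cd <- S4Vectors::DataFrame(cell_meta[, c("barcode", "cell_type", "subclass",
                                           "survival_class", "timepoint", "sample")],
                             row.names = cell_meta$barcode)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  S4Vectors::metadata(sce)$timepoints <- timepoints
  S4Vectors::metadata(sce)$rgc_type <- rgc_type
  sce
}

#' Read a 10x-style expression bundle into an atlas
#'
#' Expects a Matrix Market triplet file (1-based indices), a features TSV
#' (gene id in the first column), a barcodes TSV, and a cell-metadata TSV
#' with columns `barcode`, `cell_type`, `timepoint`, `sample` and optional
#' `subclass` / `survival_class`. Metadata rows are matched to the barcode
#' file; any mismatch is a parse error naming the offender.
#'
#' @param mtx_path,features_path,barcodes_path,metadata_path file paths.
#' @param timepoints declared ordered timepoint labels.
#' @return a validated atlas (see [build_atlas()]).
#' @export
load_expression <- function(mtx_path, features_path, barcodes_path,
                            metadata_path, timepoints = DEFAULT_TIMEPOINTS) {
  for (p in c(mtx_path, features_path, barcodes_path, metadata_path))
    if (!file.exists(p)) abort("file not found: %s", p)
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- data.table::fread(features_path, header = FALSE, sep = "\t",
                             colClasses = "character")
  bcs <- data.table::fread(barcodes_path, header = FALSE, sep = "\t",
                           colClasses = "character")[[1L]]
  if (nrow(feats) != nrow(m))
    abort("features file lists %d genes but matrix has %d rows",
          nrow(feats), nrow(m))
  if (length(bcs) != ncol(m))
    abort("barcodes file lists %d cells but matrix has %d columns",
          length(bcs), ncol(m))
  if (anyDuplicated(bcs))
    abort("duplicate barcode(s) in barcodes file: %s",
          paste(unique(bcs[duplicated(bcs)]), collapse = ", "))
  rownames(m) <- feats[[1L]]

  meta <- data.table::fread(metadata_path, sep = "\t", header = TRUE,
                            na.strings = c("NA", ""))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  unknown <- setdiff(bcs, meta$barcode)
  if (length(unknown))
    abort("metadata is missing barcode(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  extra <- setdiff(meta$barcode, bcs)
  if (length(extra))
    abort("metadata lists barcode(s) absent from the barcodes file: %s",
          paste(utils::head(extra, 5L), collapse = ", "))
  meta <- meta[match(bcs, meta$barcode), , drop = FALSE]
  build_atlas(m, meta, timepoints = timepoints)
}

#' Write an atlas as a 10x-style bundle
#'
#' Emits `matrix.mtx` (1-based Matrix Market), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv` into `dir`.
#'
#' @param atlas an atlas from [build_atlas()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_expression <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(atlas, "counts")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(atlas))
  data.table::fwrite(cd, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(dir)
}

#' Per-cell QC thresholds
#'
#' Cells are REMOVED on strict violations: nUMI < `numi_min` or
#' > `numi_max`, nGene < `ngene_min` or > `ngene_max`, mitochondrial rate
#' > `mito_rate_max`, or log10GenesPerUMI < `log10_genes_per_umi_min`.
#' Boundary values are therefore retained. log10GenesPerUMI is
#' log10(nGene)/log10(nUMI), the standard complexity metric.
#'
#' @param numi_min,numi_max retained UMI-count range (inclusive).
#' @param ngene_min,ngene_max retained detected-gene range (inclusive).
#' @param mito_rate_max maximum retained mitochondrial fraction.
#' @param log10_genes_per_umi_min minimum retained complexity.
#' @param mito_gene_prefix gene-id prefix identifying mitochondrial genes.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(numi_min = 800, numi_max = 30000,
                          ngene_min = 350, ngene_max = 7500,
                          mito_rate_max = 0.20,
                          log10_genes_per_umi_min = 0.8,
                          mito_gene_prefix = "mt-") {
  check_scalar_num(numi_min, "numi_min", 0)
  check_scalar_num(numi_max, "numi_max", 0)
  check_scalar_num(ngene_min, "ngene_min", 0)
  check_scalar_num(ngene_max, "ngene_max", 0)
  check_scalar_num(mito_rate_max, "mito_rate_max", 0, 1)
  check_scalar_num(log10_genes_per_umi_min, "log10_genes_per_umi_min", 0, 1)
  if (numi_min >= numi_max) abort_validation("numi_min must be < numi_max")
  if (ngene_min >= ngene_max) abort_validation("ngene_min must be < ngene_max")
  structure(list(numi_min = numi_min, numi_max = numi_max,
                 ngene_min = ngene_min, ngene_max = ngene_max,
                 mito_rate_max = mito_rate_max,
                 log10_genes_per_umi_min = log10_genes_per_umi_min,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

#' Shipped QC presets
#'
#' `whole_retina`: 800 <= nUMI <= 30,000, 350 <= nGene <= 7,500, mito
#' <= 20%, complexity >= 0.8. `purified_rgc`: nUMI >= 500, nGene >= 250
#' with no upper bounds (the purified dataset's protocol states none),
#' mito <= 20%, complexity >= 0.8.
#'
#' `synthetic`: permissive bounds scaled to the package's small simulated
#' gene universes (a few hundred genes, so per-cell UMI totals sit far
#' below droplet-scale data); used by default when the pipeline runs on
#' simulated input.
#'
#' @param name preset name.
#' @return a `qc_thresholds` object.
#' @export
qc_preset <- function(name = c("whole_retina", "purified_rgc", "synthetic")) {
  name <- match.arg(name)
  switch(name,
    whole_retina = qc_thresholds(),
    purified_rgc = qc_thresholds(numi_min = 500, numi_max = Inf,
                                 ngene_min = 250, ngene_max = Inf),
    synthetic = qc_thresholds(numi_min = 20, numi_max = Inf,
                              ngene_min = 10, ngene_max = Inf,
                              mito_rate_max = 0.5,
                              log10_genes_per_umi_min = 0.5))
}

qc_metrics <- function(atlas, mito_gene_prefix = "mt-") {
  m <- SummarizedExperiment::assay(atlas, "counts")
  numi <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito_idx <- startsWith(rownames(m), mito_gene_prefix)
  mito <- if (any(mito_idx)) Matrix::colSums(m[mito_idx, , drop = FALSE]) / pmax(numi, 1)
          else rep(0, ncol(m))
  lg_umi <- log10(pmax(numi, 1))
  ratio <- ifelse(lg_umi > 0, log10(pmax(ngene, 1)) / lg_umi, 0)
  data.frame(barcode = colnames(m), numi = as.numeric(numi),
             ngene = as.numeric(ngene), mito_rate = as.numeric(mito),
             log10_genes_per_umi = ratio, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Apply per-cell QC filters
#'
#' Evaluates every criterion in [qc_thresholds()] for every cell and drops
#' violators. A cell failing several criteria is counted under each. The
#' operation is idempotent and monotone: tightening any threshold can only
#' shrink the retained set.
#'
#' @param atlas an atlas.
#' @param th a `qc_thresholds` object.
#' @return list with `atlas` (filtered), `report` (data.frame of per-
#'   criterion removal counts plus `retained` / `total`), and `metrics`
#'   (per-cell QC table with a `retained` flag).
#' @export
qc_filter_cells <- function(atlas, th = qc_thresholds()) {
  stopifnot(inherits(th, "qc_thresholds"))
  qm <- qc_metrics(atlas, th$mito_gene_prefix)
  fail <- cbind(
    numi_low   = qm$numi  < th$numi_min,
    numi_high  = qm$numi  > th$numi_max,
    ngene_low  = qm$ngene < th$ngene_min,
    ngene_high = qm$ngene > th$ngene_max,
    mito_high  = qm$mito_rate > th$mito_rate_max,
    complexity_low = qm$log10_genes_per_umi < th$log10_genes_per_umi_min)
  keep <- !apply(fail, 1L, any)
  if (!any(keep))
    message("qc_filter_cells: no cells pass QC; returning an empty atlas")
  report <- data.frame(criterion = colnames(fail),
                       removed = as.integer(colSums(fail)),
                       stringsAsFactors = FALSE)
  report <- rbind(report,
                  data.frame(criterion = c("removed_total", "retained", "total"),
                             removed = c(sum(!keep), sum(keep), length(keep))))
  qm$retained <- keep
  list(atlas = atlas[, keep], report = report, metrics = qm)
}

#' Write result tables and a run summary
#'
#' Tabular results go to TSV (UTF-8, header row, no quoting of plain
#' fields); the summary, if given, to JSON. Written files round-trip
#' through [data.table::fread()].
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param summary optional list serialized to `summary.json`.
#' @return invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir, summary = NULL) {
  if (length(tables) && is.null(names(tables)))
    abort("'tables' must be a named list")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort("cannot create output directory: %s", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.frame(tables[[nm]]), p, sep = "\t",
                       quote = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  if (!is.null(summary)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
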
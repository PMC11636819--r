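#' Summarize an atlas into per-(group, timepoint) expression profiles
#'
#' Counts are first normalized per cell to a common library size
#' (counts-per-10k by default), then averaged within each (group,
#' timepoint). The detection rate of a gene is the fraction of cells in
#' the group with a nonzero raw count, so it is invariant under any
#' monotone, zero-preserving transform.
#'
#' Grouping modes: `"cell_type"` uses the cell-type label of every cell;
#' `"subclass"` keeps only cells with a subclass label (the RGC type) and
#' groups by it; `"both"` stacks the two (cell-type groups over all cells
#' plus subclass groups over RGC cells), which is the layout the scoring
#' stage expects — senders addressed at the cell-type level, RGC
#' receivers at the subclass level.
#'
#' @param atlas an atlas from [build_atlas()].
#' @param group_by `"cell_type"`, `"subclass"` or `"both"`.
#' @param target_sum per-cell library size after normalization.
#' @return a `data.table` with columns `group`, `group_kind`, `timepoint`,
#'   `gene`, `mean_expr`, `detection_rate`, `n_cells`. Empty (group,
#'   timepoint) combinations are omitted (with a warning when a group is
#'   present at some timepoints only).
#' @export
summarize_profiles <- function(atlas, group_by = c("both", "cell_type", "subclass"),
                               target_sum = 1e4) {
  group_by <- match.arg(group_by)
  m <- SummarizedExperiment::assay(atlas, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(atlas))
  tps <- S4Vectors::metadata(atlas)$timepoints

  one_mode <- function(kind) {
    lab <- if (kind == "cell_type") cd$cell_type else cd$subclass
    keep <- !is.na(lab)
    if (!any(keep)) abort("no cells carry a %s label", kind)
    mm <- m[, keep, drop = FALSE]
    lab <- lab[keep]
    tp <- cd$timepoint[keep]
    libs <- Matrix::colSums(mm)
    if (any(libs == 0)) libs[libs == 0] <- 1  # all-zero cell contributes zeros
    norm <- mm %*% Matrix::Diagonal(x = target_sum / libs)
    key <- factor(paste(lab, tp, sep = "\r"))
    ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key), x = 1,
                                dims = c(length(key), nlevels(key)))
    n_cells <- Matrix::colSums(ind)
    mean_expr <- as.matrix(norm %*% ind %*% Matrix::Diagonal(x = 1 / n_cells))
    det <- as.matrix((mm > 0) %*% ind %*% Matrix::Diagonal(x = 1 / n_cells))
    parts <- strsplit(levels(key), "\r", fixed = TRUE)
    out <- data.table::data.table(
      group = rep(vapply(parts, `[`, "", 1L), each = nrow(mm)),
      group_kind = kind,
      timepoint = rep(vapply(parts, `[`, "", 2L), each = nrow(mm)),
      gene = rep(rownames(mm), times = nlevels(key)),
      mean_expr = as.vector(mean_expr),
      detection_rate = as.vector(det),
      n_cells = rep(as.integer(n_cells), each = nrow(mm)))
    present <- unique(out[, c("group", "timepoint")])
    missing <- setdiff(
      as.vector(outer(unique(out$group), tps, paste, sep = "@")),
      paste(present$group, present$timepoint, sep = "@"))
    if (length(missing))
      warning(sprintf("profiles omitted for empty group/timepoint(s): %s",
                      paste(missing, collapse = ", ")), call. = FALSE)
    out
  }
  res <- switch(group_by,
    cell_type = one_mode("cell_type"),
    subclass  = one_mode("subclass"),
    both      = rbind(one_mode("cell_type"), one_mode("subclass")))
  data.table::setkeyv(res, c("group", "timepoint", "gene"))
  res[]
}

#' Per-gene log2 fold changes of post-injury timepoints vs control
#'
#' For one group (cell type or subclass), genes detected above
#' `detection_min` at any timepoint get
#' `log2((mean_t + pseudocount) / (mean_control + pseudocount))` for each
#' post-injury timepoint, plus the largest absolute value across those
#' comparisons (`max_abs_log2fc`).
#'
#' @param profiles output of [summarize_profiles()].
#' @param group group id to restrict to.
#' @param pseudocount added to both means; bounds fold changes for
#'   dropout-heavy genes.
#' @param detection_min strict detection-rate cutoff for inclusion
#'   (`rate > detection_min` at >= 1 timepoint).
#' @param control control timepoint label.
#' @return data.frame: `gene`, one `log2fc_<tp>` column per post-injury
#'   timepoint, `max_abs_log2fc`.
#' @export
compute_log2fc_table <- function(profiles, group, pseudocount = 1,
                                 detection_min = 0.1, control = "control") {
  pr <- as.data.table(profiles)
  sel <- pr$group == group   # precomputed: 'group' must not hit the column
  pr <- pr[which(sel)]
  if (!nrow(pr)) abort("no profiles for group '%s'", group)
  tps <- unique(pr$timepoint)
  if (!control %in% tps) abort("control timepoint '%s' missing for group '%s'",
                               control, group)
  post <- setdiff(tps, control)
  if (!length(post)) abort("no post-injury timepoints for group '%s'", group)
  keep_genes <- unique(pr$gene[pr$detection_rate > detection_min])
  if (!length(keep_genes))
    abort("no genes exceed detection rate %g in group '%s'", detection_min, group)
  pr <- pr[pr$gene %in% keep_genes]
  wide_m <- data.table::dcast(pr, gene ~ timepoint, value.var = "mean_expr")
  out <- data.frame(gene = wide_m$gene, stringsAsFactors = FALSE)
  for (t in post)
    out[[paste0("log2fc_", t)]] <-
      log2((wide_m[[t]] + pseudocount) / (wide_m[[control]] + pseudocount))
  fc_cols <- paste0("log2fc_", post)
  out$max_abs_log2fc <- do.call(pmax, lapply(out[fc_cols], abs))
  out
}

#' Compare fold-change magnitudes of LR genes against the background
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test on `max_abs_log2fc` of
#' ligand/receptor-annotated genes versus all other genes in the table.
#'
#' @param fc_table output of [compute_log2fc_table()].
#' @param lr_gene_set character vector of LR-annotated gene ids.
#' @return list with `ks_statistic`, `p_value`, `n_lr`, `n_background`.
#' @export
compare_lr_vs_background <- function(fc_table, lr_gene_set) {
  is_lr <- fc_table$gene %in% lr_gene_set
  x <- fc_table$max_abs_log2fc[is_lr]
  y <- fc_table$max_abs_log2fc[!is_lr]
  if (!length(x) || !length(y))
    abort("both the LR group (%d genes) and the background (%d genes) must be non-empty",
          length(x), length(y))
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       n_lr = length(x), n_background = length(y))
}

#' Count expressed LR-database genes per subclass
#'
#' A gene counts as expressed in a subclass when its detection rate
#' reaches `detection_min` at any timepoint.
#'
#' @param profiles subclass-level profiles.
#' @param lr_db data.frame (`ligand`, `receptor`).
#' @param detection_min inclusive detection threshold.
#' @return data.frame: `subclass`, `n_ligands`, `n_receptors`.
#' @export
count_expressed_lr_genes <- function(profiles, lr_db, detection_min = 0.1) {
  pr <- as.data.table(profiles)
  if ("group_kind" %in% names(pr)) pr <- pr[pr$group_kind == "subclass"]
  subs <- unique(pr$group)
  res <- lapply(subs, function(s) {
    expressed <- unique(pr$gene[pr$group == s & pr$detection_rate >= detection_min])
    data.frame(subclass = s,
               n_ligands = length(intersect(unique(lr_db$ligand), expressed)),
               n_receptors = length(intersect(unique(lr_db$receptor), expressed)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res) %||% data.frame(subclass = character(0),
                                      n_ligands = integer(0),
                                      n_receptors = integer(0))
}

#' Pearson correlation between two expression profiles
#'
#' Correlates `log1p(mean_expr)` over the genes shared by the two
#' profiles; used as a cross-dataset compatibility check.
#'
#' @param profile_a,profile_b data.frames with columns `gene`,
#'   `mean_expr` (one group/timepoint each).
#' @return Pearson r (scalar).
#' @export
correlate_profiles <- function(profile_a, profile_b) {
  shared <- intersect(profile_a$gene, profile_b$gene)
  if (length(shared) < 3L)
    abort("need >= 3 shared genes, got %d", length(shared))
  a <- log1p(profile_a$mean_expr[match(shared, profile_a$gene)])
  b <- log1p(profile_b$mean_expr[match(shared, profile_b$gene)])
  stats::cor(a, b, method = "pearson")
}

#' Write profiles as TSV
#' @param profiles output of [summarize_profiles()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  data.table::fwrite(profiles, path, sep = "\t", quote = FALSE)
  invisible(path)
}
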
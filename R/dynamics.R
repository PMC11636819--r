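#' Flag temporally variable interactions
#'
#' The variability statistic is the largest pairwise fold change of the
#' score trajectory: over every pair of timepoints, take
#' `(S(t1) + epsilon) / (S(t2) + epsilon)` with the larger value in the
#' numerator; an interaction is variable when this exceeds `fc_cutoff`.
#' `epsilon` guards ratios against zero scores and defaults to 0.01.
#'
#' @param scores numeric score trajectory (ordered by timepoint), or a
#'   data.frame with columns `timepoint`, `S_LR`.
#' @param fc_cutoff fold-change cutoff (strictly exceeded to flag).
#' @param epsilon additive guard for zero scores.
#' @return list with `fc_max` and `variable`.
#' @export
flag_variable_interactions <- function(scores, fc_cutoff = 1.2, epsilon = 0.01) {
  s <- if (is.data.frame(scores)) scores$S_LR else as.numeric(scores)
  if (length(s) < 2L) abort("need >= 2 timepoints, got %d", length(s))
  v <- s + epsilon
  fc_max <- max(v) / min(v)
  list(fc_max = fc_max, variable = fc_max > fc_cutoff)
}

#' Canonical post-injury trajectory templates
#'
#' Shapes over (control, 12h, 24h, 48h) transcribing the four verbal
#' dynamic archetypes: a transient repression or activation that returns
#' to baseline by one day, a rapid sustained activation, and a slow
#' monotone activation.
#' @return named list of length-4 numeric templates.
#' @export
dynamic_templates <- function() {
  list(transient_repressed = c(0, -1, 0, 0),
       transient_activated = c(0, 1, 0, 0),
       rapid_sustained     = c(-1, 1, 1, 1),
       slow_activated      = c(-1, -1/3, 1/3, 1))
}

#' Assign a variable trajectory to a dynamic group
#'
#' Correlates the trajectory with each fixed template (Pearson, so the
#' assignment is invariant to affine transforms of the trajectory) and
#' returns the best match; ties break in template-list order. A
#' non-variable trajectory gets `"none"`.
#'
#' @param trajectory numeric scores in timepoint order (length must match
#'   the templates).
#' @param variable is the trajectory variable? Compute it with
#'   [flag_variable_interactions()]; when `NULL` it is derived from the
#'   trajectory with the given cutoff/epsilon.
#' @param templates named list of templates (see [dynamic_templates()]).
#' @param fc_cutoff,epsilon used only when `variable` is NULL.
#' @return the group name, or `"none"`.
#' @export
assign_dynamic_group <- function(trajectory, variable = NULL,
                                 templates = dynamic_templates(),
                                 fc_cutoff = 1.2, epsilon = 0.01) {
  if (is.null(variable))
    variable <- flag_variable_interactions(trajectory, fc_cutoff, epsilon)$variable
  if (!variable) return("none")
  if (stats::sd(trajectory) == 0) return("none")
  cors <- vapply(templates, function(tm) {
    if (length(tm) != length(trajectory))
      abort("template length %d != trajectory length %d",
            length(tm), length(trajectory))
    stats::cor(trajectory, tm)
  }, 0)
  names(templates)[which.max(cors)]
}

#' Trajectory table for all retained interactions
#'
#' @param scores retained scores (see [filter_interactions()]).
#' @param timepoints ordered timepoint labels.
#' @param fc_cutoff,epsilon see [flag_variable_interactions()].
#' @param templates see [dynamic_templates()].
#' @return `data.table` keyed by (sender, receiver, ligand, receptor)
#'   with one `S_<tp>` column per timepoint plus `fc_max`, `variable`,
#'   `group`.
#' @export
dynamics_table <- function(scores, timepoints = DEFAULT_TIMEPOINTS,
                           fc_cutoff = 1.2, epsilon = 0.01,
                           templates = dynamic_templates()) {
  sc <- as.data.table(scores)
  wide <- data.table::dcast(sc, sender + receiver + ligand + receptor ~ timepoint,
                            value.var = "S_LR")
  tps <- intersect(timepoints, names(wide))
  out <- wide[, c("sender", "receiver", "ligand", "receptor", tps), with = FALSE]
  data.table::setnames(out, tps, paste0("S_", tps))
  traj <- as.matrix(wide[, tps, with = FALSE])
  res <- t(apply(traj, 1L, function(x) {
    fv <- flag_variable_interactions(x, fc_cutoff, epsilon)
    c(fc_max = fv$fc_max, variable = fv$variable)
  }))
  out$fc_max <- res[, "fc_max"]
  out$variable <- as.logical(res[, "variable"])
  out$group <- vapply(seq_len(nrow(traj)), function(i)
    assign_dynamic_group(traj[i, ], variable = out$variable[i],
                         templates = templates), "")
  out[]
}

#' Data-driven alternative grouping by hierarchical clustering
#'
#' Average-linkage clustering on correlation distance of z-scored
#' trajectories, cut at `k` groups; mirrors heatmap-style grouping for
#' atlas outputs where fixed templates are too rigid.
#'
#' @param traj_matrix interactions x timepoints score matrix.
#' @param k number of clusters.
#' @return integer cluster labels.
#' @export
cluster_dynamic_groups <- function(traj_matrix, k = 4L) {
  z <- t(scale(t(traj_matrix)))
  z[!is.finite(z)] <- 0
  d <- stats::as.dist(1 - stats::cor(t(z)))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}
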
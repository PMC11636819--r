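#' Survival partition of receiver subclasses
#'
#' @param high,low disjoint, non-empty character vectors of subclass ids
#'   (defaults follow the resilient trio ipRGC / alphaRGC / Gpr88RGC vs
#'   the injury-susceptible rest of a six-subclass design).
#' @return object of class `survival_partition`.
#' @export
survival_partition <- function(high = c("ipRGC", "alphaRGC", "Gpr88RGC"),
                               low = c("T-RGC", "F-RGC", "N-RGC")) {
  if (!length(high) || !length(low))
    abort_validation("both partition sides must be non-empty")
  if (length(intersect(high, low)))
    abort_validation("partition sides overlap: %s",
                     paste(intersect(high, low), collapse = ", "))
  structure(list(high = as.character(high), low = as.character(low)),
            class = "survival_partition")
}

# per-subclass max over timepoints for one (sender, pair) score family;
# missing (subclass, timepoint) combinations are implicitly absent from
# the max; a subclass with no scores at all is handled per `missing`
subclass_max <- function(scores, subclasses, missing = c("zero", "skip"),
                         value_col = "S_LR") {
  missing <- match.arg(missing)
  sc <- as.data.table(scores)
  have <- sc[sc$receiver %in% subclasses,
             list(max_s = max(.SD[[1L]])), by = "receiver",
             .SDcols = value_col]
  vals <- stats::setNames(have$max_s, have$receiver)
  absent <- setdiff(subclasses, names(vals))
  if (length(absent)) {
    if (missing == "zero") {
      warning(sprintf("no scores for subclass(es) %s; treating their max as 0",
                      paste(absent, collapse = ", ")), call. = FALSE)
      vals[absent] <- 0
    }
  }
  vals
}

#' Differential interaction score between survival classes
#'
#' For one (sender, LR pair) family of scores across receiver subclasses
#' and timepoints: take each subclass's maximum score over timepoints,
#' average those maxima within the high-survival set and within the
#' low-survival set, and return high minus low. Values above the cutoff
#' mark interactions preferentially received by resilient subclasses.
#'
#' @param scores score rows for one sender and one LR pair; columns
#'   `receiver`, `timepoint`, `S_LR`.
#' @param partition a [survival_partition()].
#' @param missing how to treat a subclass with no scores: `"zero"`
#'   (default, counts as max 0 with a warning) or `"skip"` (drop it from
#'   its side's mean).
#' @return the differential score (scalar).
#' @export
compute_ds_lr <- function(scores, partition, missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  stopifnot(inherits(partition, "survival_partition"))
  hi <- subclass_max(scores, partition$high, missing)
  lo <- subclass_max(scores, partition$low, missing)
  if (!length(hi) || !length(lo))
    abort("an entire partition side has no scores (high: %d, low: %d subclasses scored)",
          length(hi), length(lo))
  mean(hi) - mean(lo)
}

#' Classify an interaction by its differential score
#'
#' Strict comparisons: above the cutoff is protective, below its negation
#' is stronger-in-low (a category the analysis must carry even when
#' empirically empty), anything else neutral.
#'
#' @param ds_lr numeric vector of differential scores.
#' @param cutoff positive cutoff (default 0.25).
#' @return character vector in
#'   `{"protective", "neutral", "stronger_in_low"}`.
#' @export
classify_protective <- function(ds_lr, cutoff = 0.25) {
  check_scalar_num(cutoff, "cutoff")
  if (cutoff <= 0) abort_validation("cutoff must be > 0")
  ifelse(ds_lr > cutoff, "protective",
         ifelse(ds_lr < -cutoff, "stronger_in_low", "neutral"))
}

#' Preset vs induced timing of a differential interaction
#'
#' `delta_pre` is the high-minus-low mean score difference at the control
#' timepoint; `delta_post` is the same difference on per-subclass maxima
#' over post-injury timepoints. Timing: `preset` when the advantage
#' already exists before injury (`delta_pre >= cutoff`); `induced` when
#' it only appears after (`delta_pre < cutoff` and
#' `delta_post >= cutoff`); otherwise `neither`.
#'
#' @param scores score rows for one (sender, pair) family; columns
#'   `receiver`, `timepoint`, `S_LR`.
#' @param partition a [survival_partition()].
#' @param cutoff score-difference cutoff shared by both axes.
#' @param control control timepoint label.
#' @param missing see [compute_ds_lr()].
#' @return list with `delta_pre`, `delta_post`, `timing`.
#' @export
classify_preset_induced <- function(scores, partition, cutoff = 0.25,
                                    control = "control",
                                    missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  sc <- as.data.table(scores)
  if (!control %in% sc$timepoint)
    abort("control timepoint '%s' missing from scores", control)
  pre <- sc[sc$timepoint == control]
  post <- sc[sc$timepoint != control]
  side_mean <- function(rows, subclasses) {
    v <- subclass_max(rows, subclasses, missing)
    if (!length(v)) abort("an entire partition side has no scores")
    mean(v)
  }
  delta_pre <- side_mean(pre, partition$high) - side_mean(pre, partition$low)
  delta_post <- side_mean(post, partition$high) - side_mean(post, partition$low)
  timing <- if (delta_pre >= cutoff) "preset"
            else if (delta_post >= cutoff) "induced"
            else "neither"
  list(delta_pre = delta_pre, delta_post = delta_post, timing = timing)
}

#' Autocrine vs paracrine signaling mode of a ligand
#'
#' At one timepoint (12 h post-injury in the reference analysis), checks
#' where the ligand is expressed: in >= 1 RGC subclass (detection at or
#' above `detection_min`), in >= 1 non-RGC cell type, or both.
#'
#' @param ligand gene id.
#' @param profiles profiles containing subclass and cell-type groups
#'   (see [summarize_profiles()] with `group_by = "both"`).
#' @param rgc_groups subclass group ids; `other_groups` non-RGC cell-type
#'   group ids. Defaults are inferred from `group_kind` when present.
#' @param other_groups see `rgc_groups`.
#' @param detection_min inclusive detection threshold.
#' @param timepoint timepoint to evaluate at.
#' @param rgc_type cell-type label to exclude from the non-RGC side when
#'   inferring groups.
#' @return `"autocrine"`, `"paracrine"`, `"both"`, or `"undefined"`
#'   (ligand detected nowhere; flagged with a warning).
#' @export
classify_signaling_mode <- function(ligand, profiles, rgc_groups = NULL,
                                    other_groups = NULL, detection_min = 0.1,
                                    timepoint = "12h", rgc_type = "RGC") {
  pr <- as.data.table(profiles)
  sel <- pr$timepoint == timepoint & pr$gene == ligand
  pr <- pr[which(sel)]
  if (!nrow(pr)) abort("no profiles for gene '%s' at timepoint '%s'",
                       ligand, timepoint)
  if (is.null(rgc_groups) && "group_kind" %in% names(pr))
    rgc_groups <- unique(pr$group[pr$group_kind == "subclass"])
  if (is.null(other_groups) && "group_kind" %in% names(pr))
    other_groups <- setdiff(unique(pr$group[pr$group_kind == "cell_type"]), rgc_type)
  in_rgc <- any(pr$detection_rate[pr$group %in% rgc_groups] >= detection_min)
  in_other <- any(pr$detection_rate[pr$group %in% other_groups] >= detection_min)
  if (in_rgc && in_other) "both"
  else if (in_rgc) "autocrine"
  else if (in_other) "paracrine"
  else {
    warning(sprintf("ligand '%s' not detected in any group at %s; mode undefined",
                    ligand, timepoint), call. = FALSE)
    "undefined"
  }
}

#' Full differential table over all (sender, pair) families
#'
#' Runs [compute_ds_lr()], [classify_protective()],
#' [classify_preset_induced()] and (optionally)
#' [classify_signaling_mode()] for every (sender, ligand, receptor)
#' present in `scores` whose receivers are subclasses in the partition.
#'
#' @param scores the FULL score table over all receiver subclasses (not
#'   just retained rows): per-receiver retention must not silence one
#'   partition side, or a pair retained only toward one side would get a
#'   zero-filled, inflated differential.
#' @param partition a [survival_partition()].
#' @param cutoff differential-score cutoff.
#' @param control control timepoint label.
#' @param profiles optional profiles for the signaling-mode call (skipped
#'   when NULL).
#' @param detection_min detection threshold for the mode call.
#' @param mode_timepoint timepoint for the mode call.
#' @param missing see [compute_ds_lr()].
#' @param retained optional retained scores from [filter_interactions()];
#'   when given, only (sender, pair) families retained toward >= 1
#'   receiver subclass are evaluated.
#' @return `data.table`: `sender`, `ligand`, `receptor`, `ds_lr`,
#'   `class`, `delta_pre`, `delta_post`, `timing`, `mode`.
#' @export
differential_table <- function(scores, partition, cutoff = 0.25,
                               control = "control", profiles = NULL,
                               detection_min = 0.1, mode_timepoint = "12h",
                               missing = "zero", retained = NULL) {
  sc <- as.data.table(scores)
  sc <- sc[sc$receiver %in% c(partition$high, partition$low)]
  fams <- unique(sc[, c("sender", "ligand", "receptor")])
  if (!is.null(retained)) {
    rt <- as.data.table(retained)
    rt <- rt[rt$receiver %in% c(partition$high, partition$low)]
    fams <- fams[paste(fams$sender, fams$ligand, fams$receptor) %in%
                   unique(paste(rt$sender, rt$ligand, rt$receptor))]
  }
  if (!nrow(fams))
    return(data.table::data.table(sender = character(0), ligand = character(0),
                                  receptor = character(0), ds_lr = numeric(0),
                                  class = character(0), delta_pre = numeric(0),
                                  delta_post = numeric(0), timing = character(0),
                                  mode = character(0)))
  rows <- lapply(seq_len(nrow(fams)), function(i) {
    fam <- sc[sc$sender == fams$sender[i] & sc$ligand == fams$ligand[i] &
                sc$receptor == fams$receptor[i]]
    ds <- compute_ds_lr(fam, partition, missing = missing)
    ti <- classify_preset_induced(fam, partition, cutoff = cutoff,
                                  control = control, missing = missing)
    data.table::data.table(
      sender = fams$sender[i], ligand = fams$ligand[i],
      receptor = fams$receptor[i], ds_lr = ds,
      class = classify_protective(ds, cutoff),
      delta_pre = ti$delta_pre, delta_post = ti$delta_post,
      timing = ti$timing)
  })
  out <- data.table::rbindlist(rows)
  out$mode <- NA_character_
  if (!is.null(profiles)) {
    modes <- vapply(unique(out$ligand), function(lg)
      classify_signaling_mode(lg, profiles, detection_min = detection_min,
                              timepoint = mode_timepoint), "")
    out$mode <- modes[out$ligand]
  }
  out[]
}

#' Roll protective interactions up to non-redundant pairs
#'
#' Two roll-ups of the per-sender protective calls: by (ligand,
#' receptor) identity alone (the "non-redundant" union) and by (sender,
#' ligand, receptor).
#'
#' @param diff_table output of [differential_table()].
#' @return list with `by_pair` (data.frame of unique protective pairs
#'   and their sender count) and `by_sender_pair` (the protective rows).
#' @export
rollup_protective <- function(diff_table) {
  dt <- as.data.table(diff_table)
  prot <- dt[dt$class == "protective"]
  by_pair <- prot[, list(n_senders = length(unique(sender)),
                         max_ds_lr = if (.N) max(ds_lr) else numeric(0)),
                  by = c("ligand", "receptor")]
  list(by_pair = as.data.frame(by_pair),
       by_sender_pair = as.data.frame(prot))
}

#' Survival-adjusted subclass proportions
#'
#' Normalizes subclass cell counts to within-condition shares, scales
#' each non-sham condition's shares by that condition's overall survival
#' rate, and divides by the sham share to estimate per-subclass
#' survival. By construction the adjusted shares of a condition sum to
#' its overall survival rate.
#'
#' @param counts data.frame with columns `subclass`, `condition`, `n`
#'   (cell counts); must include the sham condition.
#' @param overall_survival named numeric vector of overall survival
#'   rates for each non-sham condition (e.g.
#'   `c(onc = 0.638, onc_oprm1 = 0.854)`).
#' @param sham label of the uninjured reference condition.
#' @return data.frame: `subclass`, `condition`, `share_sham`,
#'   `share_cond`, `adjusted_share`, `est_subclass_survival`.
#' @export
adjust_subclass_survival <- function(counts, overall_survival, sham = "sham") {
  cdt <- as.data.table(counts)
  if (!all(c("subclass", "condition", "n") %in% names(cdt)))
    abort("'counts' needs columns subclass, condition, n")
  if (!sham %in% cdt$condition)
    abort("sham condition '%s' absent from counts", sham)
  sham_rows <- cdt[cdt$condition == sham]
  if (any(sham_rows$n <= 0))
    abort("sham counts must be positive for every subclass")
  sham_share <- stats::setNames(sham_rows$n / sum(sham_rows$n), sham_rows$subclass)
  conds <- names(overall_survival)
  miss <- setdiff(conds, unique(cdt$condition))
  if (length(miss)) abort("condition(s) absent from counts: %s",
                          paste(miss, collapse = ", "))
  rows <- lapply(conds, function(cc) {
    r <- cdt[cdt$condition == cc]
    absent <- setdiff(r$subclass, names(sham_share))
    if (length(absent))
      abort("subclass(es) absent from sham: %s", paste(absent, collapse = ", "))
    share <- r$n / sum(r$n)
    surv <- overall_survival[[cc]]
    data.frame(subclass = r$subclass, condition = cc,
               share_sham = unname(sham_share[r$subclass]),
               share_cond = share,
               adjusted_share = share * surv,
               est_subclass_survival = share * surv / unname(sham_share[r$subclass]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
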
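default_config <- function() {
  list(
    seed = 1L,
    out_dir = "lrcomm_out",
    input = NULL,        # list(mtx, features, barcodes, metadata, lr_pairs, network)
    simulate = list(
      enabled = TRUE,
      n_cell_types = 8L,
      subclasses_high = c("ipRGC", "alphaRGC"),
      subclasses_low = c("T-RGC", "N-RGC"),
      cells_per_group = 500L,
      n_genes = 300L,
      n_planted = 10L,
      n_decoys = 20L,
      prop_induced = 0.5,
      prop_loops = 0.5,
      ligand_boost = 4,
      receptor_boost = 8,
      noise_sd = 0.1,
      extra_edges = 0L),
    qc = list(enabled = TRUE, preset = "synthetic", thresholds = NULL),
    scoring = list(alpha = 0.5, gamma = 0.5, K = 3L,
                   strict_all_timepoints = FALSE,
                   prune_network_by_detection = FALSE,
                   min_cells = 10L),
    partition = NULL,    # list(high = ..., low = ...); defaults to simulate's
    cutoffs = list(ds = 0.25, fc = 1.2, score_min = 0.5,
                   detection_min = 0.10, epsilon = 0.01),
    timepoints = DEFAULT_TIMEPOINTS,
    stages = list(qc = TRUE, profiles = TRUE, score = TRUE,
                  differential = TRUE, dynamics = TRUE))
}

merge_section <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort_validation("unknown config key(s) under '%s': %s", path,
                     paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_section(defaults[[k]], user[[k]],
                                     paste0(path, ".", k))
    } else {
      v <- if (is.list(user[[k]]) &&
               all(vapply(user[[k]], length, 0L) == 1L))
        unlist(user[[k]]) else user[[k]]
      defaults[k] <- list(v)  # single-bracket: a NULL must not drop the key
    }
  }
  defaults
}

validate_config <- function(cfg) {
  check_scalar_num(cfg$cutoffs$ds, "cutoffs.ds", 0, Inf)
  if (cfg$cutoffs$ds <= 0) abort_validation("cutoffs.ds must be > 0")
  check_scalar_num(cfg$cutoffs$fc, "cutoffs.fc", 1, Inf)
  check_scalar_num(cfg$cutoffs$score_min, "cutoffs.score_min", 0, 1)
  check_scalar_num(cfg$cutoffs$detection_min, "cutoffs.detection_min", 0, 1)
  check_scalar_num(cfg$cutoffs$epsilon, "cutoffs.epsilon", 0, Inf)
  check_scalar_num(cfg$scoring$alpha, "scoring.alpha", 0, 1)
  check_scalar_num(cfg$scoring$gamma, "scoring.gamma", 0, 1)
  check_scalar_num(cfg$seed, "seed", 0, 2^31 - 1)
  if (!is.null(cfg$partition))
    survival_partition(cfg$partition$high, cfg$partition$low)
  cfg
}

#' Parse a pipeline configuration file
#'
#' JSON with the sections of `default_config()`: `seed`, `out_dir`,
#' `input`, `simulate`, `qc`, `scoring`, `partition`, `cutoffs`,
#' `timepoints`, `stages`. Absent keys get defaults; unknown keys are
#' rejected; out-of-range cutoffs raise a validation error naming the
#' key.
#'
#' @param path JSON file.
#' @return validated config list (class `lrcomm_config`).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_section(default_config(), user, "config")
  cfg$seed <- as.integer(cfg$seed)
  structure(validate_config(cfg), class = "lrcomm_config")
}

#' Write a configuration as JSON
#' @param cfg config list.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_partition <- function(cfg) {
  if (!is.null(cfg$partition))
    return(survival_partition(cfg$partition$high, cfg$partition$low))
  survival_partition(cfg$simulate$subclasses_high, cfg$simulate$subclasses_low)
}

config_design <- function(cfg) {
  s <- cfg$simulate
  rgc <- data.frame(
    name = c(s$subclasses_high, s$subclasses_low),
    survival_class = c(rep("high", length(s$subclasses_high)),
                       rep("low", length(s$subclasses_low))),
    stringsAsFactors = FALSE)
  synthetic_design(
    n_planted = s$n_planted, n_decoys = s$n_decoys,
    prop_induced = s$prop_induced, prop_loops = s$prop_loops,
    ligand_boost = s$ligand_boost, receptor_boost = s$receptor_boost,
    n_genes = s$n_genes, n_cell_types = s$n_cell_types,
    rgc_subclasses = rgc, timepoints = cfg$timepoints,
    cells_per_group = s$cells_per_group, noise_sd = s$noise_sd,
    seed = cfg$seed)
}

#' Run the pipeline end to end
#'
#' Stages: simulate (or load the configured input bundle), per-cell QC,
#' profile summarization, interaction scoring, retention filtering,
#' differential protection calling, and dynamics classification. Each
#' stage logs a timing line; artifacts are written as TSV plus a
#' `report.json` with a config echo and per-stage counts. Identical
#' config and seed give identical outputs.
#'
#' @param cfg a config from [parse_config()] or `default_config()`
#'   overrides.
#' @param quiet suppress log lines.
#' @return the run report (list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "lrcomm_config"))
    cfg <- structure(validate_config(merge_section(default_config(), cfg,
                                                   "config")),
                     class = "lrcomm_config")
  log_line <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0_all <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("lrcomm")),
                 config = unclass(cfg), stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e),
            class = "lrcomm_stage_error"))
    log_line("[%s] done in %.2fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  truth <- NULL
  if (isTRUE(cfg$simulate$enabled) && is.null(cfg$input)) {
    sim <- stage("simulate", {
      design <- config_design(cfg)
      simulate_experiment(design)
    })
    atlas <- sim$atlas
    truth <- sim$truth
    network <- stage("network",
                     build_synthetic_network(truth, cfg$simulate$extra_edges))
    lr_db <- truth_lr_pairs(truth)
    export_truth(truth, file.path(cfg$out_dir, "truth.json"))
    report$stages$simulate <- list(
      n_cells = ncol(atlas), n_genes = nrow(atlas),
      n_planted = length(truth$planted), n_decoys = length(truth$decoys))
  } else {
    inp <- cfg$input
    atlas <- stage("load", load_expression(inp$mtx, inp$features, inp$barcodes,
                                           inp$metadata, cfg$timepoints))
    lr_db <- stage("load_lr", read_lr_pairs(inp$lr_pairs))
    network <- stage("load_network", read_network(inp$network))
    report$stages$load <- list(n_cells = ncol(atlas), n_genes = nrow(atlas),
                               n_pairs = nrow(lr_db), n_edges = nrow(network))
  }

  if (isTRUE(cfg$stages$qc) && isTRUE(cfg$qc$enabled)) {
    qc <- stage("qc", {
      th <- if (!is.null(cfg$qc$thresholds))
        do.call(qc_thresholds, as.list(cfg$qc$thresholds))
      else qc_preset(cfg$qc$preset)
      qc_filter_cells(atlas, th)
    })
    atlas <- qc$atlas
    write_results(list(qc_report = qc$report), cfg$out_dir)
    report$stages$qc <- list(retained = ncol(atlas),
                             removed = qc$report$removed[qc$report$criterion == "removed_total"])
  } else report$stages$qc <- list(skipped = TRUE)

  if (!isTRUE(cfg$stages$profiles)) {
    report$stages$profiles <- list(skipped = TRUE)
    return(finish_report(report, cfg, t0_all, quiet))
  }
  profiles <- stage("profiles", summarize_profiles(atlas, group_by = "both"))
  write_profiles(profiles, file.path(cfg$out_dir, "profiles.tsv"))
  report$stages$profiles <- list(n_groups = length(unique(profiles$group)))

  if (!isTRUE(cfg$stages$score)) {
    report$stages$score <- list(skipped = TRUE)
    return(finish_report(report, cfg, t0_all, quiet))
  }
  params <- scoring_params(
    alpha = cfg$scoring$alpha, gamma = cfg$scoring$gamma, K = cfg$scoring$K,
    detection_min = cfg$cutoffs$detection_min,
    score_min = cfg$cutoffs$score_min,
    strict_all_timepoints = isTRUE(cfg$scoring$strict_all_timepoints),
    prune_network_by_detection = isTRUE(cfg$scoring$prune_network_by_detection),
    min_cells = cfg$scoring$min_cells)
  cd <- as.data.frame(SummarizedExperiment::colData(atlas))
  cell_types <- unique(cd$cell_type)
  subclasses <- unique(cd$subclass[!is.na(cd$subclass)])
  scores <- stage("score",
                  score_interactions(profiles, lr_db, network, params,
                                     senders = cell_types,
                                     receivers = subclasses))
  retained <- stage("filter", filter_interactions(scores, profiles, params))
  data.table::fwrite(scores, file.path(cfg$out_dir, "scores.tsv"), sep = "\t")
  data.table::fwrite(retained, file.path(cfg$out_dir, "scores_retained.tsv"),
                     sep = "\t")
  fs <- attr(retained, "filter_summary")
  report$stages$score <- list(pairs_scored = nrow(lr_db),
                              triples = fs$n_triples,
                              retained = fs$retained,
                              fail_detection = fs$fail_detection,
                              fail_score = fs$fail_score)

  if (isTRUE(cfg$stages$differential)) {
    partition <- config_partition(cfg)
    diff_tab <- stage("differential",
                      differential_table(scores, partition,
                                         cutoff = cfg$cutoffs$ds,
                                         profiles = profiles,
                                         detection_min = cfg$cutoffs$detection_min,
                                         retained = retained))
    data.table::fwrite(diff_tab, file.path(cfg$out_dir, "differential.tsv"),
                       sep = "\t")
    report$stages$differential <- list(
      n_families = nrow(diff_tab),
      protective = sum(diff_tab$class == "protective"),
      neutral = sum(diff_tab$class == "neutral"),
      stronger_in_low = sum(diff_tab$class == "stronger_in_low"),
      timing = as.list(table(diff_tab$timing)),
      mode = as.list(table(diff_tab$mode)))
  } else report$stages$differential <- list(skipped = TRUE)

  if (isTRUE(cfg$stages$dynamics)) {
    dyn <- stage("dynamics",
                 dynamics_table(retained, timepoints = cfg$timepoints,
                                fc_cutoff = cfg$cutoffs$fc,
                                epsilon = cfg$cutoffs$epsilon))
    data.table::fwrite(dyn, file.path(cfg$out_dir, "dynamics.tsv"), sep = "\t")
    report$stages$dynamics <- list(
      n = nrow(dyn), variable = sum(dyn$variable),
      groups = as.list(table(dyn$group[dyn$variable])))
  } else report$stages$dynamics <- list(skipped = TRUE)

  finish_report(report, cfg, t0_all, quiet)
}

finish_report <- function(report, cfg, t0_all, quiet) {
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0_all, units = "secs"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  if (!quiet) message(sprintf("pipeline finished in %.2fs", report$elapsed_s))
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (and stage-limited variants `simulate`, `qc`,
#' `profile`, `score`, `differential`, `dynamics`), which take
#' `--config <path>` and optionally `--out <dir>`; and `fishquant`,
#' which takes `--dots <tsv> --region <json>` plus a calibration bundle
#' `--cal-dots/--cal-region` (defaults to the field itself) and writes a
#' JSON estimate to `--out`. Exit codes: 0 ok, 2 validation error, 3
#' stage failure.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return the exit code, invisibly.
#' @export
lr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lrcomm <subcommand> [--config cfg.json] [--out dir]",
    "  subcommands: run-all simulate qc profile score differential dynamics fishquant",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  sub <- args[[1L]]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
  }
  code <- tryCatch({
    if (sub == "fishquant") {
      dots <- opt("--dots"); region <- opt("--region")
      if (is.null(dots) || is.null(region))
        abort_validation("fishquant requires --dots and --region")
      field <- read_dot_field(dots, region)
      cal <- if (!is.null(opt("--cal-dots")))
        read_dot_field(opt("--cal-dots"), opt("--cal-region")) else field
      avg <- average_dot_intensity(cal)
      est <- estimate_dot_count(field, avg)
      out <- opt("--out", "fishquant.json")
      jsonlite::write_json(list(avg_intensity_per_dot = avg,
                                estimated_dot_count = est),
                           out, auto_unbox = TRUE, digits = NA)
      message(sprintf("avg intensity/dot = %g; estimated dots = %g", avg, est))
      0L
    } else if (sub %in% c("run-all", "simulate", "qc", "profile", "score",
                          "differential", "dynamics")) {
      cfg_path <- opt("--config")
      cfg <- if (is.null(cfg_path))
        structure(validate_config(default_config()), class = "lrcomm_config")
      else parse_config(cfg_path)
      out <- opt("--out"); if (!is.null(out)) cfg$out_dir <- out
      seed <- opt("--seed"); if (!is.null(seed)) cfg$seed <- as.integer(seed)
      lim <- list(simulate = "qc", qc = "profiles", profile = "score",
                  score = "differential", differential = "dynamics")
      if (sub %in% names(lim)) {
        off <- switch(sub,
          simulate = c("qc", "profiles", "score", "differential", "dynamics"),
          qc = c("profiles", "score", "differential", "dynamics"),
          profile = c("score", "differential", "dynamics"),
          score = c("differential", "dynamics"),
          differential = "dynamics")
        for (s in off) cfg$stages[[s]] <- FALSE
      }
      run_pipeline(cfg)
      0L
    } else {
      message(usage)
      2L
    }
  },
  lrcomm_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 2L },
  lrcomm_stage_error = function(e) { message(conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  invisible(code)
}
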
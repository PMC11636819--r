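#' Declare a planted ligand-receptor interaction
#'
#' A planted interaction is the generator's ground truth: a ligand boosted
#' in one sender cell type and a receptor boosted in a set of target
#' (receiver) subclasses. Two temporal archetypes are supported. A
#' `preset` interaction keeps the same receptor multiplier at every
#' timepoint (constantly stronger toward its targets); an `induced`
#' interaction starts at multiplier 1 in the control and rises after
#' injury. The per-timepoint receptor multiplier in target subclasses is
#' exactly `induction_schedule`; `receptor_boost` only seeds the default
#' schedule (`preset`: flat at `receptor_boost`; `induced`: 1 at control,
#' `receptor_boost` afterwards). The ligand multiplier in the sender is
#' `ligand_boost`, constant over time.
#'
#' @param ligand,receptor gene ids.
#' @param sender sender cell-type id.
#' @param target_subclasses character vector of receiver subclass ids.
#' @param pattern `"preset"` or `"induced"`.
#' @param ligand_boost,receptor_boost multiplicative boosts, >= 1.
#' @param induction_schedule optional named per-timepoint multipliers;
#'   overrides the default schedule.
#' @param has_loop does a reciprocal (receiver to sender) pair close a
#'   feedback loop through the network?
#' @param loop_partner list with `ligand` and `receptor` gene ids of the
#'   reverse-direction pair (required when `has_loop`).
#' @param timepoints ordered timepoint labels the schedule is indexed by.
#' @return an object of class `planted_interaction`.
#' @export
planted_interaction <- function(ligand, receptor, sender, target_subclasses,
                                pattern = c("preset", "induced"),
                                ligand_boost = 4, receptor_boost = 8,
                                induction_schedule = NULL,
                                has_loop = FALSE, loop_partner = NULL,
                                timepoints = DEFAULT_TIMEPOINTS) {
  pattern <- match.arg(pattern)
  check_scalar_num(ligand_boost, "ligand_boost", 1)
  check_scalar_num(receptor_boost, "receptor_boost", 1)
  check_flag(has_loop, "has_loop")
  if (is.null(induction_schedule)) {
    induction_schedule <- if (pattern == "preset")
      stats::setNames(rep(receptor_boost, length(timepoints)), timepoints)
    else
      stats::setNames(c(1, rep(receptor_boost, length(timepoints) - 1L)),
                      timepoints)
  }
  if (is.null(names(induction_schedule)) ||
      !setequal(names(induction_schedule), timepoints))
    abort_validation("induction_schedule must be named by the timepoints")
  induction_schedule <- induction_schedule[timepoints]
  if (has_loop && (is.null(loop_partner) ||
                   !all(c("ligand", "receptor") %in% names(loop_partner))))
    abort_validation("has_loop requires loop_partner = list(ligand=, receptor=)")
  structure(list(ligand = ligand, receptor = receptor, sender = sender,
                 target_subclasses = as.character(target_subclasses),
                 pattern = pattern,
                 ligand_boost = ligand_boost, receptor_boost = receptor_boost,
                 induction_schedule = induction_schedule,
                 has_loop = has_loop,
                 loop_partner = if (has_loop) loop_partner[c("ligand", "receptor")] else NULL),
            class = "planted_interaction")
}

#' Specify a synthetic experiment design
#'
#' The stated world every test runs in: a multi-timepoint retina-like
#' atlas with `n_cell_types` cell types of which one ("RGC") is split
#' into survival-labeled subclasses, negative-binomial counts with a
#' single global dispersion, lognormal gene baselines, per-cell lognormal
#' library-size factors, and optional multiplicative lognormal noise on
#' every (gene, group, timepoint) mean.
#'
#' @param n_cell_types total number of cell types including the RGC type.
#' @param rgc_subclasses data.frame with columns `name` and
#'   `survival_class` (`"high"` / `"low"`).
#' @param timepoints ordered labels, control first.
#' @param cells_per_group cells simulated per (group, timepoint); a group
#'   is a non-RGC cell type or an RGC subclass.
#' @param n_genes gene-universe size.
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of the
#'   per-gene baseline mean.
#' @param nb_dispersion negative-binomial size parameter (> 0).
#' @param marker_boost multiplier on each group's marker gene (>= 1).
#' @param planted list of [planted_interaction()] objects.
#' @param decoys list of lists `(ligand, receptor, sender, ligand_boost,
#'   receptor_boost)`; decoy receptors are boosted identically in ALL
#'   subclasses, so they match planted marginal levels with no subclass
#'   bias.
#' @param noise_sd lognormal sd of the per-(gene, group, timepoint) mean
#'   jitter (0 disables).
#' @param lib_size_sd lognormal sd of per-cell library factors.
#' @param seed master RNG seed.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_cell_types = 14,
                       rgc_subclasses = data.frame(
                         name = c("ipRGC", "alphaRGC", "Gpr88RGC",
                                  "T-RGC", "F-RGC", "N-RGC"),
                         survival_class = c("high", "high", "high",
                                            "low", "low", "low"),
                         stringsAsFactors = FALSE),
                       timepoints = DEFAULT_TIMEPOINTS,
                       cells_per_group = 500L,
                       n_genes = 300L,
                       baseline_log_mean = 0,
                       baseline_log_sd = 0.5,
                       nb_dispersion = 2,
                       marker_boost = 5,
                       planted = list(),
                       decoys = list(),
                       noise_sd = 0.1,
                       lib_size_sd = 0.2,
                       seed = 1L) {
  design <- structure(list(
    n_cell_types = as.integer(n_cell_types),
    rgc_subclasses = as.data.frame(rgc_subclasses, stringsAsFactors = FALSE),
    timepoints = timepoints,
    cells_per_group = as.integer(cells_per_group),
    n_genes = as.integer(n_genes),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion,
    marker_boost = marker_boost,
    planted = planted,
    decoys = decoys,
    noise_sd = noise_sd,
    lib_size_sd = lib_size_sd,
    seed = as.integer(seed)), class = "sim_design")
  validate_design(design)
  design
}

design_cell_types <- function(design) {
  c(sprintf("CT%02d", seq_len(design$n_cell_types - 1L)), "RGC")
}

design_groups <- function(design) {
  c(sprintf("CT%02d", seq_len(design$n_cell_types - 1L)),
    design$rgc_subclasses$name)
}

design_genes <- function(design) sprintf("g%04d", seq_len(design$n_genes))

#' Validate a simulation design
#'
#' Checks every design invariant and fails with a message naming the
#' first violated one.
#' @param design a `sim_design`.
#' @return invisibly `TRUE`.
#' @export
validate_design <- function(design) {
  sc <- design$rgc_subclasses
  if (!all(c("name", "survival_class") %in% names(sc)))
    abort_validation("invariant violated: rgc_subclasses needs columns name, survival_class")
  if (!any(sc$survival_class == "high") || !any(sc$survival_class == "low"))
    abort_validation("invariant violated: need >=1 high and >=1 low survival subclass")
  if (!all(sc$survival_class %in% c("high", "low")))
    abort_validation("invariant violated: survival_class must be 'high' or 'low'")
  if (length(design$timepoints) < 2L || design$timepoints[1L] != "control")
    abort_validation("invariant violated: timepoints must have >=2 entries with 'control' first")
  if (design$n_cell_types < 2L)
    abort_validation("invariant violated: need >=2 cell types (one is the RGC type)")
  check_scalar_num(design$nb_dispersion, "nb_dispersion")
  if (design$nb_dispersion <= 0)
    abort_validation("invariant violated: nb_dispersion must be > 0")
  if (design$marker_boost < 1)
    abort_validation("invariant violated: marker_boost must be >= 1")
  if (design$noise_sd < 0)
    abort_validation("invariant violated: noise_sd must be >= 0")
  cts <- design_cell_types(design)
  post <- design$timepoints[-1L]
  for (p in design$planted) {
    if (!inherits(p, "planted_interaction"))
      abort_validation("invariant violated: planted entries must be planted_interaction objects")
    if (!p$sender %in% cts)
      abort_validation("invariant violated: planted sender '%s' is not a declared cell type", p$sender)
    if (!length(p$target_subclasses))
      abort_validation("invariant violated: target_subclasses is empty for %s-%s", p$ligand, p$receptor)
    if (!all(p$target_subclasses %in% sc$name))
      abort_validation("invariant violated: unknown target subclass for %s-%s", p$ligand, p$receptor)
    if (p$ligand_boost < 1 || p$receptor_boost < 1 || any(p$induction_schedule < 0))
      abort_validation("invariant violated: boosts must be >= 1 for %s-%s", p$ligand, p$receptor)
    if (!setequal(names(p$induction_schedule), design$timepoints))
      abort_validation("invariant violated: schedule timepoints mismatch for %s-%s", p$ligand, p$receptor)
    if (p$pattern == "induced") {
      if (p$induction_schedule[["control"]] != 1)
        abort_validation("invariant violated: induced pattern must have control multiplier 1.0 (%s-%s)", p$ligand, p$receptor)
      if (!any(p$induction_schedule[post] > 1))
        abort_validation("invariant violated: induced pattern needs a post-injury multiplier > 1 (%s-%s)", p$ligand, p$receptor)
    } else if (length(unique(p$induction_schedule)) != 1L) {
      abort_validation("invariant violated: preset pattern must have identical multipliers at all timepoints (%s-%s)", p$ligand, p$receptor)
    }
  }
  keys <- function(x) vapply(x, function(e) paste(e$ligand, e$receptor, e$sender), "")
  if (length(intersect(keys(design$planted), keys(design$decoys))))
    abort_validation("invariant violated: planted and decoy sets overlap")
  invisible(TRUE)
}

#' Build a fully wired acceptance-style design
#'
#' Convenience constructor that allocates gene ids for planted pairs
#' (alternating preset/induced, with feedback-loop partners on a subset),
#' decoy pairs, per-group markers, transcription factors and
#' network-support target genes, then returns a valid [sim_design()].
#' Boost defaults (ligand 4x, receptor 8x) are the package's calibration
#' of a "strong" protective interaction: with full network support they
#' put the design's timepoint-maximal score gap between boosted and
#' unboosted subclasses near 1 - sqrt(1/8) ~ 0.65.
#'
#' @param n_planted,n_decoys numbers of planted and decoy pairs.
#' @param prop_induced fraction of planted pairs given the induced
#'   archetype (the rest are preset).
#' @param prop_loops fraction of planted pairs wired with a feedback
#'   loop partner.
#' @param n_mito number of mitochondrial ("mt-") genes for QC exercises.
#' @param ... further arguments to [sim_design()] (e.g. `n_cell_types`,
#'   `rgc_subclasses`, `cells_per_group`, `seed`).
#' @inheritParams sim_design
#' @return a `sim_design` whose planted/decoy gene ids are disjoint;
#'   allocation details are attached as attributes `tf_genes` and
#'   `support_targets` (consumed by [build_synthetic_network()]).
#' @export
synthetic_design <- function(n_planted = 10, n_decoys = 20,
                             prop_induced = 0.5, prop_loops = 0.5,
                             ligand_boost = 4, receptor_boost = 8,
                             n_genes = 300L, n_mito = 5L, ...) {
  dots <- list(...)
  base <- do.call(sim_design, c(list(n_genes = n_genes), dots))
  genes <- design_genes(base)
  sc <- base$rgc_subclasses
  high <- sc$name[sc$survival_class == "high"]
  cts <- design_cell_types(base)
  senders <- setdiff(cts, "RGC")
  tp <- base$timepoints

  n_loops <- floor(n_planted * prop_loops)
  # front allocation: pair genes, per-planted TFs (looped pairs get two),
  # one TF shared by all decoys, support targets
  need <- 2L * n_planted + 2L * n_loops + 2L * n_decoys +
    n_planted + n_loops + (n_decoys > 0L) + 4L
  n_markers <- length(design_groups(base))
  mb <- base$marker_boost
  if (need + n_mito > n_genes ||
      (mb > 1 && need + n_mito + n_markers > n_genes))
    abort_validation("n_genes=%d too small for %d planted + %d decoys (need >= %d)",
                     n_genes, n_planted, n_decoys,
                     need + n_mito + if (mb > 1) n_markers else 0L)
  take <- local({ i <- 0L; function(k) { on.exit(i <<- i + k, add = TRUE); genes[i + seq_len(k)] } })

  planted <- vector("list", n_planted)
  tf_genes <- character(0)
  support_targets <- take(4L)
  for (i in seq_len(n_planted)) {
    lg <- take(1L); rc <- take(1L)
    has_loop <- i <= n_loops
    partner <- NULL
    if (has_loop) partner <- list(ligand = take(1L), receptor = take(1L))
    pattern <- if (i %% 2L == 0L && prop_induced > 0) "induced" else "preset"
    if (prop_induced >= 1) pattern <- "induced"
    if (prop_induced <= 0) pattern <- "preset"
    planted[[i]] <- planted_interaction(
      ligand = lg, receptor = rc,
      sender = senders[((i - 1L) %% length(senders)) + 1L],
      target_subclasses = high, pattern = pattern,
      ligand_boost = ligand_boost, receptor_boost = receptor_boost,
      has_loop = has_loop, loop_partner = partner, timepoints = tp)
    tf_genes <- c(tf_genes, take(1L))
    if (has_loop) tf_genes <- c(tf_genes, take(1L))
  }
  decoys <- lapply(seq_len(n_decoys), function(i) {
    list(ligand = take(1L), receptor = take(1L),
         sender = senders[((i - 1L) %% length(senders)) + 1L],
         ligand_boost = ligand_boost, receptor_boost = receptor_boost)
  })
  decoy_tfs <- if (n_decoys > 0L) take(1L) else character(0)

  des <- do.call(sim_design, c(list(n_genes = n_genes, planted = planted,
                                    decoys = decoys), dots))
  if (n_mito > 0) {
    # rename tail genes to the mitochondrial prefix (kept out of allocation)
    mito <- genes[(n_genes - n_mito + 1L):n_genes]
    attr(des, "mito_genes") <- sub("^g", "mt-", mito)
  }
  attr(des, "tf_genes") <- tf_genes
  attr(des, "decoy_tfs") <- decoy_tfs
  attr(des, "support_targets") <- support_targets
  des
}

# per-(gene, group, timepoint) design means before noise/library factors
design_mean_array <- function(design, baseline) {
  genes <- design_genes(design)
  groups <- design_groups(design)
  tp <- design$timepoints
  arr <- array(rep(baseline, times = length(groups) * length(tp)),
               dim = c(length(genes), length(groups), length(tp)),
               dimnames = list(genes, groups, tp))
  # one marker gene per group, constant boost (last genes of the universe,
  # before any mito-renamed tail)
  marker_idx <- length(genes) - length(groups) + seq_along(groups) -
    length(attr(design, "mito_genes") %||% character(0))
  marker_idx <- marker_idx[marker_idx >= 1]
  for (j in seq_along(marker_idx))
    arr[marker_idx[j], j, ] <- arr[marker_idx[j], j, ] * design$marker_boost
  for (p in design$planted) {
    arr[p$ligand, p$sender, ] <- arr[p$ligand, p$sender, ] * p$ligand_boost
    for (s in p$target_subclasses)
      arr[p$receptor, s, ] <- arr[p$receptor, s, ] *
        p$induction_schedule[tp]
    if (p$has_loop) {
      for (s in p$target_subclasses)
        arr[p$loop_partner$ligand, s, ] <-
          arr[p$loop_partner$ligand, s, ] * p$ligand_boost
      arr[p$loop_partner$receptor, p$sender, ] <-
        arr[p$loop_partner$receptor, p$sender, ] * p$receptor_boost
    }
  }
  for (d in design$decoys) {
    arr[d$ligand, d$sender, ] <- arr[d$ligand, d$sender, ] * d$ligand_boost
    for (s in design$rgc_subclasses$name)   # all subclasses: no bias
      arr[d$receptor, s, ] <- arr[d$receptor, s, ] * d$receptor_boost
  }
  arr
}

#' Simulate a labeled multi-timepoint expression atlas
#'
#' Draws negative-binomial counts with per-(gene, group, timepoint) means
#' equal to lognormal gene baselines times the design's boost structure,
#' optionally jittered by multiplicative lognormal noise, and scaled per
#' cell by a lognormal library factor. Deterministic given `design$seed`.
#'
#' @param design a valid [sim_design()].
#' @return list with `atlas` (see [build_atlas()]) and `truth`, a
#'   `synthetic_truth` object holding the planted interactions, decoys,
#'   a design echo, and the realized mean array (`realized_means`,
#'   excluded from JSON export).
#' @export
simulate_experiment <- function(design) {
  validate_design(design)
  set.seed(child_seed(design$seed, "simulate"))
  genes <- design_genes(design)
  mito <- attr(design, "mito_genes")
  groups <- design_groups(design)
  tp <- design$timepoints
  sc <- design$rgc_subclasses
  n_g <- length(genes)

  baseline <- stats::rlnorm(n_g, design$baseline_log_mean, design$baseline_log_sd)
  arr <- design_mean_array(design, baseline)
  if (design$noise_sd > 0)
    arr <- arr * stats::rlnorm(length(arr), 0, design$noise_sd)

  ncells <- design$cells_per_group
  blocks <- vector("list", length(groups) * length(tp))
  meta <- vector("list", length(blocks))
  k <- 0L
  for (t in tp) for (g in groups) {
    k <- k + 1L
    mu <- arr[, g, t]
    lib <- stats::rlnorm(ncells, 0, design$lib_size_sd)
    m <- matrix(stats::rnbinom(n_g * ncells, size = design$nb_dispersion,
                               mu = outer(mu, lib)),
                nrow = n_g)
    blocks[[k]] <- Matrix::Matrix(m, sparse = TRUE)
    is_sub <- g %in% sc$name
    meta[[k]] <- data.frame(
      barcode = sprintf("%s_%s_c%04d", g, t, seq_len(ncells)),
      cell_type = if (is_sub) "RGC" else g,
      subclass = if (is_sub) g else NA_character_,
      survival_class = if (is_sub) sc$survival_class[match(g, sc$name)] else NA_character_,
      timepoint = t, sample = paste0("S_", t),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  rn <- genes
  if (!is.null(mito))
    rn[(n_g - length(mito) + 1L):n_g] <- mito
  rownames(counts) <- rn
  dimnames(arr)[[1L]] <- rn
  atlas <- build_atlas(counts, do.call(rbind, meta), timepoints = tp)

  truth <- structure(list(planted = design$planted,
                          decoys = design$decoys,
                          design = design,
                          realized_means = arr),
                     class = "synthetic_truth")
  list(atlas = atlas, truth = truth)
}

#' Ligand-receptor database implied by a synthetic truth
#'
#' Planted pairs, their feedback-loop partners, and decoys, deduplicated.
#' @param truth a `synthetic_truth`.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
truth_lr_pairs <- function(truth) {
  rows <- list()
  for (p in truth$planted) {
    rows[[length(rows) + 1L]] <- c(p$ligand, p$receptor)
    if (p$has_loop)
      rows[[length(rows) + 1L]] <- c(p$loop_partner$ligand, p$loop_partner$receptor)
  }
  for (d in truth$decoys)
    rows[[length(rows) + 1L]] <- c(d$ligand, d$receptor)
  df <- unique(as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE))
  if (!nrow(df)) return(data.frame(ligand = character(0), receptor = character(0)))
  names(df) <- c("ligand", "receptor")
  rownames(df) <- NULL
  df
}

#' Build a signaling/regulatory network realizing the planted truth
#'
#' For every planted pair the network gets receptor -> TF (signaling) and
#' TF -> support-target (regulatory) scaffolding, so the receptor has
#' downstream targets; decoy receptors get the same scaffolding to their
#' own TFs (a fair test: decoys differ only in subclass bias, not network
#' support). For looped pairs the forward TF additionally regulates the
#' loop-partner ligand, and the partner receptor reaches the forward
#' ligand through its own TF, closing the loop in both directions.
#' `extra_edges` uniformly random distractor edges are appended and
#' recorded in `attr(net, "random_edges")`.
#'
#' @param truth a `synthetic_truth` from [simulate_experiment()].
#' @param extra_edges number of random distractor edges.
#' @param seed RNG seed for the distractors (defaults to the design seed).
#' @return data.frame with columns `source`, `target`, `kind`
#'   (`signaling` / `regulatory`).
#' @export
build_synthetic_network <- function(truth, extra_edges = 0L,
                                    seed = truth$design$seed) {
  design <- truth$design
  genes_all <- rownames(truth$realized_means) %||% design_genes(design)
  used <- unique(unlist(lapply(truth$planted, function(p)
    c(p$ligand, p$receptor, p$loop_partner$ligand, p$loop_partner$receptor))))
  used <- unique(c(used, unlist(lapply(truth$decoys, function(d) c(d$ligand, d$receptor)))))

  tf_pool <- attr(design, "tf_genes")
  decoy_tfs <- attr(design, "decoy_tfs")
  support <- attr(design, "support_targets")
  free <- setdiff(genes_all, used)
  if (is.null(support)) { support <- utils::head(free, 4L); free <- setdiff(free, support) }
  need_tf <- sum(vapply(truth$planted, function(p) 1L + p$has_loop, 1L))
  if (is.null(tf_pool)) { tf_pool <- utils::head(free, need_tf); free <- setdiff(free, tf_pool) }
  if (is.null(decoy_tfs))
    decoy_tfs <- utils::head(free, min(1L, length(truth$decoys)))

  edges <- list()
  add <- function(s, t, k) edges[[length(edges) + 1L]] <<- data.frame(
    source = s, target = t, kind = k, stringsAsFactors = FALSE)
  ti <- 0L
  for (p in truth$planted) {
    ti <- ti + 1L; tf <- tf_pool[ti]
    add(p$receptor, tf, "signaling")
    add(rep(tf, length(support)), support, "regulatory")
    if (p$has_loop) {
      add(tf, p$loop_partner$ligand, "regulatory")
      ti <- ti + 1L; tf2 <- tf_pool[ti]
      add(p$loop_partner$receptor, tf2, "signaling")
      add(tf2, p$ligand, "regulatory")
      add(rep(tf2, length(support)), support, "regulatory")
    }
  }
  for (i in seq_along(truth$decoys)) {
    d <- truth$decoys[[i]]
    # one TF is shared by every decoy: it reaches only housekeeping
    # targets, so sharing cannot create loop-closing paths
    tf <- decoy_tfs[[min(i, length(decoy_tfs))]]
    add(d$receptor, tf, "signaling")
    add(rep(tf, length(support)), support, "regulatory")
  }
  net <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(0), target = character(0), kind = character(0))

  random_edges <- NULL
  if (extra_edges > 0) {
    set.seed(child_seed(seed, "network"))
    src <- sample(genes_all, extra_edges, replace = TRUE)
    tgt <- sample(genes_all, extra_edges, replace = TRUE)
    kind <- sample(c("signaling", "regulatory"), extra_edges, replace = TRUE)
    keep <- src != tgt
    random_edges <- data.frame(source = src[keep], target = tgt[keep],
                               kind = kind[keep], stringsAsFactors = FALSE)
    net <- unique(rbind(net, random_edges))
  }
  rownames(net) <- NULL
  attr(net, "random_edges") <- random_edges
  net
}

truth_to_list <- function(truth) {
  design <- truth$design
  list(
    planted = lapply(truth$planted, function(p) {
      l <- unclass(p)
      l$induction_schedule <- as.list(l$induction_schedule)
      l
    }),
    decoys = truth$decoys,
    design = list(
      n_cell_types = design$n_cell_types,
      rgc_subclasses = design$rgc_subclasses,
      timepoints = design$timepoints,
      cells_per_group = design$cells_per_group,
      n_genes = design$n_genes,
      baseline_log_mean = design$baseline_log_mean,
      baseline_log_sd = design$baseline_log_sd,
      nb_dispersion = design$nb_dispersion,
      marker_boost = design$marker_boost,
      noise_sd = design$noise_sd,
      lib_size_sd = design$lib_size_sd,
      seed = design$seed))
}

#' Export a synthetic truth to JSON
#'
#' Writes planted pairs, decoys, and the design echo (the realized mean
#' array is not serialized). [read_truth()] reconstructs an object whose
#' exported fields compare equal.
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_truth <- function(truth, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort("cannot write truth: directory %s does not exist", dir)
  jsonlite::write_json(truth_to_list(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a synthetic truth back from JSON
#' @param path file written by [export_truth()].
#' @return a `synthetic_truth` (without `realized_means`).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- x$design
  tp <- vapply(d$timepoints, as.character, "")
  planted <- lapply(x$planted, function(p) {
    planted_interaction(
      ligand = p$ligand, receptor = p$receptor, sender = p$sender,
      target_subclasses = unlist(p$target_subclasses),
      pattern = p$pattern, ligand_boost = p$ligand_boost,
      receptor_boost = p$receptor_boost,
      induction_schedule = unlist(p$induction_schedule)[tp],
      has_loop = isTRUE(p$has_loop),
      loop_partner = if (isTRUE(p$has_loop)) lapply(p$loop_partner, identity) else NULL,
      timepoints = tp)
  })
  decoys <- lapply(x$decoys, function(dd) lapply(dd, identity))
  rgc <- data.frame(
    name = vapply(d$rgc_subclasses, function(r) r$name, ""),
    survival_class = vapply(d$rgc_subclasses, function(r) r$survival_class, ""),
    stringsAsFactors = FALSE)
  design <- sim_design(
    n_cell_types = d$n_cell_types,
    rgc_subclasses = rgc,
    timepoints = tp, cells_per_group = d$cells_per_group,
    n_genes = d$n_genes, baseline_log_mean = d$baseline_log_mean,
    baseline_log_sd = d$baseline_log_sd, nb_dispersion = d$nb_dispersion,
    marker_boost = d$marker_boost, planted = planted, decoys = decoys,
    noise_sd = d$noise_sd, lib_size_sd = d$lib_size_sd, seed = d$seed)
  structure(list(planted = planted, decoys = decoys, design = design,
                 realized_means = NULL),
            class = "synthetic_truth")
}

#' Write a network edge list as TSV
#' @param network data.frame (`source`, `target`, `kind`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path) {
  data.table::fwrite(network, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read and validate a network edge list
#'
#' @param path TSV with header `source`, `target`, `kind`.
#' @return validated data.frame; self-edges or unknown kinds are errors.
#' @export
read_network <- function(path) {
  net <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = "character"))
  validate_network(net)
}

#' @rdname read_network
#' @param network in-memory edge list to validate.
#' @export
validate_network <- function(network) {
  need <- c("source", "target", "kind")
  if (!all(need %in% names(network)))
    abort_validation("network needs columns: %s", paste(need, collapse = ", "))
  if (any(network$source == network$target))
    abort_validation("network contains self-edges")
  bad <- setdiff(unique(network$kind), c("signaling", "regulatory"))
  if (length(bad))
    abort_validation("unknown edge kind(s): %s", paste(bad, collapse = ", "))
  network
}

#' Write a ligand-receptor pair table as TSV
#' @param lr_pairs data.frame (`ligand`, `receptor`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_lr_pairs <- function(lr_pairs, path) {
  data.table::fwrite(lr_pairs, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair table
#' @param path TSV with header `ligand`, `receptor`.
#' @return data.frame with unique pairs.
#' @export
read_lr_pairs <- function(path) {
  lr <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character"))
  if (!all(c("ligand", "receptor") %in% names(lr)))
    abort_validation("LR table needs columns ligand, receptor")
  if (anyDuplicated(paste(lr$ligand, lr$receptor)))
    abort_validation("LR table contains duplicate pairs")
  lr
}
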
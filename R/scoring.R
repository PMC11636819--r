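#' Scoring parameters
#'
#' `alpha` sets the floor of the network-support factor (at `alpha = 1`
#' the network is ignored); `gamma` scales the feedback-loop bonus; `K`
#' bounds the signaling path length explored downstream of a receptor;
#' `detection_min` and `score_min` are the two retention cutoffs (a pair
#' must be detected in at least 10% of sender/receiver cells and reach a
#' score of at least 0.5). With `strict_all_timepoints = TRUE` the score
#' cutoff must hold at every timepoint instead of at least one; the
#' default keeps the max-over-timepoints reading, which is the one the
#' downstream differential statistic is built on.
#'
#' @param alpha expression-only weight in `[0,1]`.
#' @param gamma loop-bonus weight in `[0,1]`.
#' @param K maximum number of signaling edges before the single
#'   regulatory edge when collecting receptor targets.
#' @param detection_min detection-rate cutoff (inclusive).
#' @param score_min score cutoff (inclusive).
#' @param strict_all_timepoints require `score_min` at every timepoint.
#' @param prune_network_by_detection drop network nodes not detected in
#'   the receiver before path-finding when computing network support.
#' @param min_cells flag profile groups smaller than this in reports.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.5, gamma = 0.5, K = 3L,
                           detection_min = 0.10, score_min = 0.5,
                           strict_all_timepoints = FALSE,
                           prune_network_by_detection = FALSE,
                           min_cells = 10L) {
  check_scalar_num(alpha, "alpha", 0, 1)
  check_scalar_num(gamma, "gamma", 0, 1)
  check_scalar_num(K, "K", 0)
  check_scalar_num(detection_min, "detection_min", 0, 1)
  check_scalar_num(score_min, "score_min", 0, 1)
  check_flag(strict_all_timepoints, "strict_all_timepoints")
  check_flag(prune_network_by_detection, "prune_network_by_detection")
  structure(list(alpha = alpha, gamma = gamma, K = as.integer(K),
                 detection_min = detection_min, score_min = score_min,
                 strict_all_timepoints = strict_all_timepoints,
                 prune_network_by_detection = prune_network_by_detection,
                 min_cells = as.integer(min_cells)),
            class = "scoring_params")
}

# downstream target sets for a set of receptors: nodes reachable through
# 0..K signaling edges followed by exactly one regulatory edge
targets_downstream <- function(network, receptors, K) {
  sig <- network[network$kind == "signaling", , drop = FALSE]
  reg <- network[network$kind == "regulatory", , drop = FALSE]
  nodes <- unique(c(network$source, network$target, receptors))
  g <- igraph::graph_from_data_frame(sig[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  d <- igraph::distances(g, v = receptors, mode = "out")
  reg_by_src <- split(reg$target, reg$source)
  out <- lapply(seq_along(receptors), function(i) {
    within_k <- colnames(d)[is.finite(d[i, ]) & d[i, ] <= K]
    unique(unlist(reg_by_src[within_k], use.names = FALSE)) %||% character(0)
  })
  names(out) <- receptors
  out
}

#' Downstream target set of a receptor
#'
#' Genes reachable from `receptor` via at most `K` signaling edges
#' followed by exactly one regulatory edge (0 signaling edges allowed, so
#' a receptor's direct regulatory targets count).
#'
#' @param network edge list (`source`, `target`, `kind`).
#' @param receptor gene id.
#' @param K signaling path-length bound.
#' @return character vector of target gene ids (possibly empty).
#' @export
reachable_targets <- function(network, receptor, K = 3L) {
  validate_network(network)
  targets_downstream(network, receptor, K)[[1L]]
}

#' Network support of a receptor in a receiver group
#'
#' The fraction of the receptor's downstream target set (see
#' [reachable_targets()]) detected at `detection_min` or above in the
#' receiver profile; 0 when the target set is empty. With
#' `prune_network_by_detection` the network is first restricted to nodes
#' detected in the receiver, so undetected intermediates break paths.
#'
#' @param receptor gene id.
#' @param receiver_profile data.frame with columns `gene`,
#'   `detection_rate` for one (group, timepoint).
#' @param network edge list.
#' @param params a [scoring_params()].
#' @return support value in `[0, 1]`.
#' @export
network_support <- function(receptor, receiver_profile, network,
                            params = scoring_params()) {
  net <- validate_network(network)
  if (params$prune_network_by_detection) {
    detected <- receiver_profile$gene[receiver_profile$detection_rate >= params$detection_min]
    keep_nodes <- unique(c(detected, receptor))
    net <- net[net$source %in% keep_nodes & net$target %in% keep_nodes, , drop = FALSE]
  }
  tset <- targets_downstream(net, receptor, params$K)[[1L]]
  if (!length(tset)) return(0)
  det <- receiver_profile$detection_rate[match(tset, receiver_profile$gene)]
  det[is.na(det)] <- 0
  mean(det >= params$detection_min)
}

#' Reverse-pair loop qualification between LR pairs
#'
#' Pair Q (a candidate reverse of pair P) qualifies when Q's ligand lies
#' in the downstream target set of P's receptor AND P's ligand lies in
#' the downstream target set of Q's receptor — i.e., the two pairs close
#' a feedback loop through the signaling/regulatory network in both
#' directions.
#'
#' @param lr_db data.frame (`ligand`, `receptor`).
#' @param network edge list.
#' @param K signaling path-length bound.
#' @return logical matrix `[i, j]`: does pair j qualify as a loop
#'   reverse of pair i? (Symmetric by construction.)
#' @export
loop_qualification <- function(lr_db, network, K = 3L) {
  validate_network(network)
  n <- nrow(lr_db)
  tsets <- targets_downstream(network, lr_db$receptor, K)
  m1 <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    m1[i, ] <- lr_db$ligand %in% tsets[[i]]
  qual <- m1 & t(m1)
  dimnames(qual) <- list(paste(lr_db$ligand, lr_db$receptor, sep = "-"),
                         paste(lr_db$ligand, lr_db$receptor, sep = "-"))
  qual
}

#' Base and loop-adjusted interaction score
#'
#' The closed form at the heart of the scoring stage, vectorized over its
#' arguments: `S0 = sqrt(e_L * e_R) * (alpha + (1 - alpha) * n_support)`
#' and `S_LR = S0 + gamma * loop_strength * (1 - S0)` when `S0 > 0`,
#' else 0. All inputs in `[0, 1]` give outputs in `[0, 1]` with
#' `S_LR >= S0`, non-decreasing in every argument.
#'
#' @param e_L,e_R scaled ligand/receptor expression in `[0,1]`.
#' @param n_support network support in `[0,1]`.
#' @param loop_strength loop bonus driver in `[0,1]`.
#' @param alpha,gamma weights in `[0,1]`.
#' @return list with vectors `S0` and `S_LR`.
#' @export
lr_score <- function(e_L, e_R, n_support = 0, loop_strength = 0,
                     alpha = 0.5, gamma = 0.5) {
  S0 <- sqrt(e_L * e_R) * (alpha + (1 - alpha) * n_support)
  S_LR <- ifelse(S0 > 0, S0 + gamma * loop_strength * (1 - S0), 0)
  list(S0 = S0, S_LR = S_LR)
}

# per-gene global maximum of mean expression across every profile row
gene_max_expr <- function(profiles) {
  pr <- as.data.table(profiles)
  gm <- pr[, list(gmax = max(mean_expr)), by = "gene"]
  stats::setNames(gm$gmax, gm$gene)
}

#' Score ligand-receptor interactions
#'
#' For every LR pair, ordered (sender, receiver) group pair (autocrine
#' included) and timepoint:
#' \itemize{
#'   \item `e_L` — the sender's mean ligand expression scaled by the
#'     ligand's maximum mean expression over all profile rows (so
#'     `e_L`, `e_R` lie in `[0,1]` and scores are comparable across
#'     pairs); `e_R` analogously for the receptor in the receiver.
#'   \item `S0 = sqrt(e_L * e_R) * (alpha + (1 - alpha) * n_support)` —
#'     the base score combining expression with network support.
#'   \item `S_LR = S0 + gamma * loop_strength * (1 - S0)` when `S0 > 0`,
#'     else 0 — the loop bonus can only raise a live score toward 1.
#' }
#' `loop_strength` is the maximum base score, at the same timepoint, of
#' any reverse-direction pair (receiver back to sender) that qualifies
#' under [loop_qualification()]; for autocrine scores the interaction
#' cannot partner with its own instance.
#'
#' Pairs whose ligand or receptor is absent from the profile gene
#' universe are skipped with a warning. Group/timepoint combinations
#' without profiles yield no rows.
#'
#' @param profiles output of [summarize_profiles()] covering both sender
#'   and receiver groups.
#' @param lr_db data.frame (`ligand`, `receptor`).
#' @param network edge list (`source`, `target`, `kind`).
#' @param params a [scoring_params()].
#' @param senders,receivers group ids to report (defaults: all groups in
#'   `profiles`). Reverse-direction base scores needed for the loop
#'   bonus are always computed internally.
#' @return `data.table`: `sender`, `receiver`, `ligand`, `receptor`,
#'   `timepoint`, `e_L`, `e_R`, `n_support`, `S0`, `loop_strength`,
#'   `S_LR`.
#' @export
score_interactions <- function(profiles, lr_db, network,
                               params = scoring_params(),
                               senders = NULL, receivers = NULL) {
  pr <- as.data.table(profiles)
  validate_network(network)
  all_groups <- unique(pr$group)
  senders <- senders %||% all_groups
  receivers <- receivers %||% all_groups
  bad <- setdiff(c(senders, receivers), all_groups)
  if (length(bad)) abort("group(s) absent from profiles: %s",
                         paste(bad, collapse = ", "))
  G <- union(senders, receivers)
  tps <- unique(pr$timepoint)

  universe <- unique(pr$gene)
  known <- lr_db$ligand %in% universe & lr_db$receptor %in% universe
  if (any(!known)) {
    warning(sprintf("skipping %d LR pair(s) with genes outside the universe: %s",
                    sum(!known),
                    paste(utils::head(paste0(lr_db$ligand[!known], "-",
                                             lr_db$receptor[!known]), 5L),
                          collapse = ", ")), call. = FALSE)
    lr_db <- lr_db[known, , drop = FALSE]
  }
  n_pairs <- nrow(lr_db)
  if (!n_pairs)
    return(data.table::data.table(sender = character(0), receiver = character(0),
                                  ligand = character(0), receptor = character(0),
                                  timepoint = character(0), e_L = numeric(0),
                                  e_R = numeric(0), n_support = numeric(0),
                                  S0 = numeric(0), loop_strength = numeric(0),
                                  S_LR = numeric(0)))
  lr_db <- as.data.frame(lr_db, stringsAsFactors = FALSE)
  rownames(lr_db) <- NULL

  gmax <- gene_max_expr(pr)
  prG <- pr[pr$group %in% G]
  expr_of <- function(genes) {
    e <- prG[prG$gene %in% unique(genes)]
    sc <- gmax[e$gene]
    e$scaled <- ifelse(sc > 0, e$mean_expr / sc, 0)
    e
  }
  eL_tab <- expr_of(lr_db$ligand)
  eR_tab <- expr_of(lr_db$receptor)

  # network support per (receptor, group, timepoint)
  receptors <- unique(lr_db$receptor)
  tsets <- targets_downstream(network, receptors, params$K)
  det_tab <- prG[prG$gene %in% unique(unlist(tsets, use.names = FALSE))]
  grp_tp <- unique(prG[, c("group", "timepoint")])
  sup <- data.table::rbindlist(lapply(receptors, function(rcp) {
    tset <- tsets[[rcp]]
    if (params$prune_network_by_detection) {
      gt <- grp_tp
      val <- vapply(seq_len(nrow(gt)), function(i) {
        prof <- prG[prG$group == gt$group[i] & prG$timepoint == gt$timepoint[i]]
        network_support(rcp, prof, network, params)
      }, 0)
      return(data.table::data.table(receptor = rcp, group = gt$group,
                                    timepoint = gt$timepoint, n_support = val))
    }
    if (!length(tset))
      return(data.table::data.table(receptor = rcp, group = grp_tp$group,
                                    timepoint = grp_tp$timepoint, n_support = 0))
    dt <- det_tab[det_tab$gene %in% tset]
    agg <- dt[, list(n_support = sum(detection_rate >= params$detection_min) / length(tset)),
              by = c("group", "timepoint")]
    miss <- grp_tp[!paste(grp_tp$group, grp_tp$timepoint) %in%
                     paste(agg$group, agg$timepoint), ]
    if (nrow(miss))
      agg <- rbind(agg, data.table::data.table(group = miss$group,
                                               timepoint = miss$timepoint,
                                               n_support = 0))
    data.table::data.table(receptor = rcp, group = agg$group,
                           timepoint = agg$timepoint, n_support = agg$n_support)
  }))

  # base-score grid over all ordered (s, r) in G x G
  grid <- data.table::CJ(pair_id = seq_len(n_pairs), sender = G, receiver = G,
                         timepoint = tps)
  grid[, `:=`(ligand = lr_db$ligand[pair_id], receptor = lr_db$receptor[pair_id])]
  eL_key <- eL_tab[, c("gene", "group", "timepoint", "scaled")]
  data.table::setnames(eL_key, c("ligand", "sender", "timepoint", "e_L"))
  eR_key <- eR_tab[, c("gene", "group", "timepoint", "scaled")]
  data.table::setnames(eR_key, c("receptor", "receiver", "timepoint", "e_R"))
  grid <- merge(grid, eL_key, by = c("ligand", "sender", "timepoint"))
  grid <- merge(grid, eR_key, by = c("receptor", "receiver", "timepoint"))
  sup_key <- data.table::copy(sup)
  data.table::setnames(sup_key, "group", "receiver")
  grid <- merge(grid, sup_key, by = c("receptor", "receiver", "timepoint"),
                all.x = TRUE)
  grid[is.na(n_support), n_support := 0]
  grid[, S0 := lr_score(e_L, e_R, n_support, 0, params$alpha, params$gamma)$S0]

  # loop strength: max same-timepoint reverse-direction base score among
  # qualifying pairs
  qual <- loop_qualification(lr_db, network, params$K)
  s_idx <- match(grid$sender, G); r_idx <- match(grid$receiver, G)
  t_idx <- match(grid$timepoint, tps)
  S0A <- array(NA_real_, dim = c(n_pairs, length(G), length(G), length(tps)))
  S0A[cbind(grid$pair_id, s_idx, r_idx, t_idx)] <- grid$S0
  lam <- array(0, dim = dim(S0A))
  for (p in seq_len(n_pairs)) {
    qs <- which(qual[p, ])
    if (!length(qs)) next
    rev_max <- apply(S0A[qs, , , , drop = FALSE], c(2L, 3L, 4L),
                     function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    # reverse direction: receiver -> sender, so transpose group dims
    lam[p, , , ] <- aperm(rev_max, c(2L, 1L, 3L))
    if (p %in% qs && length(G)) {
      # autocrine: the interaction cannot loop with its own instance
      others <- setdiff(qs, p)
      for (gi in seq_along(G)) {
        if (!length(others)) { lam[p, gi, gi, ] <- 0; next }
        om <- S0A[others, gi, gi, , drop = FALSE]
        lam[p, gi, gi, ] <- apply(om, 4L, function(x)
          if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
      }
    }
  }
  grid[, loop_strength := lam[cbind(pair_id, s_idx, r_idx, t_idx)]]
  grid[is.na(loop_strength), loop_strength := 0]
  grid[, S_LR := lr_score(e_L, e_R, n_support, loop_strength,
                          params$alpha, params$gamma)$S_LR]

  out <- grid[grid$sender %in% senders & grid$receiver %in% receivers,
              c("sender", "receiver", "ligand", "receptor", "timepoint",
                "e_L", "e_R", "n_support", "S0", "loop_strength", "S_LR")]
  data.table::setkeyv(out, c("sender", "receiver", "ligand", "receptor", "timepoint"))
  out[]
}

#' Loop strength of one interaction
#'
#' Convenience wrapper around [score_interactions()] answering: at each
#' timepoint, what loop bonus does `pair` receive between `sender` and
#' `receiver`, given the database of candidate reverse pairs?
#'
#' @param pair list or one-row data.frame with `ligand`, `receptor`.
#' @param sender,receiver group ids.
#' @param all_pairs candidate LR database (must contain `pair`).
#' @param network edge list.
#' @param profiles profiles covering both groups.
#' @param params a [scoring_params()].
#' @return named numeric vector of loop strengths per timepoint.
#' @export
find_lr_loops <- function(pair, sender, receiver, all_pairs, network,
                          profiles, params = scoring_params()) {
  sc <- score_interactions(profiles, all_pairs, network, params,
                           senders = c(sender, receiver),
                           receivers = c(sender, receiver))
  sel <- sc$sender == sender & sc$receiver == receiver &
    sc$ligand == pair$ligand & sc$receptor == pair$receptor
  rows <- sc[which(sel), ]
  stats::setNames(rows$loop_strength, rows$timepoint)
}

#' Apply the two retention criteria
#'
#' A (sender, receiver, pair) triple is retained when (1) its ligand is
#' detected in at least `detection_min` of sender cells and its receptor
#' in at least `detection_min` of receiver cells at one or more
#' timepoints, and (2) its score reaches `score_min` — at >= 1 timepoint
#' by default, at every timepoint with `strict_all_timepoints`.
#'
#' @param scores output of [score_interactions()].
#' @param profiles the profiles the scores were computed from.
#' @param params a [scoring_params()].
#' @return the retained score rows (all timepoints of retained triples),
#'   with a `filter_summary` attribute counting drops per criterion.
#' @export
filter_interactions <- function(scores, profiles, params = scoring_params()) {
  sc <- as.data.table(scores)
  pr <- as.data.table(profiles)
  det <- pr[, list(det_any = max(detection_rate)), by = c("group", "gene")]
  lig_det <- stats::setNames(det$det_any, paste(det$group, det$gene))
  key <- sc[, list(
    max_s = max(S_LR),
    min_s = min(S_LR),
    det_l = lig_det[paste(sender[1L], ligand[1L])],
    det_r = lig_det[paste(receiver[1L], receptor[1L])]),
    by = c("sender", "receiver", "ligand", "receptor")]
  key[is.na(det_l), det_l := 0]
  key[is.na(det_r), det_r := 0]
  key[, crit1 := det_l >= params$detection_min & det_r >= params$detection_min]
  key[, crit2 := if (params$strict_all_timepoints) min_s >= params$score_min
                 else max_s >= params$score_min]
  key[, keep := crit1 & crit2]
  out <- merge(sc, key[, c("sender", "receiver", "ligand", "receptor", "keep")],
               by = c("sender", "receiver", "ligand", "receptor"))
  out <- out[out$keep == TRUE][, keep := NULL]
  attr(out, "filter_summary") <- list(
    n_triples = nrow(key),
    fail_detection = sum(!key$crit1),
    fail_score = sum(key$crit1 & !key$crit2),
    retained = sum(key$keep))
  data.table::setkeyv(out, c("sender", "receiver", "ligand", "receptor", "timepoint"))
  out[]
}

#' Overall cell-type-level communication score
#'
#' The sum of retained interaction scores between a sender and a
#' receiver, per timepoint, and optionally summed across timepoints.
#'
#' @param scores retained scores from [filter_interactions()].
#' @param across_timepoints also collapse timepoints into one total per
#'   (sender, receiver).
#' @return `data.table` of `sender`, `receiver`, (`timepoint`,) `overall`.
#' @export
aggregate_celltype_scores <- function(scores, across_timepoints = FALSE) {
  sc <- as.data.table(scores)
  by <- if (across_timepoints) c("sender", "receiver")
        else c("sender", "receiver", "timepoint")
  sc[, list(overall = sum(S_LR)), by = by]
}
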
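# Shared toy builders and independent oracles. Oracles are deliberately
# plain-R re-derivations (recursive DFS, dense arithmetic, ECDF sweeps)
# that never call the package code paths they check.

toy_atlas <- function(counts, cell_type, timepoint,
                      subclass = rep(NA_character_, length(cell_type)),
                      survival_class = rep(NA_character_, length(cell_type)),
                      timepoints = DEFAULT_TIMEPOINTS) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  meta <- data.frame(
    barcode = sprintf("bc%04d", seq_len(ncol(counts))),
    cell_type = cell_type, subclass = subclass,
    survival_class = survival_class, timepoint = timepoint,
    sample = "S1", stringsAsFactors = FALSE)
  build_atlas(counts, meta, timepoints = timepoints)
}

# fabricate a profiles table directly (mean/detection decoupled on purpose)
toy_profiles <- function(...) {
  rows <- list(...)
  dt <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(group = r$group,
                           group_kind = r$group_kind %||% "cell_type",
                           timepoint = r$timepoint, gene = r$gene,
                           mean_expr = r$mean_expr,
                           detection_rate = r$detection_rate %||% 1,
                           n_cells = r$n_cells %||% 100L)))
  data.table::setkeyv(dt, c("group", "timepoint", "gene"))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- oracles ---------------------------------------------------------------

# exhaustive DFS: nodes reachable from `from` via 0..K signaling edges,
# then exactly one regulatory edge
oracle_targets <- function(network, from, K) {
  sig <- network[network$kind == "signaling", , drop = FALSE]
  reg <- network[network$kind == "regulatory", , drop = FALSE]
  frontier <- from
  seen <- from
  for (step in seq_len(K)) {
    nxt <- unique(sig$target[sig$source %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- unique(c(seen, nxt))
    if (!length(frontier)) break
  }
  sort(unique(reg$target[reg$source %in% seen]))
}

# every distinct signaling path (<= K edges) + one regulatory edge from
# `from` to `to`; returns the number of such paths
oracle_count_paths <- function(network, from, to, K) {
  sig <- network[network$kind == "signaling", , drop = FALSE]
  reg <- network[network$kind == "regulatory", , drop = FALSE]
  n_paths <- 0L
  recurse <- function(node, depth) {
    n_paths <<- n_paths + sum(reg$source == node & reg$target == to)
    if (depth < K)
      for (nx in sig$target[sig$source == node]) recurse(nx, depth + 1L)
  }
  recurse(from, 0L)
  n_paths
}

# independently coded max-over-timepoints / mean differential statistic
oracle_ds_lr <- function(tab, high, low) {
  mx <- tapply(tab$S_LR, tab$receiver, max)
  mean(mx[high]) - mean(mx[low])
}

# brute-force two-sample KS statistic via an ECDF sweep
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

# plain-loop re-derivation of the whole scoring stage (expression scaling,
# DFS network support, loop qualification and bonus); O(pairs^2 * groups^2)
oracle_score_table <- function(profiles, lr_db, network, alpha, gamma, K,
                               detection_min) {
  pr <- as.data.frame(profiles)
  groups <- unique(pr$group)
  tps <- unique(pr$timepoint)
  gmax <- tapply(pr$mean_expr, pr$gene, max)
  look <- function(col, gene, grp, tp) {
    v <- pr[pr$gene == gene & pr$group == grp & pr$timepoint == tp, col]
    if (length(v)) v else NA_real_
  }
  e_of <- function(gene, grp, tp) {
    m <- look("mean_expr", gene, grp, tp)
    if (is.na(m)) return(NA_real_)
    if (gmax[[gene]] > 0) m / gmax[[gene]] else 0
  }
  tsets <- lapply(lr_db$receptor, function(r) oracle_targets(network, r, K))
  n_of <- function(pi, grp, tp) {
    tset <- tsets[[pi]]
    if (!length(tset)) return(0)
    det <- vapply(tset, function(g) {
      d <- look("detection_rate", g, grp, tp)
      if (is.na(d)) 0 else d
    }, 0)
    mean(det >= detection_min)
  }
  np <- nrow(lr_db)
  qual <- matrix(FALSE, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    qual[i, j] <- (lr_db$ligand[j] %in% tsets[[i]]) &&
      (lr_db$ligand[i] %in% tsets[[j]])
  s0 <- function(pi, s, r, tp) {
    eL <- e_of(lr_db$ligand[pi], s, tp)
    eR <- e_of(lr_db$receptor[pi], r, tp)
    if (is.na(eL) || is.na(eR)) return(NA_real_)
    sqrt(eL * eR) * (alpha + (1 - alpha) * n_of(pi, r, tp))
  }
  rows <- list()
  for (pi in seq_len(np)) for (s in groups) for (r in groups) for (tp in tps) {
    base <- s0(pi, s, r, tp)
    if (is.na(base)) next
    lam <- 0
    for (qi in seq_len(np)) {
      if (!qual[pi, qi]) next
      if (s == r && qi == pi) next
      rev_s0 <- s0(qi, r, s, tp)
      if (!is.na(rev_s0)) lam <- max(lam, rev_s0)
    }
    slr <- if (base > 0) base + gamma * lam * (1 - base) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      sender = s, receiver = r, ligand = lr_db$ligand[pi],
      receptor = lr_db$receptor[pi], timepoint = tp,
      n_support = n_of(pi, r, tp), S0 = base, loop_strength = lam,
      S_LR = slr, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# random scoring fixture: network <= n_nodes, fabricated complete profiles
random_scoring_fixture <- function(n_nodes = 20, n_edges = 40, n_pairs = 6,
                                   n_groups = 2, n_tp = 2) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != tgt
  net <- unique(data.frame(source = src[keep], target = tgt[keep],
                           kind = sample(c("signaling", "regulatory"),
                                         sum(keep), replace = TRUE),
                           stringsAsFactors = FALSE))
  lr <- unique(data.frame(ligand = sample(nodes, n_pairs, replace = TRUE),
                          receptor = sample(nodes, n_pairs, replace = TRUE),
                          stringsAsFactors = FALSE))
  groups <- sprintf("G%d", seq_len(n_groups))
  tps <- sprintf("t%d", seq_len(n_tp))
  grid <- expand.grid(group = groups, timepoint = tps, gene = nodes,
                      stringsAsFactors = FALSE)
  pr <- data.table::data.table(
    group = grid$group, group_kind = "cell_type", timepoint = grid$timepoint,
    gene = grid$gene, mean_expr = stats::runif(nrow(grid)),
    detection_rate = stats::runif(nrow(grid)), n_cells = 50L)
  list(network = net, lr = lr, profiles = pr, groups = groups)
}

# small random score table for DS_LR fuzzing
random_score_table <- function(n_high, n_low, n_tp = 4L) {
  high <- sprintf("H%d", seq_len(n_high))
  low <- sprintf("L%d", seq_len(n_low))
  tp <- sprintf("t%d", seq_len(n_tp))
  g <- expand.grid(receiver = c(high, low), timepoint = tp,
                   stringsAsFactors = FALSE)
  g$S_LR <- stats::runif(nrow(g))
  list(tab = g, high = high, low = low)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- synthetic_design(
        n_planted = 4, n_decoys = 6, n_cell_types = 5,
        rgc_subclasses = data.frame(
          name = c("ipRGC", "alphaRGC", "T-RGC", "N-RGC"),
          survival_class = c("high", "high", "low", "low"),
          stringsAsFactors = FALSE),
        cells_per_group = 120, n_genes = 120, seed = 42)
      sim <- simulate_experiment(des)
      net <- build_synthetic_network(sim$truth, extra_edges = 0)
      prof <- summarize_profiles(sim$atlas, "both")
      cache <<- list(design = des, atlas = sim$atlas, truth = sim$truth,
                     network = net, profiles = prof,
                     lr = truth_lr_pairs(sim$truth),
                     partition = survival_partition(c("ipRGC", "alphaRGC"),
                                                    c("T-RGC", "N-RGC")))
    }
    cache
  }
})
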
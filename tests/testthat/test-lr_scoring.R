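test_that("network support counts detected downstream targets", {
  net <- data.frame(
    source = c("R", "a", "b", "b", "b", "b"),
    target = c("a", "b", "t1", "t2", "t3", "t4"),
    kind = c("signaling", "signaling", rep("regulatory", 4)))
  prof <- toy_profiles(list(group = "B", timepoint = "t",
                            gene = c("t1", "t2", "t3", "t4"),
                            mean_expr = c(1, 1, 0, 0),
                            detection_rate = c(0.5, 0.5, 0, 0)))
  recv <- as.data.frame(prof)
  expect_setequal(reachable_targets(net, "R", K = 3), c("t1", "t2", "t3", "t4"))
  expect_setequal(reachable_targets(net, "R", K = 3), oracle_targets(net, "R", 3))
  expect_equal(network_support("R", recv, net), 0.5)
  recv$detection_rate <- 1
  expect_equal(network_support("R", recv, net), 1.0)
  # K too short: two signaling hops needed
  expect_equal(network_support("R", recv, net,
                               scoring_params(K = 1)), 0)
  # unknown receptor: empty target set
  expect_equal(network_support("Rx", recv, net), 0)
})

# two-group, single-timepoint loop toy: P = L1->R1 (A to B), Q = L2->R2
loop_toy <- function(alpha = 1) {
  net <- data.frame(
    source = c("R1", "TF1", "R2", "TF2"),
    target = c("TF1", "L2", "TF2", "L1"),
    kind = c("signaling", "regulatory", "signaling", "regulatory"))
  prof <- toy_profiles(
    list(group = "A", timepoint = "control",
         gene = c("L1", "R1", "L2", "R2"),
         mean_expr = c(0.81, 1.0, 1.0, 1.0), detection_rate = 1),
    list(group = "B", timepoint = "control",
         gene = c("L1", "R1", "L2", "R2"),
         mean_expr = c(1.0, 1.0, 0.36, 0.5), detection_rate = 1))
  pairs <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  list(net = net, prof = prof, pairs = pairs,
       params = scoring_params(alpha = alpha, gamma = 0.5))
}

test_that("loop strength is the best qualifying reverse base score", {
  toy <- loop_toy()
  lam <- find_lr_loops(list(ligand = "L1", receptor = "R1"), "A", "B",
                       toy$pairs, toy$net, toy$prof, toy$params)
  # reverse Q from B to A: e_L(L2 in B) = 0.36, e_R(R2 in A) = 1, alpha = 1
  expect_equal(unname(lam["control"]), 0.6)
  sc <- score_interactions(toy$prof, toy$pairs, toy$net, toy$params)
  p_ab <- sc[sc$sender == "A" & sc$receiver == "B" & sc$ligand == "L1", ]
  expect_equal(p_ab$S0, 0.9)   # sqrt(0.81 * 1)
  expect_equal(p_ab$S_LR, 0.9 + 0.5 * 0.6 * 0.1)
  # loop symmetry: Q from B to A carries at least S0(P) as its bonus
  q_ba <- sc[sc$sender == "B" & sc$receiver == "A" & sc$ligand == "L2", ]
  expect_gte(q_ba$loop_strength, p_ab$S0)

  # severing one direction kills the loop both ways
  net1 <- toy$net[toy$net$target != "L1", ]
  lam1 <- find_lr_loops(list(ligand = "L1", receptor = "R1"), "A", "B",
                        toy$pairs, net1, toy$prof, toy$params)
  expect_equal(unname(lam1["control"]), 0)

  # empty network: no support, no loops
  net0 <- data.frame(source = character(0), target = character(0),
                     kind = character(0))
  sc0 <- score_interactions(toy$prof, toy$pairs, net0, toy$params)
  expect_true(all(sc0$loop_strength == 0))
})

test_that("the full worked score decomposition is reproduced", {
  # e_L = 0.81, e_R = 0.49, n = 0.5, alpha = 0.5, loop = 0.4, gamma = 0.5
  net <- data.frame(
    source = c("R", "TF", "TF", "TF", "TF", "Rp", "TF2"),
    target = c("TF", "T1", "T2", "Lp", "X", "TF2", "L"),
    kind = c("signaling", rep("regulatory", 4), "signaling", "regulatory"))
  prof <- toy_profiles(
    list(group = "A", timepoint = "t",
         gene = c("L", "R", "Lp", "Rp", "T1", "T2", "X"),
         mean_expr = c(0.81, 1.0, 1.0, 1.0, 1, 1, 1),
         detection_rate = c(0.05, 1, 1, 1, 1, 1, 1)),
    list(group = "B", timepoint = "t",
         gene = c("L", "R", "Lp", "Rp", "T1", "T2", "X"),
         mean_expr = c(1.0, 0.49, 0.64, 1.0, 1, 1, 1),
         detection_rate = c(1, 1, 0.05, 1, 0.5, 0.3, 0)))
  pairs <- data.frame(ligand = c("L", "Lp"), receptor = c("R", "Rp"))
  sc <- score_interactions(prof, pairs, net,
                           scoring_params(alpha = 0.5, gamma = 0.5))
  row <- sc[sc$sender == "A" & sc$receiver == "B" & sc$ligand == "L", ]
  expect_equal(row$e_L, 0.81, tolerance = 1e-12)
  expect_equal(row$e_R, 0.49, tolerance = 1e-12)
  expect_equal(row$n_support, 0.5, tolerance = 1e-12)
  expect_equal(row$S0, 0.4725, tolerance = 1e-12)
  expect_equal(row$loop_strength, 0.4, tolerance = 1e-12)
  expect_equal(row$S_LR, 0.578, tolerance = 1e-12)
})

test_that("score closed form honors its gates and extremes", {
  expect_equal(lr_score(1, 1, 1, 0)$S_LR, 1)
  expect_equal(lr_score(0, 1, 1, 0.9)$S_LR, 0)   # dead ligand gates the loop
  expect_equal(lr_score(0.81, 0.49, 0.5, 0.4, 0.5, 0.5)$S_LR, 0.578,
               tolerance = 1e-12)
  s <- lr_score(0.5, 0.5, 0.3, 0.7, 0.4, 0.6)
  expect_gte(s$S_LR, s$S0)
})

test_that("pairs outside the gene universe are skipped with a warning", {
  toy <- loop_toy()
  pairs <- rbind(toy$pairs, data.frame(ligand = "ghost", receptor = "R1"))
  expect_warning(sc <- score_interactions(toy$prof, pairs, toy$net, toy$params),
                 "ghost")
  expect_false("ghost" %in% sc$ligand)
})

test_that("retention applies both criteria at their boundaries", {
  mk_scores <- function(slr) data.table::data.table(
    sender = "A", receiver = "B", ligand = "L", receptor = "R",
    timepoint = sprintf("t%d", seq_along(slr)),
    e_L = 1, e_R = 1, n_support = 1, S0 = slr, loop_strength = 0, S_LR = slr)
  prof_det <- function(dl, dr) toy_profiles(
    list(group = "A", timepoint = "t1", gene = c("L", "R"),
         mean_expr = 1, detection_rate = c(dl, 0)),
    list(group = "B", timepoint = "t1", gene = c("L", "R"),
         mean_expr = 1, detection_rate = c(0, dr)))
  p <- scoring_params()
  # detection exactly 0.10 passes criterion 1
  r1 <- filter_interactions(mk_scores(c(0.6, 0.6)), prof_det(0.10, 0.10), p)
  expect_equal(nrow(r1), 2L)
  r2 <- filter_interactions(mk_scores(c(0.6, 0.6)), prof_det(0.09, 0.10), p)
  expect_equal(nrow(r2), 0L)
  # S_LR below 0.5 at every timepoint fails criterion 2
  r3 <- filter_interactions(mk_scores(c(0.49, 0.49)), prof_det(1, 1), p)
  expect_equal(nrow(r3), 0L)
  r4 <- filter_interactions(mk_scores(c(0.49, 0.51)), prof_det(1, 1), p)
  expect_equal(nrow(r4), 2L)
  # strict mode requires the cutoff everywhere
  r5 <- filter_interactions(mk_scores(c(0.49, 0.51)), prof_det(1, 1),
                            scoring_params(strict_all_timepoints = TRUE))
  expect_equal(nrow(r5), 0L)
})

test_that("retention equals exhaustive rule evaluation on random triples", {
  set.seed(31)
  p <- scoring_params()
  genes <- sprintf("gene%02d", 1:10)
  groups <- sprintf("G%d", 1:4)
  tps <- c("t1", "t2")
  grid <- expand.grid(group = groups, timepoint = tps, gene = genes,
                      stringsAsFactors = FALSE)
  prof <- data.table::data.table(
    group = grid$group, group_kind = "cell_type", timepoint = grid$timepoint,
    gene = grid$gene, mean_expr = runif(nrow(grid)),
    detection_rate = sample(c(0, 0.05, 0.1, 0.5), nrow(grid), replace = TRUE),
    n_cells = 10L)
  triples <- unique(data.frame(
    sender = sample(groups, 50, replace = TRUE),
    receiver = sample(groups, 50, replace = TRUE),
    ligand = sample(genes, 50, replace = TRUE),
    receptor = sample(genes, 50, replace = TRUE)))
  scores <- data.table::rbindlist(lapply(tps, function(tp)
    data.table::data.table(triples, timepoint = tp, e_L = 1, e_R = 1,
                           n_support = 1, S0 = runif(nrow(triples)),
                           loop_strength = 0,
                           S_LR = runif(nrow(triples)))))
  got <- filter_interactions(scores, prof, p)
  want <- vapply(seq_len(nrow(triples)), function(i) {
    with(triples[i, ], {
      dl <- max(prof$detection_rate[prof$group == sender & prof$gene == ligand])
      dr <- max(prof$detection_rate[prof$group == receiver & prof$gene == receptor])
      smax <- max(scores$S_LR[scores$sender == sender & scores$receiver == receiver &
                                scores$ligand == ligand & scores$receptor == receptor])
      dl >= 0.10 && dr >= 0.10 && smax >= 0.5
    })
  }, TRUE)
  expect_equal(nrow(got), 2L * sum(want))
  kept_keys <- unique(paste(got$sender, got$receiver, got$ligand, got$receptor))
  want_keys <- paste(triples$sender, triples$receiver, triples$ligand,
                     triples$receptor)[want]
  expect_setequal(kept_keys, want_keys)
})

test_that("overall cell-type score is the order-invariant sum", {
  empty <- aggregate_celltype_scores(data.table::data.table(
    sender = character(0), receiver = character(0), timepoint = character(0),
    S_LR = numeric(0)))
  expect_equal(nrow(empty), 0L)
  sc <- data.table::data.table(
    sender = "MG", receiver = "ipRGC", timepoint = "t1",
    ligand = c("a", "b"), receptor = c("x", "y"), S_LR = c(0.6, 0.7))
  expect_equal(aggregate_celltype_scores(sc)$overall, 1.3)
  expect_equal(aggregate_celltype_scores(sc[2:1])$overall, 1.3)
  expect_equal(aggregate_celltype_scores(sc, across_timepoints = TRUE)$overall, 1.3)
})

test_that("scores match the exhaustive oracle on random fixtures", {
  set.seed(77)
  for (i in 1:6) {
    fx <- random_scoring_fixture(n_nodes = 14, n_edges = 30, n_pairs = 5)
    params <- scoring_params(alpha = runif(1), gamma = runif(1), K = sample(1:3, 1))
    got <- score_interactions(fx$profiles, fx$lr, fx$network, params)
    want <- oracle_score_table(fx$profiles, fx$lr, fx$network,
                               params$alpha, params$gamma, params$K,
                               params$detection_min)
    key <- function(d) paste(d$sender, d$receiver, d$ligand, d$receptor, d$timepoint)
    got <- got[order(key(got)), ]
    want <- want[order(key(want)), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$n_support, want$n_support, tolerance = 1e-12)
    expect_equal(got$S0, want$S0, tolerance = 1e-12)
    expect_equal(got$loop_strength, want$loop_strength, tolerance = 1e-12)
    expect_equal(got$S_LR, want$S_LR, tolerance = 1e-12)
  }
})

test_that("planted loops close and decoys stay loop-free", {
  s <- small_sim()
  params <- scoring_params()
  senders <- unique(SummarizedExperiment::colData(s$atlas)$cell_type)
  sc <- score_interactions(s$profiles, s$lr, s$network, params,
                           senders = senders,
                           receivers = c(s$partition$high, s$partition$low))
  for (p in s$truth$planted) {
    rows <- sc[sc$ligand == p$ligand & sc$receptor == p$receptor &
                 sc$sender == p$sender & sc$receiver %in% p$target_subclasses, ]
    if (p$has_loop) expect_gt(max(rows$loop_strength), 0)
    else expect_equal(max(rows$loop_strength), 0)
  }
  for (d in s$truth$decoys) {
    rows <- sc[sc$ligand == d$ligand & sc$receptor == d$receptor, ]
    expect_equal(max(rows$loop_strength), 0)
  }
})
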
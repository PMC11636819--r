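test_that("design validation names the violated invariant", {
  expect_error(sim_design(rgc_subclasses = data.frame(
    name = c("a", "b"), survival_class = c("high", "high"))),
    "high and >=1 low")
  expect_error(sim_design(timepoints = c("12h", "control")),
               "'control' first")
  expect_error(sim_design(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_design(noise_sd = -1), "noise_sd")
  expect_error(
    sim_design(planted = list(planted_interaction(
      "g1", "g2", sender = "nonexistent", target_subclasses = "ipRGC"))),
    "not a declared cell type")
  expect_error(planted_interaction("g1", "g2", "CT01", "ipRGC",
                                   pattern = "induced",
                                   induction_schedule = c(control = 2, `12h` = 3,
                                                          `24h` = 3, `48h` = 3)) |>
                 (\(p) sim_design(planted = list(p)))(),
               "control multiplier 1.0")
  expect_error(planted_interaction("g1", "g2", "CT01", "ipRGC",
                                   pattern = "preset",
                                   induction_schedule = c(control = 2, `12h` = 3,
                                                          `24h` = 2, `48h` = 2)) |>
                 (\(p) sim_design(planted = list(p)))(),
               "identical multipliers")
  expect_error(planted_interaction("g1", "g2", "CT01", "ipRGC",
                                   has_loop = TRUE),
               "loop_partner")
})

test_that("planted and decoy sets must be disjoint", {
  p <- planted_interaction("g0001", "g0002", "CT01", "ipRGC")
  d <- list(ligand = "g0001", receptor = "g0002", sender = "CT01",
            ligand_boost = 2, receptor_boost = 2)
  expect_error(sim_design(planted = list(p), decoys = list(d)),
               "overlap")
})

test_that("simulation is deterministic given the seed", {
  des <- sim_design(n_cell_types = 3,
                    rgc_subclasses = data.frame(
                      name = c("hi", "lo"), survival_class = c("high", "low")),
                    cells_per_group = 30, n_genes = 40, seed = 11)
  a <- simulate_experiment(des)
  b <- simulate_experiment(des)
  expect_identical(SummarizedExperiment::assay(a$atlas),
                   SummarizedExperiment::assay(b$atlas))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a$atlas)),
                   as.data.frame(SummarizedExperiment::colData(b$atlas)))
})

test_that("exchangeable design yields indistinguishable cell types", {
  # no planted pairs, no noise, no markers: per-gene mean expression of any
  # two cell types should come from one distribution
  des <- sim_design(n_cell_types = 3,
                    rgc_subclasses = data.frame(
                      name = c("hi", "lo"), survival_class = c("high", "low")),
                    cells_per_group = 500, n_genes = 100, marker_boost = 1,
                    noise_sd = 0, seed = 5)
  sim <- simulate_experiment(des)
  m <- SummarizedExperiment::assay(sim$atlas)
  cd <- SummarizedExperiment::colData(sim$atlas)
  sel <- cd$timepoint == "control"
  mu1 <- Matrix::rowMeans(m[, sel & cd$cell_type == "CT01"])
  mu2 <- Matrix::rowMeans(m[, sel & cd$cell_type == "CT02"])
  expect_gt(suppressWarnings(stats::ks.test(mu1, mu2))$p.value, 0.01)
})

test_that("planted preset receptor bias shows in empirical detection rates", {
  des <- sim_design(n_cell_types = 2,
                    rgc_subclasses = data.frame(
                      name = c("hi", "lo"), survival_class = c("high", "low")),
                    cells_per_group = 500, n_genes = 60, noise_sd = 0, seed = 1,
                    baseline_log_mean = -1.5,
                    planted = list(planted_interaction(
                      "g0001", "g0002", "CT01", "hi", pattern = "preset",
                      receptor_boost = 8)))
  sim <- simulate_experiment(des)
  m <- SummarizedExperiment::assay(sim$atlas)
  cd <- SummarizedExperiment::colData(sim$atlas)
  for (tp in DEFAULT_TIMEPOINTS) {
    det <- function(sub) mean(m["g0002", cd$subclass %in% sub &
                                  cd$timepoint == tp] > 0)
    expect_gt(det("hi"), det("lo"))
  }
})

test_that("empirical means converge to design means (noise_sd = 0)", {
  des <- sim_design(n_cell_types = 2,
                    rgc_subclasses = data.frame(
                      name = c("hi", "lo"), survival_class = c("high", "low")),
                    cells_per_group = 1000, n_genes = 50, noise_sd = 0,
                    timepoints = c("control", "12h"), seed = 3)
  sim <- simulate_experiment(des)
  m <- SummarizedExperiment::assay(sim$atlas)
  cd <- SummarizedExperiment::colData(sim$atlas)
  sel <- cd$cell_type == "CT01" & cd$timepoint == "control"
  emp <- Matrix::rowMeans(m[, sel])
  se <- apply(as.matrix(m[, sel]), 1L, stats::sd) / sqrt(sum(sel))
  # per-cell library factors are lognormal(0, sd), so E[count] carries
  # the lognormal mean exp(sd^2/2)
  target <- sim$truth$realized_means[, "CT01", "control"] *
    exp(des$lib_size_sd^2 / 2)
  frac_ok <- mean(abs(emp - target) <= 3 * se)
  expect_gte(frac_ok, 0.95)
})

test_that("synthetic network realizes exactly the mandated paths", {
  # one looped planted pair, no distractors
  des <- synthetic_design(n_planted = 1, n_decoys = 0, prop_loops = 1,
                          n_cell_types = 3,
                          rgc_subclasses = data.frame(
                            name = c("hi", "lo"),
                            survival_class = c("high", "low")),
                          cells_per_group = 10, n_genes = 60, seed = 2)
  sim <- simulate_experiment(des)
  net <- build_synthetic_network(sim$truth, extra_edges = 0)
  p <- sim$truth$planted[[1]]
  expect_true(p$has_loop)
  # exactly one forward-receptor -> partner-ligand path, one reverse
  expect_identical(oracle_count_paths(net, p$receptor, p$loop_partner$ligand, 3), 1L)
  expect_identical(oracle_count_paths(net, p$loop_partner$receptor, p$ligand, 3), 1L)

  # without loops: scaffolding only, zero loop-closing paths
  des2 <- synthetic_design(n_planted = 2, n_decoys = 2, prop_loops = 0,
                           n_cell_types = 3,
                           rgc_subclasses = data.frame(
                             name = c("hi", "lo"),
                             survival_class = c("high", "low")),
                           cells_per_group = 10, n_genes = 80, seed = 2)
  sim2 <- simulate_experiment(des2)
  net2 <- build_synthetic_network(sim2$truth, extra_edges = 0)
  lr2 <- truth_lr_pairs(sim2$truth)
  for (i in seq_len(nrow(lr2))) for (j in seq_len(nrow(lr2)))
    expect_identical(
      oracle_count_paths(net2, lr2$receptor[i], lr2$ligand[j], 3), 0L)
  expect_true(all(net2$kind %in% c("signaling", "regulatory")))

  # determinism with distractors
  n1 <- build_synthetic_network(sim$truth, extra_edges = 25, seed = 9)
  n2 <- build_synthetic_network(sim$truth, extra_edges = 25, seed = 9)
  expect_identical(n1, n2)
})

test_that("truth export/read round-trips losslessly", {
  des <- synthetic_design(n_planted = 20, n_decoys = 100, n_cell_types = 6,
                          rgc_subclasses = data.frame(
                            name = c("hi1", "hi2", "lo1", "lo2"),
                            survival_class = c("high", "high", "low", "low")),
                          cells_per_group = 10, n_genes = 600, seed = 8)
  truth <- structure(list(planted = des$planted, decoys = des$decoys,
                          design = des, realized_means = NULL),
                     class = "synthetic_truth")
  path <- file.path(withr::local_tempdir(), "truth.json")
  export_truth(truth, path)
  back <- read_truth(path)
  expect_length(back$planted, 20L)
  expect_length(back$decoys, 100L)
  expect_equal(back$planted, truth$planted)
  expect_equal(lapply(back$decoys, as.list), lapply(truth$decoys, as.list))
  expect_equal(back$design$rgc_subclasses, des$rgc_subclasses)
  expect_equal(back$design$timepoints, des$timepoints)

  # empty planted list is valid JSON with an empty array
  t0 <- structure(list(planted = list(), decoys = list(),
                       design = sim_design(n_cell_types = 3, n_genes = 10,
                                           cells_per_group = 5),
                       realized_means = NULL), class = "synthetic_truth")
  p0 <- file.path(withr::local_tempdir(), "t0.json")
  export_truth(t0, p0)
  expect_length(read_truth(p0)$planted, 0L)
  expect_error(export_truth(t0, "/nonexistent_dir_xyz/t.json"), "directory")
})

test_that("atlas bundle writes and reloads identically", {
  s <- small_sim()
  dir <- withr::local_tempdir()
  write_expression(s$atlas, dir)
  back <- load_expression(file.path(dir, "matrix.mtx"),
                          file.path(dir, "features.tsv"),
                          file.path(dir, "barcodes.tsv"),
                          file.path(dir, "cell_metadata.tsv"))
  expect_equal(as.matrix(SummarizedExperiment::assay(back)),
               as.matrix(SummarizedExperiment::assay(s$atlas)))
  expect_identical(back$subclass, s$atlas$subclass)
})
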
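mk_fam <- function(...) {
  # list(receiver = c(t1, t2, t3, t4) scores)
  vals <- list(...)
  data.table::rbindlist(lapply(names(vals), function(r)
    data.table::data.table(sender = "MG", ligand = "L", receptor = "R",
                           receiver = r,
                           timepoint = c("control", "12h", "24h", "48h"),
                           S_LR = vals[[r]])))
}

test_that("the differential score is mean(max) high minus low", {
  part <- survival_partition(c("A", "B"), c("C", "D"))
  fam <- mk_fam(A = c(0.2, 0.8, 0.5, 0.4), B = rep(0.6, 4),
                C = c(0.1, 0.3, 0.2, 0.2), D = c(0.5, 0.1, 0.0, 0.2))
  # maxima: A 0.8, B 0.6 -> mean 0.7; C 0.3, D 0.5 -> mean 0.4
  expect_equal(compute_ds_lr(fam, part), 0.3, tolerance = 1e-12)

  same <- mk_fam(A = 1:4 / 10, B = 1:4 / 10, C = 1:4 / 10, D = 1:4 / 10)
  expect_equal(compute_ds_lr(same, part), 0)
})

test_that("random tables match the independently coded max/mean oracle", {
  set.seed(101)
  for (i in 1:200) {
    rt <- random_score_table(sample(2:4, 1), sample(2:8, 1))
    part <- survival_partition(rt$high, rt$low)
    expect_equal(compute_ds_lr(rt$tab, part),
                 oracle_ds_lr(rt$tab, rt$high, rt$low), tolerance = 1e-12)
  }
})

test_that("antisymmetry and translation invariance hold", {
  set.seed(55)
  for (i in 1:50) {
    rt <- random_score_table(3, 3)
    part <- survival_partition(rt$high, rt$low)
    flipped <- survival_partition(rt$low, rt$high)
    expect_equal(compute_ds_lr(rt$tab, part),
                 -compute_ds_lr(rt$tab, flipped), tolerance = 1e-12)
    shifted <- rt$tab
    shifted$S_LR <- shifted$S_LR + 0.37
    expect_equal(compute_ds_lr(shifted, part),
                 compute_ds_lr(rt$tab, part), tolerance = 1e-12)
  }
})

test_that("missing subclasses follow the chosen policy", {
  part <- survival_partition(c("A", "B"), "C")
  fam <- mk_fam(A = rep(0.6, 4), C = rep(0.2, 4))   # B absent
  expect_warning(ds0 <- compute_ds_lr(fam, part, missing = "zero"), "B")
  expect_equal(ds0, 0.3 - 0.2)                       # B counted as 0
  expect_equal(compute_ds_lr(fam, part, missing = "skip"), 0.4)
  only_high <- mk_fam(A = rep(0.6, 4))
  expect_error(suppressWarnings(
    compute_ds_lr(only_high, survival_partition("A", "C"), missing = "skip")),
    "partition side")
})

test_that("protective classification uses strict cutoffs", {
  expect_identical(classify_protective(0.3), "protective")
  expect_identical(classify_protective(0.25), "neutral")
  expect_identical(classify_protective(0.0), "neutral")
  expect_identical(classify_protective(-0.25), "neutral")
  expect_identical(classify_protective(-0.3), "stronger_in_low")
  expect_identical(classify_protective(c(0.6, -0.6, 0.1)),
                   c("protective", "stronger_in_low", "neutral"))
  expect_error(classify_protective(0.3, cutoff = -1), "> 0")
})

test_that("preset/induced timing follows the two score-difference axes", {
  part <- survival_partition(c("A", "B"), c("C", "D"))
  const_gap <- mk_fam(A = rep(0.8, 4), B = rep(0.8, 4),
                      C = rep(0.4, 4), D = rep(0.4, 4))
  r <- classify_preset_induced(const_gap, part)
  expect_equal(r$delta_pre, 0.4)
  expect_identical(r$timing, "preset")

  induced <- mk_fam(A = c(0.4, 0.8, 0.8, 0.8), B = c(0.4, 0.8, 0.8, 0.8),
                    C = rep(0.4, 4), D = rep(0.4, 4))
  r2 <- classify_preset_induced(induced, part)
  expect_equal(r2$delta_pre, 0)
  expect_equal(r2$delta_post, 0.4)
  expect_identical(r2$timing, "induced")

  flat <- mk_fam(A = rep(0.5, 4), B = rep(0.5, 4),
                 C = rep(0.5, 4), D = rep(0.5, 4))
  r3 <- classify_preset_induced(flat, part)
  expect_identical(c(r3$delta_pre, r3$delta_post), c(0, 0))
  expect_identical(r3$timing, "neither")

  no_ctrl <- const_gap[const_gap$timepoint != "control"]
  expect_error(classify_preset_induced(no_ctrl, part), "control")
})

mode_profiles <- function(rgc_det, other_det) {
  toy_profiles(
    list(group = "ipRGC", group_kind = "subclass", timepoint = "12h",
         gene = "L", mean_expr = 1, detection_rate = rgc_det),
    list(group = "Astro", group_kind = "cell_type", timepoint = "12h",
         gene = "L", mean_expr = 1, detection_rate = other_det))
}

test_that("signaling mode resolves autocrine/paracrine/both", {
  expect_identical(classify_signaling_mode("L", mode_profiles(0.0, 0.5)),
                   "paracrine")
  expect_identical(classify_signaling_mode("L", mode_profiles(0.5, 0.5)),
                   "both")
  # detection exactly at the threshold in one RGC subclass only
  expect_identical(classify_signaling_mode("L", mode_profiles(0.1, 0.05)),
                   "autocrine")
  expect_warning(m <- classify_signaling_mode("L", mode_profiles(0, 0)),
                 "undefined")
  expect_identical(m, "undefined")
})

test_that("survival adjustment conserves the overall rate", {
  counts <- data.frame(
    subclass = rep(c("s1", "s2"), 3),
    condition = rep(c("sham", "onc", "onc_oprm1"), each = 2),
    n = c(100, 100, 160, 40, 100, 100))
  surv <- c(onc = 0.638, onc_oprm1 = 0.854)
  adj <- adjust_subclass_survival(counts, surv)
  for (cc in names(surv)) {
    expect_equal(sum(adj$adjusted_share[adj$condition == cc]), surv[[cc]],
                 tolerance = 1e-12)
  }
  # equal shares in sham and condition: estimated survival = overall rate
  o1 <- adj[adj$condition == "onc_oprm1", ]
  expect_equal(o1$est_subclass_survival, c(0.854, 0.854), tolerance = 1e-12)
  # shares (0.5, 0.5) -> (0.8, 0.2) at overall 0.5: est (0.8, 0.2)
  adj2 <- adjust_subclass_survival(
    data.frame(subclass = rep(c("s1", "s2"), 2),
               condition = rep(c("sham", "inj"), each = 2),
               n = c(50, 50, 80, 20)),
    c(inj = 0.5))
  expect_equal(adj2$est_subclass_survival, c(0.8, 0.2), tolerance = 1e-12)
  # overall survival 1 and identical shares: everything survives
  adj3 <- adjust_subclass_survival(
    data.frame(subclass = rep(c("s1", "s2"), 2),
               condition = rep(c("sham", "x"), each = 2),
               n = c(30, 70, 30, 70)),
    c(x = 1))
  expect_equal(adj3$est_subclass_survival, c(1, 1), tolerance = 1e-12)

  expect_error(adjust_subclass_survival(
    data.frame(subclass = c("s1", "s2", "s1", "s3"),
               condition = c("sham", "sham", "inj", "inj"),
               n = c(10, 10, 10, 10)), c(inj = 0.5)),
    "s3")
})

test_that("differential table recovers planted truth end to end", {
  s <- small_sim()
  params <- scoring_params()
  senders <- unique(SummarizedExperiment::colData(s$atlas)$cell_type)
  receivers <- c(s$partition$high, s$partition$low)
  sc <- score_interactions(s$profiles, s$lr, s$network, params,
                           senders = senders, receivers = receivers)
  ret <- filter_interactions(sc, s$profiles, params)
  dt <- differential_table(sc, s$partition, profiles = s$profiles,
                           retained = ret)
  dt_key <- paste(dt$sender, dt$ligand, dt$receptor)
  for (p in s$truth$planted) {
    i <- match(paste(p$sender, p$ligand, p$receptor), dt_key)
    expect_false(is.na(i))
    expect_identical(dt$class[i], "protective")
    expect_identical(dt$timing[i], p$pattern)
  }
  for (d in s$truth$decoys) {
    i <- match(paste(d$sender, d$ligand, d$receptor), dt_key)
    if (!is.na(i)) expect_false(dt$class[i] == "stronger_in_low")
  }
  expect_true(all(!is.na(dt$mode)))
  ru <- rollup_protective(dt)
  expect_lte(nrow(ru$by_pair), nrow(ru$by_sender_pair))
  expect_true(all(ru$by_pair$n_senders >= 1))
})
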
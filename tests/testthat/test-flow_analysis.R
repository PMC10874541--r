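# Flow-style event analyses: gating, ROS folds, per-phase profiles, and the
# comparison statistics (verified against textbook closed forms).

test_that("PI gating: trivial thresholds and planted-fraction recovery", {
  ev <- data.table::data.table(pi = c(1, 2, 3))
  expect_equal(as.numeric(gate_pi_positive(ev, 10)), 0)
  expect_equal(as.numeric(gate_pi_positive(ev, 0.5)), 1)
  expect_error(gate_pi_positive(data.table::data.table(x = 1), 1), "pi")
  sp <- flow_condition_spec(dead_fraction = 0.3, n_events = 10000,
                            seed = SUITE_SEED)
  ev2 <- simulate_flow_events(sp)
  fr <- gate_pi_positive(ev2)  # auto valley threshold
  expect_lt(abs(as.numeric(fr) - 0.30), 0.015)
  # auto on unimodal data without a control errors; with a control it works
  uni <- simulate_flow_events(flow_condition_spec(dead_fraction = 0, seed = 2))
  expect_error(gate_pi_positive(uni), "unimodal")
  fr2 <- gate_pi_positive(uni, "auto", unstained_control = uni$pi)
  expect_lt(as.numeric(fr2), 0.01)
})

test_that("PI+ fraction is invariant to a common monotone rescaling", {
  sp <- flow_condition_spec(dead_fraction = 0.2, n_events = 5000, seed = 3)
  ev <- simulate_flow_events(sp)
  f1 <- gate_pi_positive(ev, 300)
  ev2 <- data.table::copy(ev); ev2$pi <- ev2$pi * 4.2
  expect_equal(as.numeric(gate_pi_positive(ev2, 300 * 4.2)), as.numeric(f1))
})

test_that("ROS fold recovery and gain invariance", {
  ctrl <- simulate_flow_events(flow_condition_spec("c", n_events = 5000, seed = 4))
  up <- simulate_flow_events(flow_condition_spec("u", n_events = 5000,
                                                 ros_fold = 2, seed = 5))
  dn <- simulate_flow_events(flow_condition_spec("d", n_events = 5000,
                                                 ros_fold = 0.5, seed = 6))
  expect_lt(abs(quantify_ros_shift(up, ctrl) / 2 - 1), 0.10)
  expect_lt(abs(quantify_ros_shift(dn, ctrl) / 0.5 - 1), 0.10)
  g <- 3.1  # shared instrument gain cancels
  up2 <- data.table::copy(up); up2$dcfda <- up2$dcfda * g
  ct2 <- data.table::copy(ctrl); ct2$dcfda <- ct2$dcfda * g
  expect_equal(quantify_ros_shift(up2, ct2), quantify_ros_shift(up, ctrl))
  expect_error(quantify_ros_shift(up, data.table::data.table(dcfda = rep(0, 10))),
               "zero")
})

test_that("flow per-phase profile matches the planted rates and the image path", {
  sp <- flow_condition_spec(n_events = 10000, seed = SUITE_SEED)
  ev <- simulate_flow_events(sp)
  prof <- flow_phase_peroxisome(ev)
  expect_identical(unname(prof[["G1"]]), 1)
  expect_gt(prof[["S"]], 1.7)
  expect_lt(abs(prof[["G2M"]] / 2.2 - 1), 0.15)
  # cross-modality: table-fidelity imaging population, same parameters
  tab <- control_well_table(derive_seed(SUITE_SEED, "xmod"),
                            spec = scene_spec(n_cells = 840, seed = 1))
  g <- fit_dna_gates(tab$integrated_dna)
  prof_img <- phase_peroxisome_profile(assign_phase(tab, g))
  expect_true(all(abs(prof / prof_img - 1) < 0.10))
})

test_that("t test and ANOVA agree with textbook closed forms", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  cmp <- compare_conditions(list(a = a, b = b))
  # pooled-variance two-sample t statistic, computed from first principles
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_lt(abs(cmp$statistic - t_manual), 1e-10)
  expect_equal(cmp$test, "t_test")
  # one-way ANOVA F from sums of squares
  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  cmp3 <- compare_conditions(g3)
  all_v <- unlist(g3); gm <- mean(all_v)
  ssb <- sum(vapply(g3, function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g3, function(x) sum((x - mean(x))^2), numeric(1)))
  f_manual <- (ssb / 2) / (ssw / 6)
  expect_lt(abs(cmp3$statistic - f_manual), 1e-10)
  expect_equal(cmp3$p_value, pf(f_manual, 2, 6, lower.tail = FALSE))
})

test_that("degenerate comparisons behave as stated", {
  cmp <- compare_conditions(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  flat <- compare_conditions(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$p_value, 1)
  expect_error(compare_conditions(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(compare_conditions(list(a = c(1, 2))), "2 groups")
})

test_that("a 5-SD shifted group is detected by ANOVA and flagged by Tukey", {
  withr::with_seed(SUITE_SEED, {
    g <- list(a = rnorm(3), b = rnorm(3), c = rnorm(3) + 5)
  })
  cmp <- compare_conditions(g)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(tukey_p(cmp, "c", "a"), 0.05)
  expect_lt(tukey_p(cmp, "c", "b"), 0.05)
})

test_that("synergy report reproduces the combination-design pattern", {
  planted <- c(control = 0.05, inducer = 0.15, chemical = 0.10,
               combination = 0.60, combination_inhibitor = 0.08)
  death <- lapply(names(planted), function(nm) {
    reps <- simulate_flow_replicates(
      flow_condition_spec(nm, dead_fraction = planted[[nm]], n_events = 10000,
                          seed = derive_seed(SUITE_SEED, nm)))
    vapply(reps, function(e) as.numeric(gate_pi_positive(e, 300)), numeric(1))
  })
  names(death) <- names(planted)
  rep <- synergy_report(death)
  ct <- rep$contrasts
  expect_true(ct$significant[ct$contrast == "combination vs inducer"])
  expect_true(ct$significant[ct$contrast == "combination vs chemical"])
  expect_false(ct$significant[ct$contrast == "combination_inhibitor vs control"])
  expect_error(synergy_report(death[-1]), "missing condition")
})

test_that("null conditions are rarely declared different (calibration, n = 3 reps)", {
  hits <- 0
  for (i in 1:40) {
    d <- lapply(1:2, function(j) {
      reps <- simulate_flow_replicates(
        flow_condition_spec(paste0("g", j), dead_fraction = 0.10,
                            n_events = 5000,
                            seed = derive_seed(SUITE_SEED, paste0("nul", i, j))))
      vapply(reps, function(e) as.numeric(gate_pi_positive(e, 300)), numeric(1))
    })
    if (compare_conditions(setNames(d, c("a", "b")))$p_value < 0.05)
      hits <- hits + 1
  }
  expect_lte(hits / 40, 0.10)  # >= 90% of repetitions not significant
})
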
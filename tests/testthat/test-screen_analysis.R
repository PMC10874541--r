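# Well aggregation, cytotoxicity filter, standardization, cutoffs, and
# categorization, with brute-force recomputation oracles.

well_row <- function(well_id, compound_id, replicate, role, count,
                     perox = 100, dna = 5e4, spots = 10) {
  data.table::data.table(well_id = well_id, compound_id = compound_id,
                         replicate = replicate, role = role,
                         cell_count = count, mean_spot_count = spots,
                         mean_spot_total_intensity = perox,
                         mean_integrated_dna = dna)
}

test_that("summarize_well computes arithmetic means; empty well has count 0", {
  rec <- data.table::data.table(well_id = "w", spot_count = c(2, 4, 6),
                                spot_total_intensity = c(10, 20, 30),
                                integrated_dna = c(1, 2, 3))
  s <- summarize_well(rec)
  expect_equal(s$mean_spot_count, 4)
  expect_equal(s$mean_spot_total_intensity, 20)
  expect_equal(s$cell_count, 3L)
  s0 <- summarize_well(rec[0])
  expect_equal(s0$cell_count, 0L)
  expect_true(is.na(s0$mean_spot_count))
  expect_error(summarize_well(data.table::data.table(
    well_id = c("a", "b"), spot_count = 1:2, spot_total_intensity = 1:2,
    integrated_dna = 1:2)), "one well_id")
})

test_that("cytotoxicity filter applies the strict 25%-of-control rule", {
  ws <- rbind(well_row("c1", "vehicle", 1, "control", 2000),
              well_row("c2", "vehicle", 1, "control", 2000),
              well_row("a", "A", 1, "compound", 499),
              well_row("b", "B", 1, "compound", 500),
              well_row("d", "D", 1, "compound", 2000),
              well_row("e", "E", 1, "compound", 0))
  res <- apply_cytotoxicity_filter(ws)
  expect_true(res$cytotoxic[res$compound_id == "A"])     # 499 < 500
  expect_false(res$cytotoxic[res$compound_id == "B"])    # exactly 500: retained
  expect_false(res$cytotoxic[res$compound_id == "D"])    # equal to control
  expect_true(res$cytotoxic[res$compound_id == "E"])     # empty well
  expect_error(apply_cytotoxicity_filter(ws[ws$role == "compound"]), "control")
})

test_that("standardization is the identity on control-equal compounds", {
  ws <- rbind(well_row("c1", "vehicle", 1, "control", 2000),
              well_row("x", "X", 1, "compound", 2000),
              well_row("c2", "vehicle", 2, "control", 1800),
              well_row("x2", "X", 2, "compound", 1800))
  std <- standardize_to_control(ws)
  expect_equal(std$std_peroxisome, 1)
  expect_equal(std$std_dna, 1)
  expect_equal(std$rel_cell_count, 1)
  expect_equal(std$rel_spot_count, 1)
})

test_that("a planted 1.8-fold compound is recovered within 10% at screen scale", {
  sim <- simulate_screen(list(compound_effect("B1", "B_perox_up")),
                         n_replicates = 3, fidelity = "table",
                         base_spec = scene_spec(seed = 1), seed = SUITE_SEED,
                         n_control_wells = 4)
  ws <- summarize_wells(sim$cells, sim$plate_map)
  std <- standardize_to_control(ws)
  expect_lt(abs(std$std_peroxisome / 1.8 - 1), 0.10)
  expect_lt(abs(std$std_dna - 1), 0.05)
})

test_that("percentile cutoffs follow the linear-interpolation convention", {
  cp <- compute_cutoffs(1:100)
  expect_equal(cp$low, 5.95)
  expect_equal(cp$high, 95.05)
  expect_error(compute_cutoffs(rep(1, 50)), "degenerate")
  expect_error(compute_cutoffs(1:10), "need >=")
  # brute-force oracle: manual order-statistic interpolation
  withr::with_seed(1, v <- rnorm(73))
  cp2 <- compute_cutoffs(v)
  manual <- function(p) {
    h <- (length(v) - 1) * p + 1
    s <- sort(v)
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  expect_equal(cp2$low, manual(0.05))
  expect_equal(cp2$high, manual(0.95))
})

test_that("categorization quadrant logic and exclusion precedence", {
  cut_p <- structure(list(low = 0.9, high = 1.1), class = "cutoff_pair")
  cut_d <- structure(list(low = 0.95, high = 1.05), class = "cutoff_pair")
  std <- data.table::data.table(
    compound_id = c("mid", "dna_hi", "px_hi", "px_lo", "both_lo", "dna_hi_px_hi"),
    std_peroxisome = c(1.0, 1.0, 1.5, 0.5, 0.5, 1.5),
    std_dna = c(1.0, 1.2, 1.0, 1.0, 0.90, 1.2))
  out <- categorize_compounds(std, cut_p, cut_d)
  expect_equal(out$category,
               c("none", "A", "B", "C", "none", "A"))
  expect_equal(out$perox_flagged, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("scale invariance: global intensity rescaling leaves results unchanged", {
  sim <- simulate_screen(effect_library(n_A = 2, n_B = 2, n_C = 2, n_null = 24),
                         n_replicates = 2, fidelity = "table",
                         base_spec = scene_spec(n_cells = 40, seed = 1),
                         seed = SUITE_SEED, n_control_wells = 3)
  r1 <- analyze_screen(sim$cells, sim$plate_map)
  cells2 <- data.table::copy(sim$cells)
  cells2$spot_total_intensity <- cells2$spot_total_intensity * 7.3
  cells2$integrated_dna <- cells2$integrated_dna * 7.3
  r2 <- analyze_screen(cells2, sim$plate_map)
  expect_equal(r2$compounds$category, r1$compounds$category)
  expect_equal(r2$compounds$std_peroxisome, r1$compounds$std_peroxisome,
               tolerance = 1e-12)
})

test_that("cytotoxic compounds are excluded before categorization; heatmap table", {
  sim <- simulate_screen(effect_library(n_A = 3, n_B = 3, n_C = 3,
                                        n_cytotoxic = 2, n_null = 30),
                         n_replicates = 2, fidelity = "table",
                         base_spec = scene_spec(n_cells = 60, seed = 2),
                         seed = SUITE_SEED, n_control_wells = 3)
  res <- analyze_screen(sim$cells, sim$plate_map)
  cp <- merge(res$compounds, sim$truth, by = "compound_id")
  expect_true(all(cp$category[cp$archetype == "cytotoxic"] == "excluded"))
  expect_false(any(cp$category[cp$cytotoxic == TRUE] %in% c("A", "B", "C")))
  hits <- build_heatmap_table(res$compounds[res$compounds$category != "excluded", ])
  expect_true(all(hits$category %in% c("A", "B", "C")))
  ha <- merge(hits, sim$truth, by = "compound_id")
  # archetype A: arrest raises DNA, reduces proliferation
  if (any(ha$archetype == "A_cell_cycle")) {
    expect_true(all(ha$std_dna[ha$archetype == "A_cell_cycle"] > 1))
    expect_true(all(ha$rel_cell_count[ha$archetype == "A_cell_cycle"] < 1))
  }
  # archetype B: more spots and more signal
  if (any(ha$archetype == "B_perox_up"))
    expect_true(all(ha$rel_spot_count[ha$archetype == "B_perox_up"] > 1 &
                      ha$std_peroxisome[ha$archetype == "B_perox_up"] > 1))
  expect_equal(nrow(build_heatmap_table(res$compounds[0])), 0)
})

test_that("the 25% filter agrees with brute-force recomputation on a simulated screen", {
  sim <- simulate_screen(effect_library(n_cytotoxic = 3, n_null = 12),
                         n_replicates = 3, fidelity = "table",
                         base_spec = scene_spec(n_cells = 50, seed = 3),
                         seed = SUITE_SEED, n_control_wells = 3)
  ws <- summarize_wells(sim$cells, sim$plate_map)
  tox <- apply_cytotoxicity_filter(ws)
  # brute force from the raw per-cell table
  counts <- table(sim$cells$well_id)
  pm <- sim$plate_map
  ctrl_avg <- mean(vapply(pm$well_id[pm$role == "control"], function(w) {
    v <- counts[w]; if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1)))
  for (id in tox$compound_id) {
    wells <- pm$well_id[pm$compound_id == id]
    m <- mean(vapply(wells, function(w) {
      v <- counts[w]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)))
    expect_equal(tox$cytotoxic[tox$compound_id == id],
                 m < 0.25 * ctrl_avg || m == 0)
  }
})
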
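# Generator contracts: validation, distributional structure, rendering
# conservation, determinism.

test_that("scene_spec and flow_condition_spec reject invalid parameters", {
  expect_error(scene_spec(phase_fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(scene_spec(spot_rate_per_phase = c(-1, 2, 3)), "non-negative")
  expect_error(scene_spec(n_cells = -5), "n_cells")
  expect_error(scene_spec(cluster_fraction = 1.5), "cluster_fraction")
  expect_error(scene_spec(noise_model = list(type = "speckle")), "noise_model")
  expect_error(flow_condition_spec(dead_fraction = 1.2), "dead_fraction")
  expect_error(flow_condition_spec(pi_live_mean = 100, pi_dead_mean = 50),
               "pi_dead_mean")
  expect_error(flow_condition_spec(n_events = 0), "n_events")
})

test_that("compound_effect validates archetype constraints", {
  expect_error(compound_effect("x", "null", perox_multiplier = 2), "multiplier 1")
  expect_error(compound_effect("x", "B_perox_up", perox_multiplier = 0), "> 0")
  expect_error(compound_effect("x", "cytotoxic", survival_fraction = 0), "survival")
  expect_error(compound_effect("x", "B_perox_up", phase_shift = c(.2, .2, .6)),
               "archetype A")
  a <- compound_effect("x", "A_cell_cycle")
  expect_equal(sum(a$phase_shift), 1)
  expect_lt(a$count_multiplier, 1)
})

test_that("degenerate G1-only mixture: all cells G1, mean DNA near 2N", {
  spec <- scene_spec(n_cells = 1000, phase_fractions = c(1, 0, 0),
                     image_height = 2000, image_width = 2000,
                     cluster_fraction = 0, edge_fraction = 0, seed = SUITE_SEED)
  pop <- sample_cell_population(spec)
  expect_equal(nrow(pop$cells), 1000)
  expect_true(all(pop$cells$phase == "G1"))
  expect_lt(abs(mean(pop$cells$dna_content) / spec$dna_2n_mean - 1), 0.02)
})

test_that("phase mixture, 2N/4N coupling, and Poisson spot rates at n = 10000", {
  spec <- scene_spec(seed = SUITE_SEED)
  tab <- pexscreen:::simulate_well_table(
    spec, compound_effect("vehicle", "null"), n_fields = 60,
    well_seed = SUITE_SEED, well_id = "big")  # ~10200 cells expected
  n <- nrow(tab)
  expect_gt(n, 9000)
  fr <- prop.table(table(factor(tab$true_phase, c("G1", "S", "G2M"))))
  expect_true(all(abs(as.numeric(fr) - c(0.6, 0.2, 0.2)) <= 0.01))
  ratio <- mean(tab$integrated_dna[tab$true_phase == "G2M"]) /
    mean(tab$integrated_dna[tab$true_phase == "G1"])
  expect_lt(abs(ratio / 2 - 1), 0.02)
  # per-phase mean spot count within 3 standard errors of the planted rate
  for (p in c("G1", "S", "G2M")) {
    k <- tab$spot_count[tab$true_phase == p]
    lam <- spec$spot_rate_per_phase[[p]]
    expect_lt(abs(mean(k) - lam), 3 * sqrt(lam / length(k)))
  }
})

test_that("generators are pure functions of their spec (determinism)", {
  spec <- scene_spec(image_height = 200, image_width = 200, n_cells = 12,
                     seed = SUITE_SEED)
  p1 <- sample_cell_population(spec)
  p2 <- sample_cell_population(spec)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$spots, p2$spots)
  s1 <- render_scene(p1); s2 <- render_scene(p2)
  expect_identical(s1$dna, s2$dna)  # bit-identical incl. noise
  expect_identical(s1$rfp, s2$rfp)
  spec2 <- scene_spec(image_height = 200, image_width = 200, n_cells = 12,
                      seed = SUITE_SEED + 1L)
  expect_false(identical(sample_cell_population(spec2)$cells, p1$cells))
  f1 <- simulate_flow_events(flow_condition_spec(seed = 9))
  f2 <- simulate_flow_events(flow_condition_spec(seed = 9))
  expect_identical(f1, f2)
})

test_that("empty scene renders flat backgrounds", {
  spec <- scene_spec(image_height = 64, image_width = 64, n_cells = 0,
                     noise_model = list(type = "none"), seed = 1)
  sc <- render_scene(sample_cell_population(spec))
  expect_true(all(sc$dna == spec$background_dna))
  expect_true(all(sc$rfp == spec$background_rfp))
})

test_that("noise-free reporter channel conserves planted spot mass within 1%", {
  spec <- clean_scene_spec(seed = SUITE_SEED)
  pop <- sample_cell_population(spec)
  sc <- render_scene(pop)
  rendered <- sum(sc$rfp - spec$background_rfp)
  expect_lt(abs(rendered / sum(pop$spots$intensity) - 1), 0.01)
})

test_that("planted spots lie outside the nuclear ellipse, within the cytoplasm extent", {
  spec <- clean_scene_spec(seed = 3, n_cells = 20)
  pop <- sample_cell_population(spec)
  cells <- pop$cells[pop$spots$cell_id]
  dr <- pop$spots$row - cells$center_row
  dc <- pop$spots$col - cells$center_col
  u <- dr * cos(cells$angle) + dc * sin(cells$angle)
  v <- -dr * sin(cells$angle) + dc * cos(cells$angle)
  q <- (u / cells$axis_a)^2 + (v / cells$axis_b)^2
  expect_true(all(q >= 1 - 1e-9))
  # radial offset beyond the boundary is bounded by the extent
  theta <- atan2(v, u)
  rb <- 1 / sqrt((cos(theta) / cells$axis_a)^2 + (sin(theta) / cells$axis_b)^2)
  expect_true(all(sqrt(u^2 + v^2) - rb <= spec$cytoplasm_extent_px + 1e-9))
})

test_that("simulate_screen layout, duplicate ids, and cytotoxic cell counts", {
  expect_error(simulate_screen(list(compound_effect("a", "null"),
                                    compound_effect("a", "null"))),
               "duplicate")
  expect_error(simulate_screen(n_replicates = 0), "n_replicates")
  # empty library: only control wells, one per replicate
  sim0 <- simulate_screen(list(), n_replicates = 3, n_control_wells = 1,
                          base_spec = scene_spec(n_cells = 20), seed = 1)
  expect_equal(nrow(sim0$plate_map), 3)
  expect_true(all(sim0$plate_map$role == "control"))
  # cytotoxic wells fall below 25% of the ~2000-cell control average
  sim <- simulate_screen(list(compound_effect("tox", "cytotoxic",
                                              survival_fraction = 0.1)),
                         n_replicates = 1, fidelity = "table",
                         base_spec = scene_spec(seed = 1), seed = SUITE_SEED,
                         n_control_wells = 4)
  ws <- summarize_wells(sim$cells, sim$plate_map)
  ctrl_avg <- mean(ws$cell_count[ws$role == "control"])
  tox_count <- ws$cell_count[ws$role == "compound"]
  expect_gt(ctrl_avg, 1500)
  expect_lt(tox_count, 0.25 * ctrl_avg)
})

test_that("flow generator: dead fraction extremes and null ROS fold", {
  live <- simulate_flow_events(flow_condition_spec(dead_fraction = 0, seed = 5))
  expect_false(any(live$dead))
  a <- simulate_flow_events(flow_condition_spec("a", n_events = 5000, seed = 6))
  b <- simulate_flow_events(flow_condition_spec("b", n_events = 5000,
                                                ros_fold = 1, seed = 7))
  expect_lt(abs(median(a$dcfda) / median(b$dcfda) - 1), 0.05)
})
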
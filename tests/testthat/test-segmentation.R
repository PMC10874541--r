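# Nuclear segmentation, exclusion flags, and the cytoplasm partition, checked
# against generator truth and brute-force pixel oracles.

test_that("degenerate inputs: constant image yields no nuclei, negatives error", {
  expect_equal(nrow(detect_nuclei(matrix(5, 50, 50))$nuclei), 0)
  expect_error(detect_nuclei(matrix(-1, 10, 10)), "negative")
  expect_error(detect_nuclei(1:10), "matrix")
})

test_that("well-separated nuclei are recovered exactly with sub-pixel centroids", {
  spec <- clean_scene_spec(seed = SUITE_SEED, n_cells = 14)
  pop <- sample_cell_population(spec)
  ns <- detect_nuclei(render_scene(pop)$dna)
  expect_equal(nrow(ns$nuclei), 14)
  m <- match_cells_to_nuclei(pop, ns)
  expect_lt(max(m$dist), 1)
})

test_that("integrated DNA matches planted content and a naive mask-sum oracle", {
  spec <- clean_scene_spec(seed = 7)
  pop <- sample_cell_population(spec)
  sc <- render_scene(pop)
  ns <- detect_nuclei(sc$dna)
  m <- match_cells_to_nuclei(pop, ns)
  got <- ns$nuclei$integrated_dna[match(m$label, ns$nuclei$label)]
  expect_true(all(abs(got / pop$cells$dna_content - 1) < 0.02))
  # pixel-exact oracle: naive summation over the (dilated) integration mask
  dil <- pexscreen:::cpp_nearest_site(ns$labels,
                                      nucleus_params()$integration_dilate_px)
  for (L in ns$nuclei$label) {
    naive <- sum(sc$dna[dil == L] - ns$background)
    expect_identical(ns$nuclei$integrated_dna[ns$nuclei$label == L],
                     max(naive, 0))
  }
})

test_that("edge- and cluster-flagging matches planted truth", {
  spec <- scene_spec(image_height = 400, image_width = 400, n_cells = 30,
                     noise_model = list(type = "none"),
                     cluster_fraction = 0.15, edge_fraction = 0.1,
                     seed = SUITE_SEED)
  pop <- sample_cell_population(spec)
  ns <- flag_excluded_nuclei(detect_nuclei(render_scene(pop)$dna))
  rr <- pmin(pmax(round(pop$cells$center_row), 1), 400)
  cc <- pmin(pmax(round(pop$cells$center_col), 1), 400)
  lab_at <- ns$labels[cbind(rr, cc)]
  flagged_truth <- pop$cells$clustered | pop$cells$edge
  retained <- retained_labels(ns)
  # no planted-excluded cell survives into the retained set
  expect_equal(sum(lab_at[flagged_truth][lab_at[flagged_truth] > 0] %in% retained), 0)
  # an isolated interior nucleus carries no flags
  iso <- ns$nuclei[!ns$nuclei$edge_flag & !ns$nuclei$cluster_flag, ]
  expect_gt(nrow(iso), 0)
})

test_that("a mask touching the border is edge-flagged", {
  img <- matrix(0, 80, 80)
  img[1:12, 30:45] <- 100   # touches row 1
  img[40:55, 40:55] <- 100  # interior
  ns <- flag_excluded_nuclei(detect_nuclei(img, nucleus_params(threshold = 10)))
  expect_equal(nrow(ns$nuclei), 2)
  top <- ns$nuclei[which.min(ns$nuclei$centroid_row), ]
  expect_true(top$edge_flag)
  expect_false(ns$nuclei$edge_flag[which.max(ns$nuclei$centroid_row)])
})

test_that("cytoplasm annulus of a single circular nucleus matches the analytic area", {
  img <- matrix(0, 200, 200)
  r <- 20; w <- 15
  for (i in 1:200) for (j in 1:200)
    if ((i - 100)^2 + (j - 100)^2 <= r^2) img[i, j] <- 100
  # half-amplitude threshold puts the mask contour on the true circle
  ns <- detect_nuclei(img, nucleus_params(threshold = 50))
  cm <- build_cytoplasm_regions(ns, max_extent_px = w)
  got <- sum(cm$cytoplasm_labels == 1)
  expect_lt(abs(got / (pi * ((r + w)^2 - r^2)) - 1), 0.02)
  expect_error(build_cytoplasm_regions(ns, max_extent_px = 0), "max_extent")
})

test_that("two-nucleus partition agrees with a brute-force nearest-mask oracle", {
  img <- matrix(0, 120, 160)
  for (i in 1:120) for (j in 1:160) {
    if ((i - 60)^2 + (j - 55)^2 <= 14^2) img[i, j] <- 100
    if ((i - 60)^2 + (j - 105)^2 <= 14^2) img[i, j] <- 100
  }
  ns <- detect_nuclei(img, nucleus_params(threshold = 10))
  expect_equal(nrow(ns$nuclei), 2)
  cm <- build_cytoplasm_regions(ns, max_extent_px = 20)
  lab <- ns$labels
  p1 <- which(lab == 1); p2 <- which(lab == 2)
  r1 <- (p1 - 1) %% 120 + 1; c1 <- (p1 - 1) %/% 120 + 1
  r2 <- (p2 - 1) %% 120 + 1; c2 <- (p2 - 1) %/% 120 + 1
  cyto_idx <- which(cm$cytoplasm_labels > 0)
  n_checked <- 0
  for (px in sample(cyto_idx, 400)) {
    pr <- (px - 1) %% 120 + 1; pc <- (px - 1) %/% 120 + 1
    d1 <- min(sqrt((r1 - pr)^2 + (c1 - pc)^2))
    d2 <- min(sqrt((r2 - pr)^2 + (c2 - pc)^2))
    assigned <- cm$cytoplasm_labels[px]
    # within max_extent of its own nucleus, and the nearer one (ties within 1 px)
    expect_lte(if (assigned == 1) d1 else d2, 20)
    if (abs(d1 - d2) > 1)
      expect_equal(assigned, if (d1 < d2) 1L else 2L)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 400)
})

test_that("compartment invariants hold on random scenes (property)", {
  for (sd in c(3, 13, 29)) {
    spec <- scene_spec(image_height = 300, image_width = 300, n_cells = 20,
                       cluster_fraction = 0.1, edge_fraction = 0.1, seed = sd)
    sc <- render_scene(sample_cell_population(spec))
    ns <- flag_excluded_nuclei(detect_nuclei(sc$dna))
    ret <- retained_labels(ns)
    if (length(ret) == 0) next
    cm <- build_cytoplasm_regions(ns)
    # no nuclear pixel (retained or flagged) is ever cytoplasm
    expect_true(all(cm$cytoplasm_labels[ns$labels != 0] == 0))
    # cytoplasm labels only come from retained nuclei
    expect_true(all(unique(cm$cytoplasm_labels[cm$cytoplasm_labels > 0]) %in% ret))
    # flagged nuclei appear nowhere in the seed image
    expect_true(all(unique(cm$nucleus_labels[cm$nucleus_labels > 0]) %in% ret))
  }
})

test_that("flagged nuclei are removed before the partition (territory claimable)", {
  img <- matrix(0, 120, 120)
  for (i in 1:120) for (j in 1:120) {
    if ((i - 60)^2 + (j - 40)^2 <= 12^2) img[i, j] <- 100
    if ((i - 60)^2 + (j - 80)^2 <= 12^2) img[i, j] <- 100
  }
  ns <- detect_nuclei(img, nucleus_params(threshold = 10))
  cm_all <- build_cytoplasm_regions(ns, retained = c(1L, 2L), max_extent_px = 15)
  cm_one <- build_cytoplasm_regions(ns, retained = 1L, max_extent_px = 15)
  a_all <- sum(cm_all$cytoplasm_labels == 1)
  a_one <- sum(cm_one$cytoplasm_labels == 1)
  expect_gt(a_one, a_all)  # nucleus 1 claims space toward the removed neighbour
  expect_true(all(cm_one$cytoplasm_labels[ns$labels == 2] == 0))
})
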
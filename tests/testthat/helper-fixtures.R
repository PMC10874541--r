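# Shared fixtures. All expected values are computed from generator ground
# truth or from independent brute-force oracles defined here. Suite-wide
# convention: seed 42 (fixed before outcomes were measured).

SUITE_SEED <- 42L

`%||%` <- function(a, b) if (is.null(a)) b else a

## small noise-free field with well-separated cells (no planted exclusions)
clean_scene_spec <- function(seed = SUITE_SEED, n_cells = 14, size = 400) {
  scene_spec(image_height = size, image_width = size, n_cells = n_cells,
             noise_model = list(type = "none"),
             cluster_fraction = 0, edge_fraction = 0, seed = seed)
}

## thin a population's spots to a minimum pairwise separation (greedy order)
thin_spots <- function(pop, min_sep = 5) {
  sp <- pop$spots
  keep <- rep(TRUE, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!keep[i] || i == 1) next
    j <- which(keep[seq_len(i - 1)])
    if (length(j) &&
        min(sqrt((sp$row[j] - sp$row[i])^2 + (sp$col[j] - sp$col[i])^2)) < min_sep)
      keep[i] <- FALSE
  }
  pop$spots <- sp[keep]
  pop
}

## brute-force regional truth: per-compartment planted spot mass/count,
## using the same nearest-compartment rule (plus the detector's tolerance
## ring) as the measurement contract
regional_spot_truth <- function(pop, compartments, tol = 1.5) {
  ext <- pexscreen:::cpp_nearest_site(compartments$cytoplasm_labels, tol)
  owner <- ext[cbind(round(pop$spots$row), round(pop$spots$col))]
  dt <- data.table::data.table(cell_label = owner, intensity = pop$spots$intensity)
  dt[cell_label > 0,
     .(planted_intensity = sum(intensity), planted_count = .N),
     by = cell_label]
}

## match planted cells to detected nuclei by nearest centroid
match_cells_to_nuclei <- function(pop, nucleus_set) {
  d <- sqrt(outer(pop$cells$center_row, nucleus_set$nuclei$centroid_row, "-")^2 +
              outer(pop$cells$center_col, nucleus_set$nuclei$centroid_col, "-")^2)
  data.table::data.table(cell_id = pop$cells$cell_id,
                         label = nucleus_set$nuclei$label[apply(d, 1, which.min)],
                         dist = apply(d, 1, min))
}

## fast table-fidelity control population at the screen's stated scale
control_well_table <- function(seed, n_fields = 12, spec = scene_spec(seed = seed)) {
  pexscreen:::simulate_well_table(spec, compound_effect("vehicle", "null"),
                                  n_fields, seed, "ctrl")
}
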
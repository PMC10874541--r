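## End-to-end orchestration: simulate -> segment -> quantify -> gate ->
## categorize -> report, with a serializable run configuration and a single
## seed fanned out to per-stage child seeds.

#' Build and validate a run configuration
#'
#' @param output_dir Output directory (created if missing).
#' @param seed Integer seed; mandatory for any simulation.
#' @param fidelity `"table"` or `"image"` (simulation runs).
#' @param simulation `NULL`, or a list with archetype counts `n_A`, `n_B`,
#'   `n_C`, `n_cytotoxic`, `n_null`, plus optional `n_replicates`,
#'   `n_fields`, `n_control_wells`.
#' @param images_dir,plate_map For measured-image runs: directory of
#'   per-field TIFFs named `<well>_f<NN>.tif` (pages: DNA, reporter) and the
#'   plate-map CSV path.
#' @param scene Named list of [scene_spec()] overrides for the simulated
#'   control field.
#' @param nucleus,cluster,spot Stage parameter lists (see
#'   [nucleus_params()], [cluster_params()], [spot_params()]).
#' @param max_extent_px Cytoplasm reach in px.
#' @param cutoff_source `"compounds"` or `"controls"`.
#' @param cytotox_threshold Cytotoxicity filter fraction (in `(0, 1)`).
#' @param gate_min_cells Minimum control-cell count for gate fitting
#'   (see [fit_dna_gates()]).
#' @param plots Write PNG report figures.
#' @return A list of class `run_config` (round-trips through JSON).
#' @export
run_config <- function(output_dir, seed = NULL, fidelity = "table",
                       simulation = NULL, images_dir = NULL, plate_map = NULL,
                       scene = list(), nucleus = nucleus_params(),
                       cluster = cluster_params(), spot = spot_params(),
                       max_extent_px = 15,
                       cutoff_source = "compounds", cytotox_threshold = 0.25,
                       gate_min_cells = 200, plots = TRUE) {
  cfg <- structure(list(output_dir = output_dir, seed = seed,
                        fidelity = fidelity, simulation = simulation,
                        images_dir = images_dir, plate_map = plate_map,
                        scene = scene, nucleus = unclass(nucleus),
                        cluster = unclass(cluster), spot = unclass(spot),
                        max_extent_px = max_extent_px,
                        cutoff_source = cutoff_source,
                        cytotox_threshold = cytotox_threshold,
                        gate_min_cells = gate_min_cells, plots = plots),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  fail <- function(field, msg) stop(sprintf("config$%s: %s", field, msg),
                                    call. = FALSE)
  if (is.null(cfg$output_dir) || !is.character(cfg$output_dir))
    fail("output_dir", "must be a path")
  if (!cfg$fidelity %in% c("table", "image"))
    fail("fidelity", "must be 'table' or 'image'")
  if (!is.null(cfg$simulation)) {
    if (is.null(cfg$seed)) fail("seed", "mandatory for simulation runs")
  } else {
    if (is.null(cfg$images_dir)) fail("images_dir", "required without a simulation block")
    if (is.null(cfg$plate_map)) fail("plate_map", "required without a simulation block")
  }
  if (!cfg$cutoff_source %in% c("compounds", "controls"))
    fail("cutoff_source", "must be 'compounds' or 'controls'")
  if (cfg$cytotox_threshold <= 0 || cfg$cytotox_threshold >= 1)
    fail("cytotox_threshold", "must be in (0, 1)")
  stopifnot(cfg$max_extent_px > 0)
  invisible(cfg)
}

#' Read / write a run configuration (JSON)
#' @param path File path.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## atomic write: tmp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run a screen end to end
#'
#' Simulates (or loads) the plate data, measures per-cell records (image
#' fidelity runs the full segmentation and spot pipeline per field), fits
#' DNA-content gates on pooled control cells, assigns phases, applies the
#' cytotoxicity filter, standardizes to control, and categorizes compounds.
#' All outputs are written atomically to `config$output_dir`:
#' `cells.csv`, `wells.csv`, `compounds.csv`, `gates.json`,
#' `manifest.json`, and (optionally) report PNGs. Deterministic given the
#' config, including the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `result` (`screen_result`), `gates`, `cells`,
#'   `paths`.
#' @export
run_screen <- function(config) {
  validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    effects <- effect_library(sim_cfg$n_A %||% 0, sim_cfg$n_B %||% 0,
                              sim_cfg$n_C %||% 0, sim_cfg$n_cytotoxic %||% 0,
                              sim_cfg$n_null %||% 0)
    base_spec <- do.call(scene_spec, config$scene)
    sim <- simulate_screen(effects, sim_cfg$n_replicates %||% 3,
                           config$fidelity, base_spec,
                           seed = derive_seed(config$seed, "simulate"),
                           n_fields = sim_cfg$n_fields %||% 12,
                           n_control_wells = sim_cfg$n_control_wells %||% 8)
    plate_map <- sim$plate_map
    cells <- if (config$fidelity == "table") sim$cells else
      measure_wells(sim$images, config)
  } else {
    plate_map <- fread(config$plate_map)
    if (!all(c("well_id", "compound_id", "replicate", "role") %in% names(plate_map)))
      stop("config$plate_map: needs columns well_id, compound_id, replicate, role",
           call. = FALSE)
    cells <- measure_image_dir(config$images_dir, plate_map, config)
  }
  # gates on pooled control cells, applied plate-wide
  ctrl_wells <- plate_map$well_id[plate_map$role == "control"]
  gates <- fit_dna_gates(cells$integrated_dna[cells$well_id %in% ctrl_wells],
                         min_cells = config$gate_min_cells %||% 200)
  cells <- assign_phase(cells, gates)
  result <- analyze_screen(cells, plate_map, config$cutoff_source,
                           config$cytotox_threshold)
  paths <- list(
    cells = file.path(config$output_dir, "cells.csv"),
    wells = file.path(config$output_dir, "wells.csv"),
    compounds = file.path(config$output_dir, "compounds.csv"),
    gates = file.path(config$output_dir, "gates.json"),
    manifest = file.path(config$output_dir, "manifest.json"))
  write_atomic(function(p) fwrite(cells, p), paths$cells)
  write_atomic(function(p) fwrite(result$wells, p), paths$wells)
  write_atomic(function(p) fwrite(result$compounds, p), paths$compounds)
  write_atomic(function(p) write_gates(gates, p), paths$gates)
  manifest <- list(package_version = as.character(utils::packageVersion("pexscreen")),
                   r_version = R.version.string,
                   config = unclass(config),
                   n_cells = nrow(cells), n_wells = nrow(result$wells),
                   n_compounds = nrow(result$compounds))
  write_atomic(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                                digits = NA, null = "null"),
               paths$manifest)
  if (isTRUE(config$plots)) {
    png_path <- file.path(config$output_dir, "screen_scatter.png")
    grDevices::png(png_path, 900, 700, res = 120)
    plot_screen(result)
    grDevices::dev.off()
    paths$scatter <- png_path
  }
  invisible(list(result = result, gates = gates, cells = cells, paths = paths))
}

## measure in-memory rendered wells (image-fidelity simulation)
measure_wells <- function(images, config) {
  nucleus <- do.call(nucleus_params, config$nucleus)
  cluster <- do.call(cluster_params, config$cluster)
  spot <- do.call(spot_params, config$spot)
  rbindlist(lapply(names(images), function(w) {
    rbindlist(lapply(seq_along(images[[w]]), function(f) {
      measure_field(images[[w]][[f]], nucleus = nucleus, cluster = cluster,
                    spot = spot, max_extent_px = config$max_extent_px,
                    well_id = w, field_index = f)$cells
    }))
  }))
}

## measure TIFF fields on disk, named <well>_f<NN>.tif
measure_image_dir <- function(dir, plate_map, config) {
  nucleus <- do.call(nucleus_params, config$nucleus)
  cluster <- do.call(cluster_params, config$cluster)
  spot <- do.call(spot_params, config$spot)
  files <- list.files(dir, pattern = "_f[0-9]+\\.tif$", full.names = TRUE)
  if (length(files) == 0) stop("no field TIFFs found in ", dir, call. = FALSE)
  rbindlist(lapply(files, function(fp) {
    base <- sub("\\.tif$", "", basename(fp))
    well <- sub("_f[0-9]+$", "", base)
    fidx <- as.integer(sub("^.*_f", "", base))
    if (!well %in% plate_map$well_id)
      stop("field file ", basename(fp), " has no plate-map entry", call. = FALSE)
    pages <- read_tiff(fp)
    if (length(pages) < 2) stop("malformed field TIFF (needs 2 pages): ", fp,
                                call. = FALSE)
    measure_field(list(dna = pages[[1]], rfp = pages[[2]]),
                  nucleus = nucleus, cluster = cluster, spot = spot,
                  max_extent_px = config$max_extent_px,
                  well_id = well, field_index = fidx)$cells
  }))
}

#' Run a small bundled demonstration
#'
#' Simulates four image-fidelity wells (control, G2/M-arrest, peroxisome-up,
#' peroxisome-down; small fields) plus a 96-compound table-fidelity screen,
#' runs the full pipeline on both, and writes a report (CSV tables and PNG
#' figures: per-cell intensity-vs-DNA scatter, per-phase profile bars, and
#' the categorized compound scatter).
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `image_cells`, `profile`, `screen`
#'   (`screen_result`), and `paths`.
#' @export
run_demo <- function(seed = 1L, out_dir = file.path(tempdir(), "pexscreen_demo")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- scene_spec(image_height = 300, image_width = 300, n_cells = 22,
                     nucleus_radius_mean = 9, cytoplasm_extent_px = 10,
                     spot_rate_per_phase = c(G1 = 8, S = 16, G2M = 18))
  demo_effects <- list(compound_effect("ARREST", "A_cell_cycle"),
                       compound_effect("PEROX_UP", "B_perox_up"),
                       compound_effect("PEROX_DOWN", "C_perox_down"))
  sim <- simulate_screen(demo_effects, n_replicates = 1, fidelity = "image",
                         base_spec = base, seed = derive_seed(seed, "demo_img"),
                         n_fields = 3, n_control_wells = 1)
  cfg <- list(nucleus = unclass(nucleus_params()),
              cluster = unclass(cluster_params()),
              spot = unclass(spot_params()), max_extent_px = 10)
  image_cells <- measure_wells(sim$images, cfg)
  ctrl_cells <- image_cells[well_id %in%
                              sim$plate_map$well_id[sim$plate_map$role == "control"]]
  gates <- fit_dna_gates(ctrl_cells$integrated_dna, min_cells = 50)
  image_cells <- assign_phase(image_cells, gates)
  profile <- phase_peroxisome_profile(
    image_cells[well_id %in% ctrl_cells$well_id])
  fwrite(image_cells, file.path(out_dir, "demo_image_cells.csv"))

  screen_cfg <- run_config(
    file.path(out_dir, "table_screen"), seed = derive_seed(seed, "demo_tab"),
    fidelity = "table",
    simulation = list(n_A = 5, n_B = 5, n_C = 5, n_cytotoxic = 2, n_null = 79,
                      n_replicates = 3, n_control_wells = 4),
    scene = list(n_cells = 80), plots = TRUE)
  screen <- run_screen(screen_cfg)

  p1 <- file.path(out_dir, "demo_cell_scatter.png")
  grDevices::png(p1, 800, 600, res = 120)
  plot_cell_scatter(ctrl_cells_assigned <- image_cells[well_id %in% ctrl_cells$well_id])
  grDevices::dev.off()
  p2 <- file.path(out_dir, "demo_phase_profile.png")
  grDevices::png(p2, 600, 600, res = 120)
  plot_phase_profile(profile)
  grDevices::dev.off()
  invisible(list(image_cells = image_cells, profile = profile,
                 screen = screen$result,
                 paths = list(out_dir = out_dir, cell_scatter = p1,
                              phase_profile = p2,
                              screen_dir = screen_cfg$output_dir)))
}
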
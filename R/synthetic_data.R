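## Ground-truthed generator for two-channel high-content fields, plate-level
## screens, and flow-cytometry-style event tables. The generative model mirrors
## the screen design the downstream analysis assumes: a 2N/4N DNA-content
## mixture with an S-phase bridge, phase-linked cytoplasmic spot abundance,
## compound archetypes, and 12 fields (~2000 cells) per control well.

#' Scene specification for a synthetic imaging field
#'
#' Defines the generative parameters of one microscope field: geometry,
#' cell-cycle mixture, DNA-content scale, phase-linked peroxisomal spot rates,
#' rendering and noise parameters, and the fractions of cells planted as
#' clustered pairs or edge-touching (both excluded by segmentation).
#'
#' Defaults emulate a 20x field at ~0.5 um/px of a U-2OS-like monolayer:
#' 170 cells/field so that 12 fields give ~2000 cells per control well, a
#' (0.6, 0.2, 0.2) G1/S/G2M mixture, 5% DNA staining CV, and spot rates that
#' double between G1 and S.
#'
#' @param image_height,image_width Field size in pixels.
#' @param n_cells Number of cells in the field.
#' @param phase_fractions Length-3 numeric (G1, S, G2M), must sum to 1.
#' @param dna_2n_mean Mean integrated DNA signal of a G1 (2N) cell,
#'   intensity units. G2M cells are centered on twice this value.
#' @param dna_cv Coefficient of variation of the DNA signal around its
#'   phase-specific center (lognormal).
#' @param spot_rate_per_phase Expected spots/cell for (G1, S, G2M); per-cell
#'   counts are Poisson.
#' @param spot_intensity_mean Mean integrated intensity of one spot.
#' @param spot_intensity_cv CV of per-spot intensities (gamma-distributed).
#' @param spot_sigma_px Rendered spot width (isotropic Gaussian sigma), px.
#' @param nucleus_radius_mean,nucleus_radius_cv Nuclear radius distribution
#'   (lognormal), px.
#' @param cytoplasm_extent_px Width of the cytoplasmic zone beyond the
#'   nuclear boundary within which spots are planted, px.
#' @param background_dna,background_rfp Constant channel backgrounds.
#' @param noise_model `list(type = "none")` or
#'   `list(type = "poisson_gaussian", read_sigma = <sd>)`, applied last.
#' @param cluster_fraction,edge_fraction Fractions of cells planted as
#'   merging nucleus pairs / border-touching nuclei, in `[0, 1]`.
#' @param seed Integer seed; every generator is a pure function of its spec.
#' @return An object of class `scene_spec`.
#' @examples
#' spec <- scene_spec(n_cells = 30, image_height = 256, image_width = 256)
#' pop <- sample_cell_population(spec)
#' nrow(pop$cells)
#' @export
scene_spec <- function(image_height = 1024, image_width = 1024,
                       n_cells = 170,
                       phase_fractions = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                       dna_2n_mean = 50000, dna_cv = 0.05,
                       spot_rate_per_phase = c(G1 = 10, S = 20, G2M = 22),
                       spot_intensity_mean = 500, spot_intensity_cv = 0.25,
                       spot_sigma_px = 1.5,
                       nucleus_radius_mean = 14, nucleus_radius_cv = 0.12,
                       cytoplasm_extent_px = 15,
                       background_dna = 5, background_rfp = 5,
                       noise_model = list(type = "poisson_gaussian", read_sigma = 2),
                       cluster_fraction = 0.08, edge_fraction = 0.06,
                       seed = 1L) {
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_cells = as.integer(n_cells),
    phase_fractions = setNames(as.numeric(phase_fractions), c("G1", "S", "G2M")),
    dna_2n_mean = dna_2n_mean, dna_cv = dna_cv,
    spot_rate_per_phase = setNames(as.numeric(spot_rate_per_phase), c("G1", "S", "G2M")),
    spot_intensity_mean = spot_intensity_mean, spot_intensity_cv = spot_intensity_cv,
    spot_sigma_px = spot_sigma_px,
    nucleus_radius_mean = nucleus_radius_mean, nucleus_radius_cv = nucleus_radius_cv,
    cytoplasm_extent_px = cytoplasm_extent_px,
    background_dna = background_dna, background_rfp = background_rfp,
    noise_model = noise_model,
    cluster_fraction = cluster_fraction, edge_fraction = edge_fraction,
    seed = as.integer(seed)), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (abs(sum(spec$phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1", call. = FALSE)
  if (any(spec$phase_fractions < 0)) stop("phase_fractions must be non-negative", call. = FALSE)
  if (any(spec$spot_rate_per_phase < 0)) stop("spot rates must be non-negative", call. = FALSE)
  if (spec$n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  for (f in c("dna_2n_mean", "dna_cv", "spot_intensity_mean", "spot_sigma_px",
              "nucleus_radius_mean", "nucleus_radius_cv", "cytoplasm_extent_px",
              "background_dna", "background_rfp"))
    stop_if_not_scalar_number(spec[[f]], f, min = 0)
  stop_if_not_scalar_number(spec$cluster_fraction, "cluster_fraction", 0, 1)
  stop_if_not_scalar_number(spec$edge_fraction, "edge_fraction", 0, 1)
  if (!spec$noise_model$type %in% c("none", "poisson_gaussian"))
    stop("noise_model$type must be 'none' or 'poisson_gaussian'", call. = FALSE)
  invisible(spec)
}

## phase-conditional DNA content: lognormal around 2N (G1) / 4N (G2M) with the
## stated CV; S phase is a uniform 2N..4N bridge convolved with the same CV
sample_dna_content <- function(phase, dna_2n_mean, dna_cv) {
  n <- length(phase)
  sdlog <- sqrt(log(1 + dna_cv^2))
  mul <- exp(rnorm(n, -sdlog^2 / 2, sdlog))  # mean-1 lognormal jitter
  base <- numeric(n)
  base[phase == "G1"] <- dna_2n_mean
  base[phase == "G2M"] <- 2 * dna_2n_mean
  ns <- sum(phase == "S")
  base[phase == "S"] <- runif(ns, dna_2n_mean, 2 * dna_2n_mean)
  base * mul
}

## ellipse boundary radius along direction theta (ellipse frame)
ellipse_radius <- function(theta, a, b) 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)

#' Sample a ground-truth cell population for one field
#'
#' Draws per-cell phase, DNA content, nuclear geometry, and peroxisomal spot
#' positions/intensities according to a [scene_spec()]. Designated fractions
#' of cells are planted as merging nucleus pairs (`clustered`) or placed so
#' the nucleus touches an image border (`edge`).
#'
#' @param spec A [scene_spec()].
#' @return An object of class `cell_population`: a list with `cells`
#'   (one row per cell: `cell_id`, `phase`, `dna_content`, `center_row`,
#'   `center_col`, `axis_a`, `axis_b`, `angle`, `clustered`, `edge`),
#'   `spots` (one row per spot: `cell_id`, `row`, `col`, `intensity`),
#'   and the `spec`.
#' @export
sample_cell_population <- function(spec) {
  validate_scene_spec(spec)
  n <- spec$n_cells
  nr <- spec$image_height; nc <- spec$image_width
  if (nr < 1 || nc < 1) stop("zero-size image", call. = FALSE)
  with_seed(spec$seed, {
    if (n == 0) {
      cells <- data.table(cell_id = integer(), phase = character(),
                          dna_content = numeric(), center_row = numeric(),
                          center_col = numeric(), axis_a = numeric(),
                          axis_b = numeric(), angle = numeric(),
                          clustered = logical(), edge = logical())
      return(structure(list(cells = cells,
                            spots = data.table(cell_id = integer(), row = numeric(),
                                               col = numeric(), intensity = numeric()),
                            spec = spec), class = "cell_population"))
    }
    phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE, prob = spec$phase_fractions)
    dna <- sample_dna_content(phase, spec$dna_2n_mean, spec$dna_cv)
    sdlog_r <- sqrt(log(1 + spec$nucleus_radius_cv^2))
    r <- spec$nucleus_radius_mean * exp(rnorm(n, -sdlog_r^2 / 2, sdlog_r))
    ecc <- runif(n, 1, 1.25)
    a <- r * ecc; b <- r / ecc
    angle <- runif(n, 0, pi)

    n_edge <- round(spec$edge_fraction * n)
    n_clu <- 2L * floor(spec$cluster_fraction * n / 2)
    idx <- sample.int(n)  # random assignment of roles
    edge_idx <- idx[seq_len(n_edge)]
    clu_idx <- idx[n_edge + seq_len(n_clu)]
    is_edge <- seq_len(n) %in% edge_idx
    is_clu <- seq_len(n) %in% clu_idx

    cr <- numeric(n); cc <- numeric(n)
    placed_r <- numeric(0); placed_row <- numeric(0); placed_col <- numeric(0)
    place_free <- function(ri, sep = 1.35, tries = 300) {
      m <- ri + 3
      best <- NULL; best_d <- -Inf
      for (t in seq_len(tries)) {
        p <- c(runif(1, m, nr - m), runif(1, m, nc - m))
        d <- if (length(placed_r)) min(sqrt((placed_row - p[1])^2 + (placed_col - p[2])^2) -
                                         sep * (placed_r + ri)) else Inf
        if (d >= 0) return(p)
        if (d > best_d) { best_d <- d; best <- p }
      }
      best
    }
    # clustered pairs: partner closer than the radius sum so masks merge
    pair_of <- rep(NA_integer_, n)
    if (n_clu > 0) {
      firsts <- clu_idx[seq(1, n_clu, by = 2)]
      seconds <- clu_idx[seq(2, n_clu, by = 2)]
      pair_of[firsts] <- seconds
    }
    # pairs are placed first so a partner never collides with an
    # already-placed single (later singles keep their distance from both)
    ord <- c(which(is_clu & !is.na(pair_of)), which(!is_clu & !is_edge))
    for (i in ord) {
      p <- place_free(if (is_clu[i]) r[i] + r[pair_of[i]] else r[i])
      cr[i] <- p[1]; cc[i] <- p[2]
      placed_r <- c(placed_r, r[i]); placed_row <- c(placed_row, p[1]); placed_col <- c(placed_col, p[2])
      if (is_clu[i]) {
        j <- pair_of[i]
        th <- runif(1, 0, 2 * pi)
        # distance from the directional ellipse reaches so the masks overlap
        reach <- ellipse_radius(th - angle[i], a[i], b[i]) +
          ellipse_radius(th + pi - angle[j], a[j], b[j])
        d <- runif(1, 0.80, 0.95) * reach
        cr[j] <- min(max(p[1] + d * cos(th), r[j] + 2), nr - r[j] - 2)
        cc[j] <- min(max(p[2] + d * sin(th), r[j] + 2), nc - r[j] - 2)
        placed_r <- c(placed_r, r[j]); placed_row <- c(placed_row, cr[j]); placed_col <- c(placed_col, cc[j])
      }
    }
    for (i in which(is_edge)) {  # centre near a border so the mask touches it
      side <- sample.int(4, 1)
      off <- runif(1, -0.2, 0.6) * r[i]  # distance of centre inside the border
      along <- runif(1, 1, if (side <= 2) nc else nr)
      if (side == 1) { cr[i] <- 1 + off; cc[i] <- along }
      else if (side == 2) { cr[i] <- nr - off; cc[i] <- along }
      else if (side == 3) { cc[i] <- 1 + off; cr[i] <- along }
      else { cc[i] <- nc - off; cr[i] <- along }
    }

    cells <- data.table(cell_id = seq_len(n), phase = phase, dna_content = dna,
                        center_row = cr, center_col = cc, axis_a = a, axis_b = b,
                        angle = angle, clustered = is_clu, edge = is_edge)

    rate <- spec$spot_rate_per_phase[phase]
    k <- rpois(n, rate)
    tot <- sum(k)
    if (tot > 0) {
      cid <- rep(seq_len(n), k)
      theta <- runif(tot, 0, 2 * pi)
      t_off <- runif(tot, 0, spec$cytoplasm_extent_px)
      rb <- ellipse_radius(theta, a[cid], b[cid])
      rad <- rb + t_off
      srow <- cr[cid] + rad * (cos(theta) * cos(angle[cid]) - sin(theta) * sin(angle[cid]))
      scol <- cc[cid] + rad * (cos(theta) * sin(angle[cid]) + sin(theta) * cos(angle[cid]))
      shape <- 1 / spec$spot_intensity_cv^2
      inten <- rgamma(tot, shape = shape, scale = spec$spot_intensity_mean / shape)
      keep <- srow >= 1 & srow <= nr & scol >= 1 & scol <= nc
      spots <- data.table(cell_id = cid, row = srow, col = scol, intensity = inten)[keep]
    } else {
      spots <- data.table(cell_id = integer(), row = numeric(), col = numeric(),
                          intensity = numeric())
    }
    structure(list(cells = cells, spots = spots, spec = spec),
              class = "cell_population")
  })
}

#' Render a cell population into a two-channel field
#'
#' DNA channel: each nucleus is painted as a flat ellipse whose integrated
#' signal equals the cell's `dna_content` exactly, then edge-softened with a
#' narrow Gaussian; reporter channel: unit-mass isotropic Gaussian kernels of
#' width `spot_sigma_px` scaled by each spot's intensity. The constant channel
#' backgrounds are added and the noise model is applied last. Bit-identical
#' for identical spec and seed.
#'
#' @param pop A `cell_population` from [sample_cell_population()].
#' @param spec A [scene_spec()]; defaults to the one stored in `pop`.
#' @param edge_sigma Nuclear edge softening sigma in px.
#' @return An object of class `scene`: list with numeric matrices `dna` and
#'   `rfp`, plus the ground-truth `cells` and `spots` tables and the `spec`.
#' @export
render_scene <- function(pop, spec = pop$spec, edge_sigma = 1) {
  stopifnot(inherits(pop, "cell_population"))
  validate_scene_spec(spec)
  nr <- spec$image_height; nc <- spec$image_width
  if (nr < 1 || nc < 1) stop("zero-size image", call. = FALSE)
  if (spec$spot_sigma_px <= 0) stop("spot_sigma_px must be > 0", call. = FALSE)
  dna <- matrix(0, nr, nc)
  cells <- pop$cells
  for (i in seq_len(nrow(cells))) {
    a <- cells$axis_a[i]; b <- cells$axis_b[i]; ang <- cells$angle[i]
    r0 <- cells$center_row[i]; c0 <- cells$center_col[i]
    ext <- ceiling(max(a, b)) + 1
    rows <- floor(r0 - ext):ceiling(r0 + ext)
    cols <- floor(c0 - ext):ceiling(c0 + ext)
    dr <- rows - r0; dc <- cols - c0
    u <- outer(dr, dc, function(x, y) x * cos(ang) + y * sin(ang))
    v <- outer(dr, dc, function(x, y) -x * sin(ang) + y * cos(ang))
    mask <- (u / a)^2 + (v / b)^2 <= 1
    npx <- sum(mask)
    if (npx == 0) next
    amp <- cells$dna_content[i] / npx
    inr <- rows >= 1 & rows <= nr
    inc <- cols >= 1 & cols <= nc
    sub <- mask[inr, inc, drop = FALSE] * amp
    dna[rows[inr], cols[inc]] <- dna[rows[inr], cols[inc]] + sub
  }
  if (edge_sigma > 0) dna <- gaussian_smooth(dna, edge_sigma)
  dna <- dna + spec$background_dna

  rfp <- matrix(0, nr, nc)
  spots <- pop$spots
  if (nrow(spots) > 0) {
    g <- gaussian_kernel(spec$spot_sigma_px, truncate = 4)
    k2 <- outer(g, g)  # unit mass
    R <- (length(g) - 1L) / 2L
    for (i in seq_len(nrow(spots))) {
      pr <- round(spots$row[i]); pc <- round(spots$col[i])
      rows <- (pr - R):(pr + R); cols <- (pc - R):(pc + R)
      inr <- rows >= 1 & rows <= nr
      inc <- cols >= 1 & cols <= nc
      rfp[rows[inr], cols[inc]] <- rfp[rows[inr], cols[inc]] +
        spots$intensity[i] * k2[inr, inc, drop = FALSE]
    }
  }
  rfp <- rfp + spec$background_rfp

  if (spec$noise_model$type == "poisson_gaussian") {
    rs <- spec$noise_model$read_sigma %||% 0
    with_seed(derive_seed(spec$seed, "render_noise"), {
      dna <- matrix(rpois(length(dna), dna) + rnorm(length(dna), 0, rs), nr, nc)
      rfp <- matrix(rpois(length(rfp), rfp) + rnorm(length(rfp), 0, rs), nr, nc)
    })
    dna <- pmax(dna, 0); rfp <- pmax(rfp, 0)
  }
  structure(list(dna = dna, rfp = rfp, cells = pop$cells, spots = pop$spots,
                 spec = spec), class = "scene")
}

#' Define a compound's planted effect
#'
#' Archetypes mirror the screen's compound categories: `A_cell_cycle`
#' (cell-cycle arrest shifts the phase mixture, raising mean DNA content and,
#' through the phase-linked spot model, peroxisomal signal), `B_perox_up` /
#' `C_perox_down` (fold change on spot rates without cell-cycle change),
#' `cytotoxic` (only a fraction of cells survive), and `null`.
#'
#' @param compound_id Unique compound identifier.
#' @param archetype One of `"A_cell_cycle"`, `"B_perox_up"`, `"C_perox_down"`,
#'   `"cytotoxic"`, `"null"`.
#' @param perox_multiplier Fold applied to the per-phase spot rates
#'   (default 1.8 for B, 0.5 for C, 1 otherwise). Must be > 0.
#' @param phase_shift Replacement phase fractions (archetype A only;
#'   default `c(0.2, 0.2, 0.6)`, a G2/M arrest).
#' @param survival_fraction Surviving fraction of cells (cytotoxic only;
#'   default 0.15). In `(0, 1]`.
#' @param count_multiplier Fold on expected cell count (default 0.6 for
#'   archetype A — arrest reduces proliferation — and 1 otherwise).
#' @return An object of class `compound_effect`.
#' @export
compound_effect <- function(compound_id,
                            archetype = c("null", "A_cell_cycle", "B_perox_up",
                                          "C_perox_down", "cytotoxic"),
                            perox_multiplier = NULL, phase_shift = NULL,
                            survival_fraction = NULL, count_multiplier = NULL) {
  archetype <- match.arg(archetype)
  perox_multiplier <- perox_multiplier %||%
    switch(archetype, B_perox_up = 1.8, C_perox_down = 0.5, 1)
  if (archetype == "A_cell_cycle") {
    phase_shift <- phase_shift %||% c(G1 = 0.2, S = 0.2, G2M = 0.6)
    count_multiplier <- count_multiplier %||% 0.6
  } else if (!is.null(phase_shift)) {
    stop("phase_shift is only meaningful for archetype A_cell_cycle", call. = FALSE)
  }
  count_multiplier <- count_multiplier %||% 1
  survival_fraction <- survival_fraction %||%
    if (archetype == "cytotoxic") 0.15 else 1
  if (perox_multiplier <= 0) stop("perox_multiplier must be > 0", call. = FALSE)
  if (survival_fraction <= 0 || survival_fraction > 1)
    stop("survival_fraction must be in (0, 1]", call. = FALSE)
  if (archetype == "null" && (perox_multiplier != 1 || !is.null(phase_shift)))
    stop("null archetype must have multiplier 1 and no phase_shift", call. = FALSE)
  if (!is.null(phase_shift)) {
    phase_shift <- setNames(as.numeric(phase_shift), c("G1", "S", "G2M"))
    if (abs(sum(phase_shift) - 1) > 1e-9) stop("phase_shift must sum to 1", call. = FALSE)
  }
  structure(list(compound_id = as.character(compound_id), archetype = archetype,
                 perox_multiplier = perox_multiplier, phase_shift = phase_shift,
                 survival_fraction = survival_fraction,
                 count_multiplier = count_multiplier),
            class = "compound_effect")
}

#' Build a library of compound effects by archetype counts
#'
#' @param n_A,n_B,n_C,n_cytotoxic,n_null Number of compounds per archetype.
#' @return A list of [compound_effect()] objects with ids `CPD0001`, ...
#' @export
effect_library <- function(n_A = 0, n_B = 0, n_C = 0, n_cytotoxic = 0, n_null = 0) {
  arch <- rep(c("A_cell_cycle", "B_perox_up", "C_perox_down", "cytotoxic", "null"),
              times = c(n_A, n_B, n_C, n_cytotoxic, n_null))
  lapply(seq_along(arch), function(i)
    compound_effect(sprintf("CPD%04d", i), arch[i]))
}

#' Simulate a multi-replicate compound screen
#'
#' Lays out one well per compound per replicate plus vehicle-control wells on
#' every replicate. `"table"` fidelity emits per-cell measurement tables
#' directly from the generative model (fast path for library-scale screens);
#' `"image"` fidelity renders two-channel fields (default 12 per well) for the
#' imaging stages.
#'
#' @param effects List of [compound_effect()] objects (may be empty).
#' @param n_replicates Number of biological replicates (default 3).
#' @param fidelity `"table"` or `"image"`.
#' @param base_spec [scene_spec()] describing one control field; well-level
#'   expected cell count is `n_cells * n_fields`.
#' @param seed Top-level seed; all well-level randomness derives from it.
#' @param n_fields Fields per well (image fidelity; also scales table-fidelity
#'   cell counts).
#' @param n_control_wells Control wells per replicate.
#' @param dir Optional directory: image fidelity writes per-field TIFFs
#'   (pages: DNA, reporter) plus plate map and truth CSVs there.
#' @return An object of class `screen_sim`: list with `plate_map`
#'   (well_id, compound_id, replicate, role), `cells` (table fidelity; one row
#'   per cell), `images` (image fidelity; nested list well -> field -> scene,
#'   unless written to `dir`), and `truth` (compound_id, archetype, ...).
#' @export
simulate_screen <- function(effects = list(), n_replicates = 3,
                            fidelity = c("table", "image"),
                            base_spec = scene_spec(), seed = 1L,
                            n_fields = 12, n_control_wells = 8, dir = NULL) {
  fidelity <- match.arg(fidelity)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  ids <- vapply(effects, function(e) e$compound_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound_id", call. = FALSE)
  validate_scene_spec(base_spec)

  pm <- rbindlist(lapply(seq_len(n_replicates), function(r) {
    ctrl <- data.table(well_id = sprintf("R%d_CTRL%02d", r, seq_len(n_control_wells)),
                       compound_id = "vehicle", replicate = r, role = "control")
    cpd <- if (length(ids)) data.table(well_id = sprintf("R%d_%s", r, ids),
                                       compound_id = ids, replicate = r,
                                       role = "compound") else NULL
    rbind(ctrl, cpd)
  }))
  truth <- rbindlist(lapply(effects, function(e)
    data.table(compound_id = e$compound_id, archetype = e$archetype,
               perox_multiplier = e$perox_multiplier,
               survival_fraction = e$survival_fraction,
               count_multiplier = e$count_multiplier)))
  eff_by_id <- setNames(effects, ids)
  null_eff <- compound_effect("vehicle", "null")

  if (fidelity == "table") {
    cells <- rbindlist(lapply(seq_len(nrow(pm)), function(i) {
      w <- pm[i]
      e <- if (w$role == "control") null_eff else eff_by_id[[w$compound_id]]
      simulate_well_table(base_spec, e, n_fields,
                          derive_seed(seed, paste0("well:", w$well_id)), w$well_id)
    }))
    out <- list(plate_map = pm, cells = cells, images = NULL, truth = truth,
                fidelity = fidelity, base_spec = base_spec, seed = as.integer(seed))
  } else {
    images <- list()
    for (i in seq_len(nrow(pm))) {
      w <- pm[i]
      e <- if (w$role == "control") null_eff else eff_by_id[[w$compound_id]]
      flds <- lapply(seq_len(n_fields), function(f) {
        sp <- apply_effect_to_spec(base_spec, e)
        sp$seed <- derive_seed(seed, sprintf("field:%s:%d", w$well_id, f))
        render_scene(sample_cell_population(sp), sp)
      })
      if (!is.null(dir)) {
        for (f in seq_along(flds))
          write_tiff(list(flds[[f]]$dna, flds[[f]]$rfp),
                     file.path(dir, sprintf("%s_f%02d.tif", w$well_id, f)))
        flds <- NULL
      }
      images[[w$well_id]] <- flds
    }
    if (!is.null(dir)) {
      fwrite(pm, file.path(dir, "plate_map.csv"))
      if (nrow(truth)) fwrite(truth, file.path(dir, "truth.csv"))
      images <- NULL
    }
    out <- list(plate_map = pm, cells = NULL, images = images, truth = truth,
                fidelity = fidelity, base_spec = base_spec, seed = as.integer(seed))
  }
  structure(out, class = "screen_sim")
}

## per-well spec with a compound effect applied (image fidelity)
apply_effect_to_spec <- function(spec, e) {
  sp <- spec
  if (!is.null(e$phase_shift)) sp$phase_fractions <- e$phase_shift
  sp$spot_rate_per_phase <- sp$spot_rate_per_phase * e$perox_multiplier
  sp$n_cells <- max(0L, as.integer(round(
    sp$n_cells * e$count_multiplier * e$survival_fraction)))
  sp
}

## table-fidelity fast path: draw CellRecord-ready rows from the generative
## model without rendering
simulate_well_table <- function(spec, e, n_fields, well_seed, well_id) {
  with_seed(well_seed, {
    n_exp <- spec$n_cells * n_fields * e$count_multiplier * e$survival_fraction
    n <- rpois(1, n_exp)
    if (n == 0)
      return(data.table(well_id = character(), field_index = integer(),
                        cell_label = integer(), phase = character(),
                        true_phase = character(),
                        integrated_dna = numeric(), spot_count = integer(),
                        spot_total_intensity = numeric(),
                        cytoplasm_mean_intensity = numeric()))
    pf <- if (!is.null(e$phase_shift)) e$phase_shift else spec$phase_fractions
    phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE, prob = pf)
    dna <- sample_dna_content(phase, spec$dna_2n_mean, spec$dna_cv)
    rate <- spec$spot_rate_per_phase[phase] * e$perox_multiplier
    k <- rpois(n, rate)
    shape <- 1 / spec$spot_intensity_cv^2
    tot <- numeric(n)
    pos <- k > 0  # sum of k gamma spots is gamma with shape k * shape
    tot[pos] <- rgamma(sum(pos), shape = k[pos] * shape,
                       scale = spec$spot_intensity_mean / shape)
    cyto_area <- pi * ((spec$nucleus_radius_mean + spec$cytoplasm_extent_px)^2 -
                         spec$nucleus_radius_mean^2)
    data.table(well_id = well_id,
               field_index = sample.int(n_fields, n, replace = TRUE),
               cell_label = seq_len(n), phase = "unassigned",
               true_phase = phase,
               integrated_dna = dna, spot_count = k,
               spot_total_intensity = tot,
               cytoplasm_mean_intensity = tot / cyto_area)
  })
}

#' Flow-cytometry condition specification
#'
#' Generative parameters for one acquisition: event count, dead fraction
#' (two-component lognormal PI mixture), ROS fold on the DCFDA channel, and
#' the same phase-linked DNA/peroxisome model used for images.
#'
#' @param condition_id Condition label.
#' @param n_events Number of events (> 0).
#' @param dead_fraction Fraction of PI-high (dead) events, in `[0, 1]`.
#' @param pi_live_mean,pi_dead_mean Medians of the live/dead PI components
#'   (lognormal); dead must exceed live.
#' @param pi_cv Lognormal spread (sdlog) of each PI component.
#' @param dcfda_mean Median DCFDA intensity of the control state.
#' @param ros_fold Fold applied to the DCFDA median.
#' @param dcfda_cv Lognormal spread (sdlog) of DCFDA.
#' @param phase_fractions,perox_rate_per_phase,dna_2n_mean,dna_cv As in
#'   [scene_spec()] (spot rates here set the peroxisome channel mean).
#' @param spot_intensity_mean,spot_intensity_cv As in [scene_spec()].
#' @param seed Integer seed.
#' @return An object of class `flow_condition_spec`.
#' @export
flow_condition_spec <- function(condition_id = "control", n_events = 10000,
                                dead_fraction = 0.05,
                                pi_live_mean = 100, pi_dead_mean = 1000,
                                pi_cv = 0.4,
                                dcfda_mean = 1000, ros_fold = 1, dcfda_cv = 0.5,
                                phase_fractions = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                                perox_rate_per_phase = c(G1 = 10, S = 20, G2M = 22),
                                dna_2n_mean = 100, dna_cv = 0.05,
                                spot_intensity_mean = 500, spot_intensity_cv = 0.25,
                                seed = 1L) {
  if (n_events <= 0) stop("n_events must be > 0", call. = FALSE)
  stop_if_not_scalar_number(dead_fraction, "dead_fraction", 0, 1)
  if (pi_dead_mean <= pi_live_mean)
    stop("pi_dead_mean must exceed pi_live_mean", call. = FALSE)
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1", call. = FALSE)
  structure(list(condition_id = condition_id, n_events = as.integer(n_events),
                 dead_fraction = dead_fraction, pi_live_mean = pi_live_mean,
                 pi_dead_mean = pi_dead_mean, pi_cv = pi_cv,
                 dcfda_mean = dcfda_mean, ros_fold = ros_fold, dcfda_cv = dcfda_cv,
                 phase_fractions = setNames(as.numeric(phase_fractions),
                                            c("G1", "S", "G2M")),
                 perox_rate_per_phase = setNames(as.numeric(perox_rate_per_phase),
                                                 c("G1", "S", "G2M")),
                 dna_2n_mean = dna_2n_mean, dna_cv = dna_cv,
                 spot_intensity_mean = spot_intensity_mean,
                 spot_intensity_cv = spot_intensity_cv,
                 seed = as.integer(seed)),
            class = "flow_condition_spec")
}

#' Simulate a flow-cytometry event table
#'
#' PI is a two-component lognormal mixture weighted by `dead_fraction`; DCFDA
#' is lognormal with median `dcfda_mean * ros_fold`; DNA and peroxisome
#' channels follow the phase-linked model shared with the imaging generator.
#'
#' @param spec A [flow_condition_spec()].
#' @return A `data.table` with columns `condition_id`, `dna`, `peroxisome`,
#'   `dcfda`, `pi`, `dead` (ground-truth flag).
#' @export
simulate_flow_events <- function(spec) {
  stopifnot(inherits(spec, "flow_condition_spec"))
  with_seed(spec$seed, {
    n <- spec$n_events
    dead <- runif(n) < spec$dead_fraction
    pi_int <- exp(rnorm(n, log(ifelse(dead, spec$pi_dead_mean, spec$pi_live_mean)),
                        spec$pi_cv))
    dcfda <- exp(rnorm(n, log(spec$dcfda_mean * spec$ros_fold), spec$dcfda_cv))
    phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                    prob = spec$phase_fractions)
    dna <- sample_dna_content(phase, spec$dna_2n_mean, spec$dna_cv)
    k <- rpois(n, spec$perox_rate_per_phase[phase])
    shape <- 1 / spec$spot_intensity_cv^2
    perox <- numeric(n)
    pos <- k > 0
    perox[pos] <- rgamma(sum(pos), shape = k[pos] * shape,
                         scale = spec$spot_intensity_mean / shape)
    data.table(condition_id = spec$condition_id, dna = dna, peroxisome = perox,
               dcfda = dcfda, pi = pi_int, dead = dead)
  })
}

#' Simulate independent flow replicates of one condition
#'
#' Emulates N independent experiments: each replicate gets its own seed and a
#' between-replicate logit-normal jitter on `dead_fraction` (biological
#' variability beyond event-level binomial noise).
#'
#' @param spec A [flow_condition_spec()].
#' @param n_replicates Number of replicates (default 3).
#' @param rep_logit_sd Between-replicate SD of the logit dead fraction.
#' @return A list of event tables (see [simulate_flow_events()]).
#' @export
simulate_flow_replicates <- function(spec, n_replicates = 3, rep_logit_sd = 0.25) {
  lapply(seq_len(n_replicates), function(r) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, paste0("rep:", r))
    if (rep_logit_sd > 0 && spec$dead_fraction > 0 && spec$dead_fraction < 1) {
      lg <- with_seed(derive_seed(sp$seed, "jitter"),
                      rnorm(1, log(spec$dead_fraction / (1 - spec$dead_fraction)),
                            rep_logit_sd))
      sp$dead_fraction <- 1 / (1 + exp(-lg))
    }
    simulate_flow_events(sp)
  })
}
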
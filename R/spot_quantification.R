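## Punctate spot detection in the cytoplasmic compartments and per-cell
## measurement aggregation.

#' Spot detection parameters
#'
#' @param sigma Expected spot width (Gaussian sigma, px); the band-pass scale.
#' @param k Contrast threshold in robust noise units: peaks must exceed
#'   `median + k * MAD` of the band-passed image over cytoplasm pixels.
#' @param dog_ratio Ratio of the two smoothing scales of the
#'   difference-of-Gaussians band-pass.
#' @param aperture_factor Intensity integration aperture radius in units of
#'   `sigma` (pixels are partitioned to the nearest peak, so overlapping
#'   apertures never double-count).
#' @param mask_frac Fraction of the peak height defining the reported spot
#'   extent (`n_px`).
#' @param peak_tol_px Peaks are also accepted within this distance inside the
#'   nucleus-mask boundary: the thresholded nuclear mask slightly overshoots
#'   the true nucleus, so perinuclear cytoplasmic spots peak just inside it.
#'   Spots deeper in the nuclear mask are never counted.
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(sigma = 1.5, k = 5, dog_ratio = 1.6,
                        aperture_factor = 3, mask_frac = 0.5,
                        peak_tol_px = 1.5) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(sigma = sigma, k = k, dog_ratio = dog_ratio,
                 aperture_factor = aperture_factor, mask_frac = mask_frac,
                 peak_tol_px = peak_tol_px),
            class = "spot_params")
}

#' Detect peroxisomal spots in cytoplasmic regions
#'
#' Band-passes the reporter channel (difference of Gaussians at scale
#' `sigma`), finds local maxima above a robust contrast threshold restricted
#' to cytoplasm pixels, and assigns each spot to the compartment containing
#' its peak. Spot intensities are background-corrected sums over a disk of
#' radius `aperture_factor * sigma` around the peak; pixels inside several
#' apertures are assigned to the nearest peak so per-spot intensities add
#' exactly to per-cell totals. The background is the per-cell median
#' cytoplasmic intensity outside all spot apertures.
#'
#' Spots closer than about `2 * sigma` merge into a single detection (counts
#' may undercount at high density).
#'
#' @param reporter_channel Numeric matrix, same shape as the compartments.
#' @param compartments A `compartment_map` from [build_cytoplasm_regions()].
#' @param params A [spot_params()] list.
#' @return A `data.table` of class `spot_set`: `cell_label`, `row`, `col`
#'   (peak, px), `peak_value` (band-pass height), `n_px` (half-peak extent),
#'   `integrated_intensity`.
#' @export
detect_spots <- function(reporter_channel, compartments, params = spot_params()) {
  stopifnot(inherits(compartments, "compartment_map"))
  cyto <- compartments$cytoplasm_labels
  if (!is.matrix(reporter_channel) || !all(dim(reporter_channel) == dim(cyto)))
    stop("reporter image and compartment map shapes differ", call. = FALSE)
  if (params$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  band <- gaussian_smooth(reporter_channel, params$sigma) -
    gaussian_smooth(reporter_channel, params$sigma * params$dog_ratio)
  cyto_mask <- cyto > 0
  if (!any(cyto_mask)) return(empty_spot_table())
  bvals <- band[cyto_mask]
  thr <- median(bvals) + params$k * mad(bvals)
  # tolerance ring: the thresholded mask sits within ~1 px of the true
  # nucleus/cytoplasm boundary, so peaks are also accepted within
  # peak_tol_px on either side of the cytoplasm region (never deeper in the
  # nuclear mask or further out)
  search_mask <- cyto_mask
  ext <- NULL
  if (params$peak_tol_px > 0) {
    ext <- cpp_nearest_site(cyto, params$peak_tol_px)
    search_mask <- ext > 0
  }
  radius <- max(1L, as.integer(floor(params$sigma / 1.5)))
  pk <- cpp_local_maxima(band, search_mask, radius, thr)
  np <- length(pk$row)
  if (np == 0) return(empty_spot_table())

  nr <- nrow(band)
  cell <- cyto[cbind(pk$row, pk$col)]
  if (!is.null(ext)) {
    ring <- cell == 0
    cell[ring] <- ext[cbind(pk$row, pk$col)][ring]
  }
  ra <- ceiling(params$aperture_factor * params$sigma)
  offs <- expand.grid(dr = -ra:ra, dc = -ra:ra)
  offs <- offs[offs$dr^2 + offs$dc^2 <= ra^2, ]
  cand <- data.table(
    spot = rep(seq_len(np), each = nrow(offs)),
    r = rep(pk$row, each = nrow(offs)) + offs$dr,
    c = rep(pk$col, each = nrow(offs)) + offs$dc,
    d2 = rep(offs$dr^2 + offs$dc^2, times = np))
  cand <- cand[r >= 1 & r <= nr & c >= 1 & c <= ncol(band)]
  cand[, px := (c - 1L) * nr + r]
  setorder(cand, px, d2, spot)
  cand <- cand[!duplicated(px)]  # each pixel claimed by its nearest peak

  # per-cell background: cytoplasm pixels outside all apertures
  claimed <- logical(length(band))
  claimed[cand$px] <- TRUE
  cyto_idx <- which(cyto_mask)
  free_idx <- cyto_idx[!claimed[cyto_idx]]
  if (length(free_idx) == 0) free_idx <- cyto_idx
  bg_tab <- tapply(reporter_channel[free_idx], cyto[free_idx], median)
  global_bg <- median(reporter_channel[free_idx])
  bg_of_cell <- function(cl) {
    v <- bg_tab[as.character(cl)]
    ifelse(is.na(v), global_bg, v)
  }
  cand[, val := reporter_channel[px]]
  sums <- cand[, .(s = sum(val), n = .N), by = spot]
  integ <- numeric(np); npx_ap <- integer(np)
  integ[sums$spot] <- sums$s
  npx_ap[sums$spot] <- sums$n
  bgs <- as.numeric(bg_of_cell(cell))
  integ <- pmax(integ - bgs * npx_ap, 0)

  # half-peak extent on the band-passed image within the claimed aperture
  cand[, bv := band[px]]
  halves <- cand[, .(nh = sum(bv >= params$mask_frac * pk$value[spot[1]])), by = spot]
  n_half <- integer(np)
  n_half[halves$spot] <- halves$nh

  structure(data.table(cell_label = cell, row = pk$row, col = pk$col,
                       peak_value = pk$value, n_px = n_half,
                       integrated_intensity = integ),
            class = c("spot_set", "data.table", "data.frame"))
}

empty_spot_table <- function() {
  structure(data.table(cell_label = integer(), row = integer(), col = integer(),
                       peak_value = numeric(), n_px = integer(),
                       integrated_intensity = numeric()),
            class = c("spot_set", "data.table", "data.frame"))
}

#' Summarize per-cell measurements
#'
#' Produces one record per retained (unflagged) nucleus: integrated DNA
#' signal, spot count and spot total intensity aggregated from the spot
#' table (exact sums), and the mean background-corrected reporter intensity
#' over the cytoplasm mask (`cytoplasm_mean_intensity`, the whole-region
#' readout used for immunofluorescence-style quantification). Phase starts
#' `"unassigned"`; see [assign_phase()].
#'
#' @param nucleus_set A flagged `nucleus_set` (see [flag_excluded_nuclei()]).
#' @param compartments The matching `compartment_map`.
#' @param spots A `spot_set` from [detect_spots()].
#' @param reporter_channel Reporter image (for the whole-region readout);
#'   `NULL` to skip.
#' @param well_id,field_index Identifiers copied into every record.
#' @return A `data.table` with columns `well_id`, `field_index`,
#'   `cell_label`, `phase`, `integrated_dna`, `spot_count`,
#'   `spot_total_intensity`, `cytoplasm_mean_intensity`.
#' @export
summarize_cells <- function(nucleus_set, compartments, spots,
                            reporter_channel = NULL,
                            well_id = "well", field_index = 1L) {
  stopifnot(inherits(nucleus_set, "nucleus_set"),
            inherits(compartments, "compartment_map"))
  keep <- retained_labels(nucleus_set)
  if (nrow(spots) > 0 && !all(spots$cell_label %in% keep))
    stop("spot references a label that is not a retained nucleus", call. = FALSE)
  nuc <- nucleus_set$nuclei[label %in% keep]
  agg <- if (nrow(spots) > 0)
    spots[, .(spot_count = .N, spot_total_intensity = sum(integrated_intensity)),
          by = cell_label] else
    data.table(cell_label = integer(), spot_count = integer(),
               spot_total_intensity = numeric())
  out <- merge(data.table(cell_label = nuc$label, integrated_dna = nuc$integrated_dna),
               agg, by = "cell_label", all.x = TRUE)
  out[is.na(spot_count), `:=`(spot_count = 0L, spot_total_intensity = 0)]
  cmi <- rep(NA_real_, nrow(out))
  if (!is.null(reporter_channel)) {
    cyto <- compartments$cytoplasm_labels
    idx <- which(cyto > 0)
    bg_field <- median(reporter_channel[cyto == 0 & nucleus_set$labels == 0])
    means <- tapply(reporter_channel[idx] - bg_field, cyto[idx], mean)
    cmi <- as.numeric(means[as.character(out$cell_label)])
  }
  out[, `:=`(well_id = well_id, field_index = as.integer(field_index),
             phase = "unassigned", cytoplasm_mean_intensity = cmi)]
  setcolorder(out, c("well_id", "field_index", "cell_label", "phase",
                     "integrated_dna", "spot_count", "spot_total_intensity",
                     "cytoplasm_mean_intensity"))
  out[]
}

#' Measure one rendered field end to end
#'
#' Convenience wrapper: [detect_nuclei()], [flag_excluded_nuclei()],
#' [build_cytoplasm_regions()], [detect_spots()], [summarize_cells()].
#'
#' @param scene A `scene` (list with `dna` and `rfp` matrices) or the two
#'   matrices given separately.
#' @param rfp Reporter matrix when `scene` is the DNA matrix.
#' @param nucleus,cluster,spot Stage parameter lists.
#' @param max_extent_px Cytoplasm reach, px.
#' @param well_id,field_index Identifiers for the records.
#' @return List with `cells` (per-cell records), `nuclei` (`nucleus_set`),
#'   `compartments`, and `spots`.
#' @export
measure_field <- function(scene, rfp = NULL, nucleus = nucleus_params(),
                          cluster = cluster_params(), spot = spot_params(),
                          max_extent_px = 15, well_id = "well",
                          field_index = 1L) {
  if (is.list(scene) && !is.null(scene$dna)) {
    dna <- scene$dna; rfp <- scene$rfp
  } else dna <- scene
  ns <- flag_excluded_nuclei(detect_nuclei(dna, nucleus), cluster)
  if (length(retained_labels(ns)) == 0)
    return(list(cells = summarize_empty(well_id, field_index), nuclei = ns,
                compartments = NULL, spots = empty_spot_table()))
  cm <- build_cytoplasm_regions(ns, max_extent_px = max_extent_px)
  sp <- detect_spots(rfp, cm, spot)
  cells <- summarize_cells(ns, cm, sp, rfp, well_id, field_index)
  list(cells = cells, nuclei = ns, compartments = cm, spots = sp)
}

summarize_empty <- function(well_id, field_index) {
  data.table(well_id = character(), field_index = integer(),
             cell_label = integer(), phase = character(),
             integrated_dna = numeric(), spot_count = integer(),
             spot_total_intensity = numeric(),
             cytoplasm_mean_intensity = numeric())
}
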
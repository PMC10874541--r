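## Well- and compound-level screen analysis: aggregation, the 25%-of-control
## cytotoxicity filter, percent-of-control standardization, 5/95 percentile
## cutoffs, and A/B/C categorization.

#' Summarize the retained cells of one well
#'
#' @param records Per-cell records sharing one `well_id`.
#' @return A one-row `data.table`: `well_id`, `cell_count`,
#'   `mean_spot_count`, `mean_spot_total_intensity`, `mean_integrated_dna`
#'   (means are `NA` when the well holds no retained cells).
#' @export
summarize_well <- function(records) {
  records <- as.data.table(records)
  if (nrow(records) > 0 && length(unique(records$well_id)) != 1)
    stop("records must share one well_id", call. = FALSE)
  if (nrow(records) == 0)
    return(data.table(well_id = NA_character_, cell_count = 0L,
                      mean_spot_count = NA_real_,
                      mean_spot_total_intensity = NA_real_,
                      mean_integrated_dna = NA_real_))
  records[, .(cell_count = .N,
              mean_spot_count = mean(spot_count),
              mean_spot_total_intensity = mean(spot_total_intensity),
              mean_integrated_dna = mean(integrated_dna)),
          by = well_id]
}

#' Summarize all wells of a screen
#'
#' @param records Per-cell records for the whole plate set.
#' @param plate_map `data.table` with `well_id`, `compound_id`, `replicate`,
#'   `role` (`"control"` / `"compound"`).
#' @return One row per well of the plate map (wells without cells get
#'   `cell_count` 0), with plate-map columns joined on.
#' @export
summarize_wells <- function(records, plate_map) {
  plate_map <- as.data.table(plate_map)
  ws <- summarize_well_by(records)
  out <- merge(plate_map, ws, by = "well_id", all.x = TRUE)
  out[is.na(cell_count), cell_count := 0L]
  out[]
}

summarize_well_by <- function(records) {
  as.data.table(records)[, .(
    cell_count = .N,
    mean_spot_count = mean(spot_count),
    mean_spot_total_intensity = mean(spot_total_intensity),
    mean_integrated_dna = mean(integrated_dna)), by = well_id]
}

#' Apply the cytotoxicity filter
#'
#' The control average is the mean retained cell count over all control wells
#' of the same replicate; a compound is cytotoxic when its replicate-mean
#' cell count is strictly less than 25% of that average (a well with zero
#' cells is cytotoxic regardless). Cytotoxic compounds are excluded from
#' standardization and categorization.
#'
#' @param well_summaries Output of [summarize_wells()].
#' @param threshold Fraction of the control average (default 0.25).
#' @return A `data.table`, one row per compound: `compound_id`,
#'   `mean_cell_count`, `control_avg_count`, `cytotoxic`.
#' @export
apply_cytotoxicity_filter <- function(well_summaries, threshold = 0.25) {
  ws <- as.data.table(well_summaries)
  ctrl <- ws[role == "control", .(control_avg = mean(cell_count)), by = replicate]
  if (nrow(ctrl) == 0) stop("no control wells", call. = FALSE)
  cpd <- merge(ws[role == "compound"], ctrl, by = "replicate")
  # replicate-mean relative count, then compare to the pooled control average
  per_rep <- cpd[, .(count = mean(cell_count), control_avg = control_avg[1]),
                 by = .(compound_id, replicate)]
  res <- per_rep[, .(mean_cell_count = mean(count),
                     control_avg_count = mean(control_avg)), by = compound_id]
  res[, cytotoxic := mean_cell_count < threshold * control_avg_count |
        mean_cell_count == 0]
  res[]
}

#' Standardize well means to the control average
#'
#' Per replicate, each compound metric is divided by that replicate's control
#' mean; compound-level values are the mean of the per-replicate folds.
#' Metrics: spot total intensity/cell (`std_peroxisome`), integrated
#' DNA/cell (`std_dna`), cell count (`rel_cell_count`), spot count/cell
#' (`rel_spot_count`).
#'
#' @param well_summaries Output of [summarize_wells()].
#' @return A `data.table`, one row per compound, with the four fold-of-control
#'   metrics.
#' @export
standardize_to_control <- function(well_summaries) {
  ws <- as.data.table(well_summaries)
  ctrl <- ws[role == "control" & cell_count > 0,
             .(c_perox = mean(mean_spot_total_intensity),
               c_dna = mean(mean_integrated_dna),
               c_count = mean(cell_count),
               c_spots = mean(mean_spot_count)), by = replicate]
  if (nrow(ctrl) == 0) stop("no control wells", call. = FALSE)
  if (any(ctrl$c_perox <= 0) || any(ctrl$c_dna <= 0) || any(ctrl$c_count <= 0))
    stop("zero control mean", call. = FALSE)
  cpd <- merge(ws[role == "compound" & cell_count > 0], ctrl, by = "replicate")
  folds <- cpd[, .(std_peroxisome = mean_spot_total_intensity / c_perox,
                   std_dna = mean_integrated_dna / c_dna,
                   rel_cell_count = cell_count / c_count,
                   rel_spot_count = mean_spot_count / c_spots),
               by = .(compound_id, replicate)]
  folds[, .(std_peroxisome = mean(std_peroxisome),
            std_dna = mean(std_dna),
            rel_cell_count = mean(rel_cell_count),
            rel_spot_count = mean(rel_spot_count)), by = compound_id]
}

#' Compute 5th/95th percentile cutoffs
#'
#' Empirical percentiles of the reference distribution under the
#' linear-interpolation convention (R quantile type 7).
#'
#' @param values Reference values for one axis (>= `min_n`).
#' @param probs Lower/upper percentile probabilities.
#' @param min_n Minimum reference size (default 20).
#' @return A list of class `cutoff_pair`: `low`, `high`.
#' @export
compute_cutoffs <- function(values, probs = c(0.05, 0.95), min_n = 20) {
  values <- values[is.finite(values)]
  if (length(values) < min_n)
    stop(sprintf("need >= %d values (got %d)", min_n, length(values)),
         call. = FALSE)
  q <- quantile(values, probs, type = 7, names = FALSE)
  if (!(q[1] < q[2]))
    stop("degenerate reference distribution: low cutoff not below high",
         call. = FALSE)
  structure(list(low = q[1], high = q[2]), class = "cutoff_pair")
}

#' Categorize compounds on the peroxisome and DNA axes
#'
#' Group A: DNA signal above its band (cell-cycle-mediated change; these
#' compounds raise peroxisomal signal through arrest). Group B / C:
#' peroxisome signal above / below its band with DNA inside its band.
#' Everything else is `"none"`. Cytotoxic compounds must be excluded before
#' calling; they never receive a category.
#'
#' @param std Compound table from [standardize_to_control()] (cytotoxic rows
#'   removed).
#' @param cutoffs_perox,cutoffs_dna `cutoff_pair` objects per axis.
#' @return `std` with `category` (`"A"`, `"B"`, `"C"`, `"none"`) and
#'   `perox_flagged` (outside the peroxisome band) columns.
#' @export
categorize_compounds <- function(std, cutoffs_perox, cutoffs_dna) {
  std <- as.data.table(std)
  stopifnot(inherits(cutoffs_perox, "cutoff_pair"),
            inherits(cutoffs_dna, "cutoff_pair"))
  dna_in <- std$std_dna >= cutoffs_dna$low & std$std_dna <= cutoffs_dna$high
  std[, category := "none"]
  std[std_dna > cutoffs_dna$high, category := "A"]
  std[dna_in & std_peroxisome > cutoffs_perox$high, category := "B"]
  std[dna_in & std_peroxisome < cutoffs_perox$low, category := "C"]
  std[, perox_flagged := std_peroxisome > cutoffs_perox$high |
        std_peroxisome < cutoffs_perox$low]
  std[]
}

#' Heatmap-style table of categorized hits
#'
#' One row per compound in groups A/B/C with the four fold-of-control
#' metrics, sorted by category then standardized peroxisome signal.
#'
#' @param results Categorized compound table (see [categorize_compounds()]).
#' @return A `data.table` subset of `results`.
#' @export
build_heatmap_table <- function(results) {
  res <- as.data.table(results)[category %in% c("A", "B", "C"),
    .(compound_id, category, rel_cell_count, rel_spot_count,
      std_peroxisome, std_dna)]
  setorder(res, category, -std_peroxisome)
  res[]
}

#' Analyze a screen end to end (well aggregation to categories)
#'
#' Runs [summarize_wells()], [apply_cytotoxicity_filter()],
#' [standardize_to_control()], [compute_cutoffs()] and
#' [categorize_compounds()]. The cutoff reference distribution defaults to
#' the full compound cloud (robust to a small hit fraction); `"controls"`
#' uses the replicate-wise standardized control wells instead.
#'
#' @param records Per-cell records.
#' @param plate_map Plate map (`well_id`, `compound_id`, `replicate`, `role`).
#' @param cutoff_source `"compounds"` or `"controls"`.
#' @param cytotox_threshold Fraction of control average (default 0.25).
#' @return An object of class `screen_result`: list with `wells`,
#'   `compounds` (categorized, incl. cytotoxic rows marked
#'   `category = "excluded"`), `cutoffs` (per axis), and `hits`
#'   (the [build_heatmap_table()] view).
#' @export
analyze_screen <- function(records, plate_map,
                           cutoff_source = c("compounds", "controls"),
                           cytotox_threshold = 0.25) {
  cutoff_source <- match.arg(cutoff_source)
  ws <- summarize_wells(records, plate_map)
  tox <- apply_cytotoxicity_filter(ws, cytotox_threshold)
  std <- standardize_to_control(ws)
  std <- merge(std, tox[, .(compound_id, cytotoxic)], by = "compound_id",
               all.x = TRUE)
  std[is.na(cytotoxic), cytotoxic := TRUE]  # no surviving wells at all
  ok <- std[cytotoxic == FALSE]
  ref <- if (cutoff_source == "compounds") {
    list(perox = ok$std_peroxisome, dna = ok$std_dna)
  } else {
    ctrl_folds <- control_reference_folds(ws)
    list(perox = ctrl_folds$std_peroxisome, dna = ctrl_folds$std_dna)
  }
  cut_p <- compute_cutoffs(ref$perox)
  cut_d <- compute_cutoffs(ref$dna)
  cat_ok <- categorize_compounds(ok, cut_p, cut_d)
  excl <- std[cytotoxic == TRUE]
  if (nrow(excl)) excl[, `:=`(category = "excluded", perox_flagged = NA)]
  compounds <- rbind(cat_ok, excl, fill = TRUE)
  setorder(compounds, compound_id)
  structure(list(wells = ws, compounds = compounds,
                 cutoffs = list(perox = cut_p, dna = cut_d),
                 cytotox = tox, hits = build_heatmap_table(cat_ok)),
            class = "screen_result")
}

## leave-one-out standardized control wells: a control-derived null reference
control_reference_folds <- function(well_summaries) {
  ws <- as.data.table(well_summaries)[role == "control" & cell_count > 0]
  ws[, .(std_peroxisome = mean_spot_total_intensity /
           mean(mean_spot_total_intensity),
         std_dna = mean_integrated_dna / mean(mean_integrated_dna)),
     by = replicate]
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(x$compounds$category)
  cat("screen_result:", nrow(x$compounds), "compounds |",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  perox band [%.3f, %.3f], dna band [%.3f, %.3f]\n",
              x$cutoffs$perox$low, x$cutoffs$perox$high,
              x$cutoffs$dna$low, x$cutoffs$dna$high))
  invisible(x)
}
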
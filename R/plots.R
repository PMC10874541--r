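## Base-graphics views of the main readouts.

#' Categorized compound scatter (peroxisome vs DNA axes)
#'
#' Standardized peroxisome signal against standardized DNA signal, one point
#' per compound, with the 5/95 percentile cutoff lines.
#'
#' @param result A `screen_result` from [analyze_screen()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted table.
#' @export
plot_screen <- function(result, ...) {
  stopifnot(inherits(result, "screen_result"))
  cp <- result$compounds[result$compounds$category != "excluded", ]
  cols <- c(A = "#D55E00", B = "#0072B2", C = "#009E73", none = "grey60")
  graphics::plot(cp$std_dna, cp$std_peroxisome, pch = 16, cex = 0.6,
                 col = cols[cp$category],
                 xlab = "standardized DNA signal (fold of control)",
                 ylab = "standardized peroxisomal signal (fold of control)",
                 ...)
  graphics::abline(v = c(result$cutoffs$dna$low, result$cutoffs$dna$high),
                   h = c(result$cutoffs$perox$low, result$cutoffs$perox$high),
                   lty = 2, col = "grey40")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(cp)
}

#' Per-phase peroxisome profile bars
#'
#' @param profile Named numeric from [phase_peroxisome_profile()] or
#'   [flow_phase_peroxisome()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_phase_profile <- function(profile, ...) {
  graphics::barplot(profile, ylab = "peroxisomal signal (fold of G1)",
                    xlab = "cell cycle phase", col = "grey75", ...)
}

#' DNA-content histogram with fitted gates
#'
#' @param values Integrated DNA intensities.
#' @param gates Optional `phase_gates` to draw as vertical lines.
#' @param breaks Histogram breaks.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot_dna_histogram <- function(values, gates = NULL, breaks = 100, ...) {
  h <- graphics::hist(values, breaks = breaks, main = "",
                      xlab = "integrated DNA signal", ...)
  if (!is.null(gates))
    graphics::abline(v = c(gates$g1_upper, gates$s_upper), lty = 2,
                     col = "#D55E00")
  invisible(h)
}

#' Per-cell peroxisome intensity vs DNA signal scatter
#'
#' @param records Per-cell records (`integrated_dna`,
#'   `spot_total_intensity`, optionally `phase`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `NULL`.
#' @export
plot_cell_scatter <- function(records, ...) {
  cols <- c(G1 = "#0072B2", S = "#009E73", G2M = "#D55E00",
            unassigned = "grey60")
  ph <- if ("phase" %in% names(records)) records$phase else "unassigned"
  graphics::plot(records$integrated_dna, records$spot_total_intensity,
                 pch = 16, cex = 0.4, col = cols[ph],
                 xlab = "integrated DNA signal",
                 ylab = "peroxisomal spot total intensity", ...)
  invisible(NULL)
}
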
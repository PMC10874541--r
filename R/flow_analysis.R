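## Flow-cytometry-style event analyses: viability gating, ROS fold-change,
## per-phase peroxisome profiles, and condition comparison statistics.

#' Fraction of PI-positive (dead) events
#'
#' With a numeric `threshold`, the fraction of events whose PI intensity
#' exceeds it. With `threshold = "auto"`, the threshold is the density valley
#' between the two modes of the log-intensity distribution; if the data are
#' unimodal, the 99.5th percentile of `unstained_control` is used instead
#' (error when neither is available).
#'
#' @param events Event table with a `pi` column.
#' @param threshold Numeric, or `"auto"`.
#' @param unstained_control Optional numeric PI intensities of an unstained
#'   (all-live) control, for the auto fallback.
#' @return The PI+ fraction in `[0, 1]`, with the threshold used as
#'   attribute `"threshold"`.
#' @export
gate_pi_positive <- function(events, threshold = "auto",
                             unstained_control = NULL) {
  if (!"pi" %in% names(events)) stop("no 'pi' column", call. = FALSE)
  x <- events$pi
  if (identical(threshold, "auto")) {
    thr <- pi_valley_threshold(x)
    if (is.na(thr)) {
      if (is.null(unstained_control))
        stop("unimodal PI distribution and no unstained control for auto threshold",
             call. = FALSE)
      thr <- quantile(unstained_control, 0.995, names = FALSE)
    }
  } else thr <- threshold
  structure(mean(x > thr), threshold = thr)
}

## valley between the two strongest modes of the log-density; NA if unimodal
pi_valley_threshold <- function(x) {
  lx <- log(pmax(x, .Machine$double.eps))
  d <- density(lx, bw = "nrd0", n = 1024)
  y <- d$y
  modes <- which(diff(sign(diff(y))) == -2) + 1L
  modes <- modes[y[modes] > 0.05 * max(y)]  # ignore negligible bumps
  if (length(modes) < 2) return(NA_real_)
  modes <- modes[order(y[modes], decreasing = TRUE)][1:2]
  lo <- min(modes); hi <- max(modes)
  exp(d$x[lo + which.min(y[lo:hi]) - 1L])
}

#' Relative ROS level (fold of control)
#'
#' Ratio of the median DCFDA intensities of treated and control events —
#' median-based for robustness and invariance to a shared instrument gain.
#'
#' @param treated_events,control_events Event tables with a `dcfda` column.
#' @param summary `"median"` (default) or `"mean"`.
#' @return The fold-change as a single number.
#' @export
quantify_ros_shift <- function(treated_events, control_events,
                               summary = c("median", "mean")) {
  summary <- match.arg(summary)
  for (e in list(treated_events, control_events))
    if (!"dcfda" %in% names(e)) stop("no 'dcfda' column", call. = FALSE)
  f <- if (summary == "median") median else mean
  den <- f(control_events$dcfda)
  if (den == 0) stop("zero control DCFDA summary", call. = FALSE)
  f(treated_events$dcfda) / den
}

#' Per-phase peroxisome profile from flow events
#'
#' Fits DNA-content gates on the `dna` column (same procedure as the imaging
#' path, [fit_dna_gates()]), assigns phases, and returns per-phase mean
#' peroxisome intensity normalized to the G1 population.
#'
#' @param events Event table with `dna` and `peroxisome` columns.
#' @param ... Passed to [fit_dna_gates()].
#' @return Named numeric `c(G1, S, G2M)`, G1 entry exactly 1.
#' @export
flow_phase_peroxisome <- function(events, ...) {
  if (!all(c("dna", "peroxisome") %in% names(events)))
    stop("need 'dna' and 'peroxisome' columns", call. = FALSE)
  gates <- fit_dna_gates(events$dna, ...)
  rec <- data.table(integrated_dna = events$dna,
                    spot_total_intensity = events$peroxisome)
  rec <- assign_phase(rec, gates)
  phase_peroxisome_profile(rec)
}

#' Compare measurement groups (t test / one-way ANOVA with Tukey)
#'
#' Two groups: unpaired Student's t test (equal variances). More than two:
#' one-way analysis of variance with Tukey's honest-significant-difference
#' post hoc pairwise comparisons. Results are reported as mean +/- SD per
#' group; significance level 0.05.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return An object of class `comparison_result`: `summary` (group, n,
#'   mean, sd), `test` (`"t_test"` or `"anova_tukey"`), `statistic`,
#'   `p_value`, and `pairwise` (Tukey table, `NULL` for two groups).
#' @export
compare_conditions <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  smry <- data.table(group = names(groups), n = n,
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, sd, numeric(1)))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), n), levels = names(groups))
  if (all(vapply(groups, function(g) var(g) == 0, logical(1))) &&
      length(unique(smry$mean)) == 1) {
    # identical degenerate groups: no evidence of difference
    return(structure(list(summary = smry,
                          test = if (length(groups) == 2) "t_test" else "anova_tukey",
                          statistic = 0, p_value = 1, pairwise = NULL),
                     class = "comparison_result"))
  }
  if (length(groups) == 2) {
    tt <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    res <- list(summary = smry, test = "t_test",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                pairwise = NULL)
  } else {
    fit <- aov(vals ~ fac)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$fac
    pw <- data.table(contrast = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"])
    res <- list(summary = smry, test = "anova_tukey",
                statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                pairwise = pw)
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  if (!is.null(x$pairwise)) {
    sig <- x$pairwise[x$pairwise$p_adj < 0.05, ]
    cat("  Tukey p<0.05:", if (nrow(sig)) paste(sig$contrast, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}

#' Pairwise Tukey p-value lookup
#' @param cmp A `comparison_result` from a >2-group comparison.
#' @param a,b Group names.
#' @return Adjusted p-value of the `a` vs `b` contrast.
#' @export
tukey_p <- function(cmp, a, b) {
  stopifnot(inherits(cmp, "comparison_result"), !is.null(cmp$pairwise))
  hit <- cmp$pairwise$contrast %in% c(paste0(a, "-", b), paste0(b, "-", a))
  if (!any(hit)) stop("no such contrast", call. = FALSE)
  cmp$pairwise$p_adj[hit][1]
}

#' Combination (synergy) analysis of death fractions
#'
#' Runs [compare_conditions()] across a combination design and extracts the
#' contrasts of interest: combination vs inducer alone, combination vs
#' chemical alone, and combination + inhibitor (rescue) vs control.
#'
#' @param death_fractions Named list of replicate death-fraction vectors;
#'   names must include `control`, `inducer`, `chemical`, `combination`,
#'   `combination_inhibitor`.
#' @return A list of class `synergy_report`: `comparison` (the full
#'   ANOVA+Tukey result) and `contrasts` (`data.table` with `contrast`,
#'   `p_adj`, `significant`).
#' @export
synergy_report <- function(death_fractions) {
  required <- c("control", "inducer", "chemical", "combination",
                "combination_inhibitor")
  missing <- setdiff(required, names(death_fractions))
  if (length(missing))
    stop("missing condition(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cmp <- compare_conditions(death_fractions)
  want <- list(c("combination", "inducer"), c("combination", "chemical"),
               c("combination_inhibitor", "control"))
  contrasts <- rbindlist(lapply(want, function(w)
    data.table(contrast = paste(w, collapse = " vs "),
               p_adj = tukey_p(cmp, w[1], w[2]))))
  contrasts[, significant := p_adj < 0.05]
  structure(list(comparison = cmp, contrasts = contrasts),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  print(x$comparison)
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("  %s: p_adj = %.4g %s\n", x$contrasts$contrast[i],
                x$contrasts$p_adj[i],
                if (x$contrasts$significant[i]) "*" else ""))
  invisible(x)
}
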
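#' Per-window change in ensemble diversity between two temperatures
#'
#' Aligns two scans of the same sequence (same window geometry) and
#' reports, for every window, the ensemble diversity at each temperature
#' and their difference. The sign convention is fixed as
#' `delta_ed = ED(higher T) - ED(lower T)`: positive values mean the
#' window samples a larger ensemble of structures when heated, the
#' signature of a melting (thermometer-like) element; negative values mean
#' the ensemble concentrates on heating.
#'
#' The difference is taken by argument position (second minus first), so
#' passing the scans in reverse order negates every record.
#'
#' Windows flagged `short` are excluded; the number excluded is recorded
#' in the `n_excluded` attribute.
#'
#' @param scan_low,scan_high `rna_scan` objects at the lower and higher
#'   temperature.
#' @return data frame of class `delta_ed` with columns `window_start`,
#'   `ed_low`, `ed_high`, `delta_ed`; attributes `gene_id`,
#'   `temperature_low`, `temperature_high`, `n_excluded`.
#' @export
delta_ed <- function(scan_low, scan_high) {
  stopifnot(inherits(scan_low, "rna_scan"), inherits(scan_high, "rna_scan"))
  a <- scan_low$windows; b <- scan_high$windows
  if (nrow(a) != nrow(b) || any(a$start != b$start)) {
    mism <- if (nrow(a) != nrow(b)) min(nrow(a), nrow(b)) + 1L
            else which(a$start != b$start)[1L]
    stop(sprintf(
      "window sets differ between the two scans (first mismatch at window %d%s)",
      mism,
      if (mism <= min(nrow(a), nrow(b)))
        sprintf(": start %d vs %d", a$start[mism], b$start[mism]) else ""))
  }
  keep <- !a$short
  out <- data.frame(window_start = a$start[keep],
                    ed_low = a$ensemble_diversity[keep],
                    ed_high = b$ensemble_diversity[keep],
                    delta_ed = b$ensemble_diversity[keep] -
                               a$ensemble_diversity[keep])
  attr(out, "gene_id") <- scan_low$gene_id
  attr(out, "temperature_low") <- scan_low$config$temperature
  attr(out, "temperature_high") <- scan_high$config$temperature
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("delta_ed", "data.frame")
  out
}

#' Per-gene delta-ED summary
#'
#' @param gene_id gene identifier.
#' @param records a `delta_ed` data frame (or any data frame with
#'   `window_start` and `delta_ed`).
#' @return list of class `gene_thermo_summary`: `gene_id`, `n_windows`,
#'   `mean_delta_ed`, `sd_delta_ed` (`NA` and flagged for a single
#'   window), `max_window` and `min_window` (each `c(start, value)`).
#' @export
gene_summary <- function(gene_id, records) {
  if (!NROW(records)) stop("no delta-ED records for gene ", gene_id)
  d <- records$delta_ed
  i_max <- which.max(d); i_min <- which.min(d)
  structure(list(
    gene_id = gene_id, n_windows = length(d),
    mean_delta_ed = mean(d),
    sd_delta_ed = if (length(d) > 1L) stats::sd(d) else NA_real_,
    sd_undefined = length(d) < 2L,
    max_window = c(start = records$window_start[i_max], value = d[i_max]),
    min_window = c(start = records$window_start[i_min], value = d[i_min]),
    n_excluded = attr(records, "n_excluded") %||% 0L),
    class = "gene_thermo_summary")
}

#' Cohort-level delta-ED statistics
#'
#' Mean, sample standard deviation, median and quartiles (linear
#' interpolation, `stats::quantile` type 7) of the per-gene mean delta-ED
#' values across a cohort.
#'
#' @param summaries list of `gene_thermo_summary` objects.
#' @return list of class `population_stats`: `n_genes`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `gene_means` (named vector).
#' @export
population_stats <- function(summaries) {
  if (length(summaries) < 2L)
    stop("population statistics require at least 2 genes")
  means <- vapply(summaries, function(s) s$mean_delta_ed, numeric(1))
  names(means) <- vapply(summaries, function(s) s$gene_id, character(1))
  q <- stats::quantile(means, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(n_genes = length(means), mean = mean(means),
                 sd = stats::sd(means), median = q[2], q1 = q[1], q3 = q[3],
                 quartile_method = "linear interpolation (type 7)",
                 gene_means = means),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(
    "<population_stats> %d genes: mean %.3f (sd %.3f), median %.3f, Q1 %.3f, Q3 %.3f\n",
    x$n_genes, x$mean, x$sd, x$median, x$q1, x$q3))
  invisible(x)
}

#' Standard score of a gene against a cohort
#'
#' The gene's mean delta-ED expressed in population standard deviations
#' from the cohort mean.
#'
#' @param gene a `gene_thermo_summary`.
#' @param pop a `population_stats`.
#' @return unitless standard score.
#' @export
standard_score <- function(gene, pop) {
  if (!is.finite(pop$sd) || pop$sd <= 0)
    stop("population sd is zero or undefined; standard score not computable")
  (gene$mean_delta_ed - pop$mean) / pop$sd
}

#' One-sample t-test of a gene family against a reference mean
#'
#' Tests whether a family's per-gene mean delta-ED values differ from a
#' reference mean (typically the transcriptome-wide cohort mean). Two
#' sided, n - 1 degrees of freedom.
#'
#' @param family_means numeric vector of per-gene mean delta-ED values
#'   (n >= 2, non-constant).
#' @param reference_mean the null-hypothesis mean.
#' @return list of class `thermo_ttest`: `n`, `family_mean`,
#'   `standard_error`, `t_statistic`, `degrees_freedom`, `p_value`,
#'   `reference_mean`.
#' @export
one_sample_t_test <- function(family_means, reference_mean) {
  n <- length(family_means)
  if (n < 2L) stop("one-sample t-test requires n >= 2 family members")
  if (stats::sd(family_means) == 0)
    stop("one-sample t-test undefined for a constant family")
  tt <- stats::t.test(family_means, mu = reference_mean)
  structure(list(n = n,
                 family_mean = mean(family_means),
                 standard_error = stats::sd(family_means) / sqrt(n),
                 t_statistic = unname(tt$statistic),
                 degrees_freedom = n - 1L,
                 p_value = tt$p.value,
                 reference_mean = reference_mean),
            class = "thermo_ttest")
}

#' @export
print.thermo_ttest <- function(x, ...) {
  cat(sprintf(
    "One-sample t-test: n = %d, family mean %.4f vs reference %.4f\n",
    x$n, x$family_mean, x$reference_mean))
  cat(sprintf("  SE %.4f, t = %.4f (df %d), two-sided p = %.4f\n",
              x$standard_error, x$t_statistic, x$degrees_freedom,
              x$p_value))
  invisible(x)
}

#' Extreme delta-ED windows
#'
#' Selects the k windows with the largest positive, most negative, or
#' largest-magnitude changes in ensemble diversity -- the candidate
#' temperature-switch regions. Ties are returned in ascending coordinate
#' order.
#'
#' @param records a `delta_ed` data frame.
#' @param k number of windows (clipped to the record count).
#' @param mode one of `"positive"`, `"negative"`, `"absolute"`.
#' @return the selected rows of `records`, ranked.
#' @export
top_delta_windows <- function(records, k = 5L,
                              mode = c("absolute", "positive", "negative")) {
  mode <- match.arg(mode)
  if (!NROW(records)) stop("no delta-ED records")
  key <- switch(mode, positive = -records$delta_ed,
                negative = records$delta_ed,
                absolute = -abs(records$delta_ed))
  ord <- order(key, records$window_start)
  records[head(ord, min(k, NROW(records))), , drop = FALSE]
}

#' Centroid structure shift between two temperatures
#'
#' Compares the centroid structures of the same window folded at two
#' temperatures: the base-pair distance between them and the pairs unique
#' to each side. `lost` pairs are present at the lower temperature only
#' (structure melted on heating); `gained` pairs appear only at the higher
#' temperature.
#'
#' @param scan_low,scan_high `rna_scan` objects of the same sequence.
#' @param window_start 0-based start of the window to compare.
#' @return list of class `centroid_shift`: `window_start`, `distance`,
#'   `gained`, `lost` (pair tables in window-local coordinates),
#'   `centroid_low`, `centroid_high`.
#' @export
centroid_shift <- function(scan_low, scan_high, window_start) {
  a <- scan_low$windows[scan_low$windows$start == window_start, ]
  b <- scan_high$windows[scan_high$windows$start == window_start, ]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop(sprintf("window starting at %d not present in both scans",
                 window_start))
  pl <- dbn_to_pairs(a$centroid_dbn)
  ph <- dbn_to_pairs(b$centroid_dbn)
  kl <- paste(pl[, 1L], pl[, 2L]); kh <- paste(ph[, 1L], ph[, 2L])
  structure(list(
    window_start = window_start,
    distance = base_pair_distance(pl, ph),
    gained = as_pair_table(ph[!(kh %in% kl), , drop = FALSE]),
    lost = as_pair_table(pl[!(kl %in% kh), , drop = FALSE]),
    centroid_low = a$centroid_dbn, centroid_high = b$centroid_dbn),
    class = "centroid_shift")
}

#' @export
print.centroid_shift <- function(x, ...) {
  cat(sprintf(
    "<centroid_shift> window %d: distance %d (%d lost, %d gained on heating)\n",
    x$window_start, x$distance, nrow(x$lost), nrow(x$gained)))
  cat("  low T:  ", x$centroid_low, "\n  high T: ", x$centroid_high, "\n",
      sep = "")
  invisible(x)
}
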
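#' WBC size threshold from the upper tail
#'
#' The size threshold separating WBC-sized from larger events is the
#' empirical quantile above which only `tail` of the WBC population lies
#' (default 0.1%, i.e. the 99.9% quantile, 13.9 um on the reference
#' healthy-donor population). Linear (type-7) interpolation is used and
#' recorded in the result's attributes.
#'
#' @param wbc_diameters numeric vector of WBC diameters, um.
#' @param tail upper-tail fraction (default 0.001).
#' @return threshold in um, with attributes `tail` and `quantile_type`.
#' @export
wbc_size_threshold <- function(wbc_diameters, tail = 0.001) {
  if (!length(wbc_diameters)) .stopf("empty diameter vector")
  if (tail <= 0 || tail >= 1) .stopf("tail must be in (0, 1)")
  if (length(wbc_diameters) < 1 / tail)
    .warnf("fewer than %g observations: the %g quantile is poorly resolved",
           1 / tail, 1 - tail)
  q <- unname(stats::quantile(wbc_diameters, 1 - tail, type = 7))
  structure(q, tail = tail, quantile_type = 7L)
}

#' CellSearch-equivalent EpCAM threshold for one cell line
#'
#' Given a cell line's expression distribution and its published recovery
#' yield on an EpCAM positive-selection platform, the equivalent threshold
#' is the expression value above which exactly that fraction of cells
#' lies, i.e. the `(1 - yield)` empirical quantile (type 7).
#'
#' @param cell_line_expressions numeric vector of expressions, a.u.
#' @param recovery_yield published recovery yield, in (0, 1).
#' @return threshold in a.u.
#' @export
equivalent_epcam_threshold <- function(cell_line_expressions,
                                       recovery_yield) {
  if (length(cell_line_expressions) < 10)
    .stopf("need at least 10 observations to place a yield quantile")
  if (recovery_yield <= 0 || recovery_yield >= 1)
    .stopf("recovery_yield must be in (0, 1)")
  unname(stats::quantile(cell_line_expressions, 1 - recovery_yield,
                         type = 7))
}

#' Consensus threshold across cell lines
#'
#' Median of the per-cell-line equivalent thresholds; order-invariant.
#' Interval-valued entries (a yield range mapping to a threshold range)
#' must be collapsed to a single endpoint by the caller first — the
#' conservative convention is the lower endpoint.
#'
#' @param per_line_thresholds numeric vector, one entry per cell line.
#' @return the median threshold, a.u.
#' @export
consensus_threshold <- function(per_line_thresholds) {
  if (!length(per_line_thresholds)) .stopf("no thresholds supplied")
  stats::median(per_line_thresholds)
}

#' Percentage of values strictly below a threshold
#'
#' @param values numeric vector (non-empty).
#' @param threshold cut value (same units as `values`).
#' @return percentage in `[0, 100]` (full precision; report at one
#'   decimal).
#' @export
fraction_below <- function(values, threshold) {
  if (!length(values)) .stopf("empty input")
  100 * mean(values < threshold)
}

#' Size-by-expression quadrant percentages
#'
#' Partitions events into four quadrants using strict-below versus
#' at-or-above on each axis, so ties at a threshold land in the upper
#' group and totals are conserved.
#'
#' @param size numeric vector of diameters, um.
#' @param expression numeric vector of expressions, a.u. (same length).
#' @param size_threshold size cut, um (e.g. 13.9).
#' @param expression_threshold expression cut, a.u. (e.g. 147).
#' @return named numeric vector of percentages
#'   (`small_low`, `small_high`, `large_low`, `large_high`) summing to
#'   100 up to rounding.
#' @export
quadrant_percentages <- function(size, expression, size_threshold,
                                 expression_threshold) {
  if (!length(size)) .stopf("empty input")
  if (length(size) != length(expression))
    .stopf("size and expression must have equal length")
  small <- size < size_threshold
  low <- expression < expression_threshold
  n <- length(size)
  100 * c(small_low = sum(small & low), small_high = sum(small & !low),
          large_low = sum(!small & low), large_high = sum(!small & !low)) / n
}

#' Expected yield of a threshold-based technology
#'
#' For a single-parameter isolation technology (pure size cut or pure
#' expression cut), the expected yield at threshold `t` is the fraction of
#' the observed CTC population at or above `t` — one minus the empirical
#' CDF, evaluated on a threshold grid.
#'
#' @param ctc_values numeric vector of the CTC measurements.
#' @param thresholds non-decreasing numeric grid.
#' @return data.frame with columns `threshold` and `yield` (non-increasing
#'   in `threshold`).
#' @export
expected_yield_curve <- function(ctc_values, thresholds) {
  if (!length(ctc_values)) .stopf("empty input")
  if (is.unsorted(thresholds)) .stopf("threshold grid must be non-decreasing")
  yield <- vapply(thresholds, function(t) mean(ctc_values >= t), numeric(1))
  data.frame(threshold = thresholds, yield = yield)
}

#' Two-sample rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: the exact null
#' distribution is enumerated when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `statistic` (the Mann-Whitney U for `a`), `p.value`
#'   and `exact` (logical).
#' @export
compare_distributions <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = min(ht$p.value, 1),
       exact = exact)
}

#' Relative yield of spiked cells
#'
#' Spiked cells found in the product divided by the total found in the
#' product plus the magnetic-sorting wastes (the streams where an
#' erroneously deflected spiked cell can end up).
#'
#' @param product_count spiked-cell count in the product.
#' @param macs_waste_counts numeric vector of spiked-cell counts in the
#'   MACS waste stream(s).
#' @return yield fraction in `[0, 1]`.
#' @export
relative_yield <- function(product_count, macs_waste_counts) {
  if (product_count < 0 || any(macs_waste_counts < 0))
    .stopf("counts must be >= 0")
  total <- product_count + sum(macs_waste_counts)
  if (total <= 0) .stopf("no spiked cells found in any stream")
  product_count / total
}

#' WBC carryover per mL of input blood
#'
#' @param product_wbc_count residual WBC count in the product.
#' @param blood_volume_ml input blood volume, mL (> 0).
#' @return carryover, WBC per mL.
#' @export
wbc_carryover <- function(product_wbc_count, blood_volume_ml) {
  if (blood_volume_ml <= 0) .stopf("blood volume must be > 0")
  if (product_wbc_count < 0) .stopf("count must be >= 0")
  product_wbc_count / blood_volume_ml
}

#' Spiked-cell concentration from chamber counts
#'
#' Cells are counted across four haemocytometer chambers; the plain mean
#' of the four counts, divided by the effective chamber volume and scaled
#' by the dilution factor, gives the spike concentration.
#'
#' @param chamber_counts exactly four non-negative counts.
#' @param chamber_volume effective chamber volume (same volume unit as the
#'   desired concentration denominator).
#' @param dilution_factor dilution applied before counting (default 1).
#' @return concentration, cells per volume unit.
#' @export
spike_concentration <- function(chamber_counts, chamber_volume,
                                dilution_factor = 1) {
  if (length(chamber_counts) != 4L)
    .stopf("expected exactly 4 chamber counts, got %d",
           length(chamber_counts))
  if (any(chamber_counts < 0)) .stopf("counts must be >= 0")
  if (chamber_volume <= 0) .stopf("chamber volume must be > 0")
  mean(chamber_counts) / chamber_volume * dilution_factor
}

#' Reagent and concentration accounting for a run
#'
#' Labeling reagents scale with input blood volume: 180 uL of antibody
#' cocktail and 1.2 mg of streptavidin magnetic beads per mL of blood.
#' The product is concentrated before imaging; the concentration factor
#' is the product volume over the concentrated volume (50x for a typical
#' 5.5 mL product reduced to 110 uL).
#'
#' @param blood_volume_ml input blood volume, mL.
#' @param product_volume_ml product volume before concentration, mL.
#' @param concentrated_volume_ml volume after concentration, mL.
#' @return list with `cocktail_ul`, `beads_mg`, `concentration_factor`.
#' @export
run_accounting <- function(blood_volume_ml, product_volume_ml,
                           concentrated_volume_ml) {
  if (blood_volume_ml <= 0 || product_volume_ml <= 0 ||
      concentrated_volume_ml <= 0)
    .stopf("all volumes must be > 0")
  list(cocktail_ul = 180 * blood_volume_ml,
       beads_mg = 1.2 * blood_volume_ml,
       concentration_factor = product_volume_ml / concentrated_volume_ml)
}
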
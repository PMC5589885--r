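#' Fluorescence and size calibration model
#'
#' Holds the MESF conversion slope and the intensity-dependent size-bias
#' curve. One arbitrary unit of mean membrane expression corresponds to
#' approximately 520 MESF (molecules of equivalent soluble fluorochrome)
#' for the R-PE/EpCAM channel. Fluorescence-based sizing overestimates true
#' size; the overestimation is about 16% for bright calibration beads,
#' diminishes with decreasing intensity, and is capped at 20%.
#'
#' The default bias curve is a saturating form `cap * I / (I + K)` through
#' (0, 0) with value `bias_bright` at `bright_intensity`, capped at `cap`.
#' A user-supplied two-column table (`intensity`, `bias_fraction`) replaces
#' it with monotone linear interpolation.
#'
#' @param mesf_per_au MESF per a.u. (default 520).
#' @param bias_bright bias fraction at `bright_intensity` (default 0.16).
#' @param bright_intensity bright-bead intensity anchor, a.u.
#' @param cap asymptotic bias cap (default 0.20).
#' @param table optional data.frame with columns `intensity` and
#'   `bias_fraction` (non-decreasing, within `[0, cap]`).
#' @return a `calibration_model`.
#' @export
#' @examples
#' m <- calibration_model()
#' au_to_mesf(147, m)   # CellSearch-equivalent threshold in MESF
calibration_model <- function(mesf_per_au = 520, bias_bright = 0.16,
                              bright_intensity = 1000, cap = 0.20,
                              table = NULL) {
  if (mesf_per_au <= 0) .stopf("mesf_per_au must be > 0")
  if (bias_bright < 0 || bias_bright > cap || cap > 0.20 + 1e-12)
    .stopf("bias fractions must lie in [0, 0.20]")
  bias_fun <- if (!is.null(table)) {
    stopifnot(all(c("intensity", "bias_fraction") %in% names(table)))
    tb <- table[order(table$intensity), ]
    if (any(diff(tb$bias_fraction) < 0))
      .stopf("bias table must be non-decreasing in intensity")
    if (any(tb$bias_fraction < 0 | tb$bias_fraction > cap))
      .stopf("bias fractions must lie in [0, %.2f]", cap)
    f <- stats::approxfun(tb$intensity, tb$bias_fraction, rule = 2)
    function(i) f(pmax(i, 0))
  } else {
    K <- bright_intensity * (cap - bias_bright) / bias_bright
    function(i) {
      i <- pmax(i, 0)
      cap * i / (i + K)
    }
  }
  structure(list(mesf_per_au = mesf_per_au, bias = bias_fun, cap = cap),
            class = "calibration_model")
}

#' Convert arbitrary units to MESF
#'
#' Linear conversion `value * mesf_per_au`. Applies to the calibrated
#' fluorochrome channel (R-PE/EpCAM by default); other channels lack a
#' bead-anchored slope and should not be converted.
#'
#' @param value expression in a.u. (>= 0).
#' @param model a [calibration_model()].
#' @return expression in MESF.
#' @export
au_to_mesf <- function(value, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(value < 0)) .stopf("expression values must be >= 0")
  value * model$mesf_per_au
}

#' Correct the intensity-dependent size overestimation
#'
#' Divides the measured diameter by `1 + bias(intensity)`, where the bias
#' fraction is the calibration model's monotone curve (zero at zero
#' intensity, capped at 20%). A fixed bias fraction can be supplied
#' directly, e.g. 0.16 for bright-bead conditions. Reported measurements
#' are conventionally left uncorrected; this correction is opt-in.
#'
#' @param measured measured diameter, um (> 0).
#' @param intensity segmentation-channel intensity, a.u.
#' @param model a [calibration_model()].
#' @param bias_fraction optional fixed bias fraction overriding the curve.
#' @return corrected diameter, um (always <= `measured`).
#' @export
correct_size_bias <- function(measured, intensity = NULL,
                              model = calibration_model(),
                              bias_fraction = NULL) {
  if (any(measured <= 0)) .stopf("measured diameter must be > 0")
  b <- if (!is.null(bias_fraction)) bias_fraction
  else {
    if (is.null(intensity)) .stopf("supply intensity or bias_fraction")
    model$bias(intensity)
  }
  if (any(b < 0 | b > model$cap + 1e-12))
    .stopf("bias fraction out of range [0, %.2f]", model$cap)
  measured / (1 + b)
}
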
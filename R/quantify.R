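#' Segment a cell from one channel of a single-cell image
#'
#' Thresholds the chosen channel to remove background, keeps the largest
#' above-threshold connected component (8-neighbour connectivity), and
#' fills its interior so that the mask is the area enclosed by the cell
#' perimeter. The segmentation channel should be the most uniform surface
#' stain for the cell type (CD45/CD16 for WBCs, EpCAM for epithelial CTCs,
#' CD146 for melanoma CTCs); for nucleus-only events the nuclear channel
#' can be used.
#'
#' @param image a `cell_image`.
#' @param marker channel to segment on.
#' @param policy threshold policy: `"otsu"` (default), `"fixed"` (use
#'   `value`), or `"kbg"` (background median + `k` x background MAD).
#' @param value fixed threshold (a.u.) for `policy = "fixed"`.
#' @param k multiplier for `policy = "kbg"` (default 3).
#' @return a `mask_set`: list with `object_mask` (logical matrix, one
#'   filled connected component), `membrane_mask` (`NULL` until
#'   [membrane_mask()] is applied) and `threshold_used`.
#' @export
segment_cell <- function(image, marker, policy = c("otsu", "fixed", "kbg"),
                         value = NULL, k = 3) {
  stopifnot(inherits(image, "cell_image"))
  policy <- match.arg(policy)
  ch <- image$channels[[marker]]
  if (is.null(ch)) .stopf("channel '%s' not present in image", marker)
  if (all(ch == 0)) .stopf("empty object: channel '%s' is all zero", marker)

  thr <- switch(policy,
    otsu = {
      mx <- max(ch)
      EBImage::otsu(EBImage::Image(ch / mx), range = c(0, 1)) * mx
    },
    fixed = {
      if (is.null(value)) .stopf("policy 'fixed' requires a threshold value")
      value
    },
    kbg = stats::median(ch) + k * stats::mad(ch))

  fg <- ch > thr
  if (!any(fg)) .stopf("empty object: no pixel above threshold %.3g", thr)

  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  obj <- EBImage::fillHull(matrix(as.numeric(lab == keep),
                                  nrow(fg), ncol(fg))) > 0
  structure(list(object_mask = obj, membrane_mask = NULL,
                 threshold_used = thr),
            class = "mask_set")
}

#' Equivalent circular diameter of a segmented object
#'
#' The pixel area enclosed by the cell perimeter is converted to the
#' diameter of the circle of equal area: `2 * scale * sqrt(A / pi)`.
#'
#' @param mask a `mask_set` or a logical matrix.
#' @param pixel_scale microns per pixel.
#' @return diameter in microns.
#' @export
equivalent_diameter <- function(mask, pixel_scale) {
  if (inherits(mask, "mask_set")) mask <- mask$object_mask
  if (pixel_scale <= 0) .stopf("pixel_scale must be > 0")
  a <- sum(mask)
  if (a == 0) .stopf("empty mask")
  2 * pixel_scale * sqrt(a / pi)
}

#' Membrane (annulus) mask from an object mask
#'
#' The membrane mask is the object mask dilated by `dilate_px` pixels minus
#' the object mask eroded by `erode_px` pixels (disk structuring elements),
#' yielding an annulus roughly `dilate_px + erode_px` pixels across that
#' straddles the cell boundary. For objects whose inradius is below the
#' erosion depth the erosion vanishes and the ring equals the dilated mask.
#'
#' @param object_mask logical matrix (or a `mask_set`).
#' @param dilate_px outward extent in pixels (default 3).
#' @param erode_px inward extent in pixels (default 7).
#' @return if given a `mask_set`, the same object with `membrane_mask`
#'   filled in; otherwise the logical ring matrix.
#' @export
membrane_mask <- function(object_mask, dilate_px = 3L, erode_px = 7L) {
  ms <- NULL
  if (inherits(object_mask, "mask_set")) {
    ms <- object_mask
    object_mask <- ms$object_mask
  }
  if (!any(object_mask)) .stopf("empty object mask")
  num <- matrix(as.numeric(object_mask),
                nrow(object_mask), ncol(object_mask))
  dil <- EBImage::dilate(num, EBImage::makeBrush(2L * dilate_px + 1L,
                                                 shape = "disc")) > 0
  ero <- EBImage::erode(num, EBImage::makeBrush(2L * erode_px + 1L,
                                                shape = "disc")) > 0
  ring <- dil & !ero
  if (is.null(ms)) return(ring)
  ms$membrane_mask <- ring
  ms
}

#' Mean membrane expression of a marker
#'
#' Arithmetic mean of the marker channel over the membrane-mask pixels;
#' this is the reported membrane expression value in arbitrary units.
#'
#' @param image a `cell_image`.
#' @param marker channel name.
#' @param ring logical ring matrix or a `mask_set` with `membrane_mask`.
#' @return mean intensity (a.u.).
#' @export
membrane_expression <- function(image, marker, ring) {
  stopifnot(inherits(image, "cell_image"))
  if (inherits(ring, "mask_set")) ring <- ring$membrane_mask
  ch <- image$channels[[marker]]
  if (is.null(ch)) .stopf("channel '%s' not present in image", marker)
  if (is.null(ring) || !any(ring)) .stopf("empty membrane mask")
  mean(ch[ring])
}

#' Normalise expression for day-to-day laser power
#'
#' Measured intensities scale linearly with excitation power, so values are
#' rescaled to a reference power: `raw * reference_power / day_power`.
#'
#' @param raw intensity (a.u.).
#' @param day_power laser power on the measurement day (mW).
#' @param reference_power reference laser power (mW).
#' @return rescaled intensity (a.u.).
#' @export
scale_by_laser_power <- function(raw, day_power, reference_power) {
  if (any(day_power <= 0) || any(reference_power <= 0))
    .stopf("laser powers must be > 0")
  raw * (reference_power / day_power)
}

#' Measure one cell image end to end
#'
#' Convenience wrapper: segments on the given channel, computes the
#' equivalent diameter, builds the membrane mask and measures the mean
#' membrane expression of every requested marker.
#'
#' @inheritParams segment_cell
#' @param markers markers to measure (default: all channels).
#' @param dilate_px,erode_px membrane-mask extents, pixels.
#' @return one-row data.frame: `event_id`, `diameter_um`, `threshold_used`,
#'   `border_touch` flag, and one expression column per marker.
#' @export
measure_cell <- function(image, marker, markers = names(image$channels),
                         policy = "otsu", value = NULL, k = 3,
                         dilate_px = 3L, erode_px = 7L) {
  ms <- segment_cell(image, marker, policy = policy, value = value, k = k)
  ms <- membrane_mask(ms, dilate_px = dilate_px, erode_px = erode_px)
  d <- equivalent_diameter(ms, image$pixel_scale)
  obj <- ms$object_mask
  border <- any(obj[1, ]) || any(obj[nrow(obj), ]) ||
    any(obj[, 1]) || any(obj[, ncol(obj)])
  expr <- vapply(markers, function(mk)
    membrane_expression(image, mk, ms), numeric(1))
  out <- data.frame(event_id = image$event_id, diameter_um = d,
                    threshold_used = ms$threshold_used,
                    border_touch = border, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(expr)))
}
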
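#' Disease-specific marker panel
#'
#' Defines the marker roles and positivity thresholds used for CTC
#' identification. All diseases share the nuclear requirement (DRAQ5) and
#' the leukocyte exclusion markers (CD45, CD66b, CD16); epithelial cancers
#' (breast, lung, prostate) require EpCAM positivity, melanoma requires
#' both CD146 and NG2.
#'
#' @param disease one of `"breast"`, `"lung"`, `"prostate"`, `"melanoma"`.
#' @param thresholds named numeric vector of positivity thresholds (a.u.),
#'   one per marker used by the rules (and any extra markers to be called).
#' @return a `marker_panel`.
#' @export
#' @examples
#' p <- marker_panel("breast",
#'   c(DRAQ5 = 20, CD45 = 30, CD66b = 30, CD16 = 30, EpCAM = 147))
marker_panel <- function(disease = c("breast", "lung", "prostate",
                                     "melanoma"),
                         thresholds) {
  disease <- match.arg(disease)
  nuclear <- "DRAQ5"
  exclusion <- c("CD45", "CD66b", "CD16")
  inclusion <- if (disease == "melanoma") c("CD146", "NG2") else "EpCAM"
  need <- c(nuclear, exclusion, inclusion)
  if (is.null(names(thresholds)) || !all(need %in% names(thresholds)))
    .stopf("thresholds must name all rule markers: %s",
           paste(need, collapse = ", "))
  if (any(thresholds < 0)) .stopf("thresholds must be >= 0")
  structure(list(disease = disease, thresholds = thresholds,
                 nuclear = nuclear, exclusion = exclusion,
                 inclusion = inclusion),
            class = "marker_panel")
}

#' Positivity thresholds from a negative-control population
#'
#' Default thresholding rule when no fixed cutoff is available: control
#' mean plus 3 robust standard deviations (MAD).
#'
#' @param control numeric vector of control-population expressions (a.u.).
#' @param k multiplier (default 3).
#' @return threshold (a.u.).
#' @export
threshold_from_controls <- function(control, k = 3) {
  if (!length(control)) .stopf("empty control population")
  mean(control) + k * stats::mad(control)
}

#' Call per-marker positivity for one event
#'
#' A marker is positive iff its expression strictly exceeds the panel
#' threshold (values exactly at the threshold are negative, which is
#' stable under zero-valued controls).
#'
#' @param event named numeric vector (or one-row data.frame) of marker
#'   expressions, a.u.
#' @param panel a [marker_panel()] (or a named threshold vector).
#' @return named logical vector of calls, one per panel threshold.
#' @export
call_positivity <- function(event, panel) {
  thr <- if (inherits(panel, "marker_panel")) panel$thresholds else panel
  if (is.data.frame(event)) event <- unlist(event[1, , drop = TRUE])
  missing <- setdiff(names(thr), names(event))
  if (length(missing))
    .stopf("event is missing marker(s): %s", paste(missing, collapse = ", "))
  vals <- as.numeric(event[names(thr)])
  stats::setNames(vals > thr, names(thr))
}

#' Identify a CTC from marker calls
#'
#' Breast/lung/prostate: nucleated (DRAQ5+), all exclusion markers
#' (CD45/CD66b/CD16) negative, and EpCAM positive. Melanoma: nucleated,
#' exclusions negative, and both CD146 and NG2 positive.
#'
#' @param calls named logical vector from [call_positivity()].
#' @param panel a [marker_panel()].
#' @return `TRUE` if the event is a CTC.
#' @export
call_ctc <- function(calls, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  need <- c(panel$nuclear, panel$exclusion, panel$inclusion)
  missing <- setdiff(need, names(calls))
  if (length(missing))
    .stopf("calls missing marker(s): %s", paste(missing, collapse = ", "))
  isTRUE(unname(calls[panel$nuclear])) &&
    !any(calls[panel$exclusion]) &&
    all(calls[panel$inclusion])
}

## Contaminant deconvolution signatures over the non-nuclear markers.
## Each class is defined by its full +/- pattern; the four patterns are
## mutually exclusive by construction.
.deconv_signatures <- function() {
  mk <- c("CD45", "CD16", "GlyA", "ConA", "CD41")
  sig <- rbind(
    leukocyte     = c(TRUE,  TRUE,  FALSE, FALSE, FALSE),
    erythroblast  = c(FALSE, FALSE, TRUE,  FALSE, FALSE),
    bare_nucleus  = c(FALSE, FALSE, FALSE, TRUE,  FALSE),
    megakaryocyte = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  colnames(sig) <- mk
  sig
}

#' Deconvolve one contaminant nucleated event
#'
#' Assigns the remaining (non-CTC) nucleated events of an enriched product
#' to one of four contaminant classes by their full marker signature:
#' leukocytes (DRAQ5+/CD45+/CD16+/GlyA-/ConA-/CD41-), erythroblasts
#' (DRAQ5+/GlyA+/CD45-/CD16-/ConA-/CD41-), bare nuclei
#' (DRAQ5+/ConA+/GlyA-/CD45-/CD16-/CD41-) and megakaryocytes
#' (DRAQ5+/CD41+/ConA-/GlyA-/CD45-/CD16-). Events matching no signature
#' are `"unclassified"`. Non-nucleated (DRAQ5-) events are outside the
#' assay's scope and raise an error.
#'
#' @param calls named logical vector with at least DRAQ5, CD45, CD16,
#'   GlyA, ConA, CD41.
#' @param satellite_platelets optional logical: `TRUE` marks punctate
#'   CD41 staining (satellite platelets on a nucleated event), which
#'   vetoes the megakaryocyte call; `NA`/`FALSE` (continuous membrane
#'   staining) leaves the CD41+ rule in force.
#' @return class label string.
#' @export
deconvolve_contaminant <- function(calls, satellite_platelets = NA) {
  missing <- setdiff(.ctcq_deconv_markers, names(calls))
  if (length(missing))
    .stopf("calls missing marker(s): %s", paste(missing, collapse = ", "))
  if (!isTRUE(unname(calls["DRAQ5"])))
    .stopf("non-nucleated event (DRAQ5-): outside deconvolution scope")
  sig <- .deconv_signatures()
  pattern <- as.logical(calls[colnames(sig)])
  hit <- which(apply(sig, 1L, function(s) all(s == pattern)))
  if (length(hit) != 1L) return("unclassified")
  label <- rownames(sig)[hit]
  if (label == "megakaryocyte" && isTRUE(satellite_platelets))
    return("unclassified")
  label
}

#' Deconvolve a table of nucleated events
#'
#' Vectorised [deconvolve_contaminant()]. With `strict = FALSE` (the
#' default for batch accounting), DRAQ5- rows are labelled
#' `"unclassified"` instead of raising an error, since a lost nuclear
#' call simply leaves the event unaccounted.
#'
#' @param calls data.frame or matrix of logical calls (columns named by
#'   marker).
#' @param strict error on DRAQ5- rows instead of labelling them.
#' @return character vector of labels, one per row.
#' @export
deconvolve_events <- function(calls, strict = FALSE) {
  calls <- as.data.frame(calls)
  missing <- setdiff(.ctcq_deconv_markers, names(calls))
  if (length(missing))
    .stopf("calls missing marker(s): %s", paste(missing, collapse = ", "))
  vapply(seq_len(nrow(calls)), function(i) {
    row <- unlist(calls[i, .ctcq_deconv_markers])
    if (!isTRUE(unname(row["DRAQ5"]))) {
      if (strict) .stopf("non-nucleated event (DRAQ5-) at row %d", i)
      return("unclassified")
    }
    deconvolve_contaminant(row)
  }, character(1))
}

#' Archetypal marker calls for a contaminant class
#'
#' Returns the exact +/- pattern that defines each deconvolution class,
#' used to synthesise ground-truth call tables.
#'
#' @param class_label one of `leukocyte`/`WBC`, `erythroblast`,
#'   `bare_nucleus`, `megakaryocyte`.
#' @return named logical vector over the deconvolution markers.
#' @export
archetype_calls <- function(class_label) {
  if (class_label == "WBC") class_label <- "leukocyte"
  sig <- .deconv_signatures()
  if (!class_label %in% rownames(sig))
    .stopf("unknown contaminant class '%s'", class_label)
  c(DRAQ5 = TRUE, sig[class_label, ])
}

#' Apply per-marker dropout noise to a call table
#'
#' Simulates staining/detection dropout: each positive call is lost
#' (flipped to negative) independently with probability `p`. Negative
#' calls are unaffected, since a marker that is not expressed cannot drop
#' out.
#'
#' @param calls data.frame of logical calls.
#' @param p dropout probability per positive call.
#' @param seed integer seed.
#' @return the call table with dropout applied.
#' @export
drop_positive_calls <- function(calls, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  calls <- as.data.frame(calls)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(seed, "dropout"))
  for (j in seq_along(calls)) {
    pos <- which(calls[[j]])
    if (length(pos)) {
      lost <- pos[stats::runif(length(pos)) < p]
      calls[lost, j] <- FALSE
    }
  }
  calls
}

#' Tally events into marker-positivity bins
#'
#' Partitions events by their +/- combination over an ordered marker list
#' and reports counts and percentages. Percentages are kept at full
#' precision and also rounded to the nearest integer for reporting.
#'
#' @param calls data.frame of logical calls (one row per event).
#' @param markers ordered character vector of markers to bin on.
#' @return data.frame with one row per observed bin: `bin` (e.g.
#'   `"PSMA+/EpCAM-"`), one logical column per marker, `count`, `percent`
#'   (exact) and `percent_reported` (nearest integer).
#' @export
marker_bins <- function(calls, markers) {
  calls <- as.data.frame(calls)
  if (!nrow(calls)) .stopf("empty input: no events to bin")
  missing <- setdiff(markers, names(calls))
  if (length(missing))
    .stopf("calls missing marker(s): %s", paste(missing, collapse = ", "))
  key <- apply(calls[, markers, drop = FALSE], 1L, function(r)
    paste0(markers, ifelse(as.logical(r), "+", "-"), collapse = "/"))
  tab <- table(key)
  n <- nrow(calls)
  out <- data.frame(bin = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  flags <- do.call(rbind, strsplit(out$bin, "/", fixed = TRUE))
  for (i in seq_along(markers))
    out[[markers[i]]] <- endsWith(flags[, i], "+")
  out$percent <- 100 * out$count / n
  out$percent_reported <- round(out$percent)
  out[order(-out$count, out$bin), , drop = FALSE]
}
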
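#' Synthetic population configuration
#'
#' Builds the configuration object consumed by [sample_population()],
#' [render_cell_image()] and [simulate_enrichment_run()]. Per-class size
#' distributions are lognormal, parameterised by median diameter (um) and
#' log-scale sigma; per-class surface-marker densities are lognormal in
#' arbitrary units (a.u.) on the instrument scale. Defaults emulate the
#' populations seen in negative-depletion CTC product: the WBC size law is
#' anchored so that its 99.9% quantile sits at 13.9 um, CTC diameters span
#' roughly 5-30 um, and the CTC EpCAM law is long-tailed so that patient-like
#' samples cover means from tens to hundreds of a.u.
#'
#' @param seed integer seed; all randomness in the generator flows from it
#'   via named substreams.
#' @param pixel_scale microns per pixel for rendered images (default 0.5).
#' @param ring_px membrane annulus thickness in rendered images, pixels.
#' @param blur_sigma Gaussian blur sigma (pixels) applied to rendered
#'   channels; 0 disables blurring.
#' @param bg_mean,bg_sd background noise level: pixels receive additive
#'   Gaussian noise `N(bg_mean, bg_sd)` clipped at zero. The default mean
#'   matches the empty-channel (WBC EpCAM) baseline of 1.98 a.u.
#' @param noise logical; set `FALSE` to render noise-free images.
#' @param bead_mean mean magnetic bead count per WBC (Poisson law).
#' @param nuclear_fraction nuclear disk diameter as a fraction of the cell
#'   diameter in rendered images.
#' @param frame_px fixed rendered frame side length in pixels, or `NULL` to
#'   size the frame automatically around each cell.
#' @param classes optional override of the per-class distribution list; see
#'   Details.
#'
#' @details
#' `classes` is a named list (names are class labels: `CTC`, `WBC`,
#' `erythroblast`, `bare_nucleus`, `megakaryocyte`); each element has
#' `size = list(median_um =, sdlog =)` and `markers = list(<marker> =
#' list(meanlog =, sdlog =))`. Markers absent from a class have zero
#' density (background only). Magnetic beads attach only to cells
#' expressing the depletion antigens (CD45/CD16/CD66b), i.e. WBCs;
#' all other classes carry zero beads.
#'
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' pop <- sample_population(cfg, 100, c(WBC = 0.9, CTC = 0.1))
#' table(pop$class_label)
synth_config <- function(seed = 1L,
                         pixel_scale = 0.5,
                         ring_px = 2L,
                         blur_sigma = 0,
                         bg_mean = 1.98,
                         bg_sd = 0.66,
                         noise = TRUE,
                         bead_mean = 7,
                         nuclear_fraction = 0.65,
                         frame_px = NULL,
                         classes = NULL) {
  if (pixel_scale <= 0) .stopf("pixel_scale must be > 0")
  if (bead_mean < 0) .stopf("bead_mean must be >= 0")
  if (ring_px < 1) .stopf("ring_px must be >= 1")
  if (!is.null(frame_px) && frame_px < 11) .stopf("frame_px too small")

  if (is.null(classes)) {
    ## WBC size law solved so that Q(0.999) = 13.9 um exactly.
    wbc_median <- 9.5
    wbc_sdlog <- log(13.9 / wbc_median) / stats::qnorm(0.999)
    lnpar <- function(mean, sdlog) list(meanlog = log(mean) - sdlog^2 / 2,
                                        sdlog = sdlog)
    classes <- list(
      WBC = list(
        size = list(median_um = wbc_median, sdlog = wbc_sdlog),
        markers = list(DRAQ5 = lnpar(200, 0.3), CD45 = lnpar(150, 0.4),
                       CD16 = lnpar(100, 0.4), CD66b = lnpar(60, 0.5))),
      CTC = list(
        size = list(median_um = 12, sdlog = 0.30),
        markers = list(DRAQ5 = lnpar(200, 0.3),
                       ## long-tailed EpCAM spanning the patient-scale means
                       EpCAM = list(meanlog = log(250) - 1.2^2 / 2,
                                    sdlog = 1.2))),
      erythroblast = list(
        size = list(median_um = 9, sdlog = 0.12),
        markers = list(DRAQ5 = lnpar(200, 0.3), GlyA = lnpar(120, 0.4))),
      bare_nucleus = list(
        size = list(median_um = 7, sdlog = 0.15),
        markers = list(DRAQ5 = lnpar(200, 0.3), ConA = lnpar(120, 0.4))),
      megakaryocyte = list(
        size = list(median_um = 18, sdlog = 0.20),
        markers = list(DRAQ5 = lnpar(200, 0.3), CD41 = lnpar(120, 0.4)))
    )
  }
  for (cl in classes) {
    if (!is.finite(cl$size$median_um) || cl$size$median_um <= 0 ||
        !is.finite(cl$size$sdlog) || cl$size$sdlog < 0)
      .stopf("invalid size distribution parameters")
  }

  structure(list(seed = as.integer(seed), pixel_scale = pixel_scale,
                 ring_px = as.integer(ring_px), blur_sigma = blur_sigma,
                 bg_mean = bg_mean, bg_sd = bg_sd, noise = isTRUE(noise),
                 bead_mean = bead_mean, nuclear_fraction = nuclear_fraction,
                 frame_px = frame_px, classes = classes),
            class = "synth_config")
}

#' Sample a ground-truthed synthetic cell population
#'
#' Draws `n` cells from the configured per-class size and marker-density
#' laws according to a class mix. Bead counts are Poisson for WBCs (the only
#' class expressing the depletion antigens) and zero otherwise.
#'
#' @param config a [synth_config()] object.
#' @param n number of cells (>= 1).
#' @param class_mix named numeric vector of class fractions summing to 1.
#' @return a data.frame with columns `cell_id`, `class_label`,
#'   `true_diameter_um`, `bead_count` and one column per marker density
#'   (a.u.); markers a class does not express are 0.
#' @export
sample_population <- function(config, n, class_mix) {
  stopifnot(inherits(config, "synth_config"))
  if (length(n) != 1L || is.na(n) || n < 1) .stopf("n must be >= 1")
  n <- as.integer(n)
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    .stopf("class_mix must be a named vector")
  unknown <- setdiff(names(class_mix), names(config$classes))
  if (length(unknown))
    .stopf("unknown class(es) in class_mix: %s", paste(unknown, collapse = ", "))
  if (any(class_mix < 0)) .stopf("class_mix fractions must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-9) .stopf("class_mix must sum to 1")

  markers <- unique(unlist(lapply(config$classes,
                                  function(cl) names(cl$markers))))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(config$seed, "sample_population"))

  labels <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  diam <- numeric(n)
  beads <- integer(n)
  dens <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    par <- config$classes[[cl]]
    diam[idx] <- stats::rlnorm(length(idx),
                               meanlog = log(par$size$median_um),
                               sdlog = par$size$sdlog)
    for (mk in names(par$markers)) {
      mp <- par$markers[[mk]]
      dens[idx, mk] <- stats::rlnorm(length(idx), mp$meanlog, mp$sdlog)
    }
    if (cl == "WBC")
      beads[idx] <- stats::rpois(length(idx), config$bead_mean)
  }
  out <- data.frame(cell_id = sprintf("cell_%06d", seq_len(n)),
                    class_label = labels,
                    true_diameter_um = diam,
                    bead_count = beads,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dens))
}

## Save/restore the global RNG state so generator calls do not disturb the
## caller's random stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a synthetic single-cell multichannel image
#'
#' Renders one cell as a set of co-registered channel images: the nuclear
#' channel (`DRAQ5`) is a filled disk, and every surface-marker channel is a
#' thin annulus just inside the cell boundary whose intensity equals the
#' cell's marker density. Optional Gaussian blur and additive background
#' noise (clipped at zero) emulate the instrument. Rendering is
#' deterministic for a fixed config seed and cell id.
#'
#' @param cell a single-row data.frame as produced by [sample_population()],
#'   or a list with `cell_id`, `true_diameter_um` and marker density fields.
#' @param config a [synth_config()] object.
#' @param markers which channels to render; defaults to every marker with a
#'   density value on the cell (zero-density markers render as pure
#'   background).
#' @return a `cell_image` object: list with `channels` (named list of
#'   numeric matrices), `pixel_scale` and `event_id`.
#' @export
render_cell_image <- function(cell, config, markers = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cell <- as.list(cell)
  d_um <- cell$true_diameter_um
  if (is.null(d_um) || d_um <= 0) .stopf("cell must have true_diameter_um > 0")

  r_px <- d_um / config$pixel_scale / 2
  margin <- 5L
  need <- ceiling(2 * r_px) + 2L * margin + 1L
  frame <- if (is.null(config$frame_px)) need else as.integer(config$frame_px)
  if (frame < need)
    .stopf("cell of %.2f um does not fit in a %d px frame with a %d px margin",
           d_um, frame, margin)

  known <- setdiff(names(cell),
                   c("cell_id", "class_label", "true_diameter_um", "bead_count"))
  if (is.null(markers)) markers <- known
  density <- vapply(markers, function(mk) {
    v <- cell[[mk]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))

  ctr <- (frame + 1) / 2
  dist <- sqrt(outer((seq_len(frame) - ctr)^2,
                     (seq_len(frame) - ctr)^2, "+"))
  ring <- dist <= r_px & dist > (r_px - config$ring_px)
  nucleus <- dist <= r_px * config$nuclear_fraction

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(config$seed,
                          paste0("render:", cell$cell_id %||% "anon")))

  channels <- lapply(markers, function(mk) {
    img <- matrix(0, frame, frame)
    if (mk == "DRAQ5") img[nucleus] <- density[[mk]]
    else img[ring] <- density[[mk]]
    if (config$blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = config$blur_sigma))
    if (config$noise) {
      img <- img + stats::rnorm(length(img), config$bg_mean, config$bg_sd)
      img[img < 0] <- 0
    }
    img
  })
  names(channels) <- markers
  structure(list(channels = channels, pixel_scale = config$pixel_scale,
                 event_id = cell$cell_id %||% "anon"),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image %s: %d channel(s) [%s], %dx%d px at %.3g um/px>\n",
              x$event_id, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_scale))
  invisible(x)
}

#' Simulate an enrichment cascade run
#'
#' Routes each input cell through the three loss/removal stages of the
#' negative-depletion cascade as a stochastic event-level simulation:
#' size-based debulking (DLD) transfers each nucleated cell with a fixed
#' probability, a first magnetic sorting stage (MACS1) removes cells
#' carrying at least `macs1_cutoff` beads, and a second, more sensitive
#' stage (MACS2) removes cells carrying at least `macs2_cutoff` beads.
#' Every cell ends in exactly one of four streams: `dld_waste`,
#' `macs1_waste`, `macs2_waste` or `product`.
#'
#' @param cells data.frame from [sample_population()] (needs `class_label`
#'   and `bead_count`).
#' @param params list with `dld_transfer` (default 0.70), `macs1_cutoff`
#'   (default 6 beads) and `macs2_cutoff` (default 1 bead).
#' @param seed integer seed for the routing randomness.
#' @return an `enrichment_tally`: list with `stream` (per-cell factor),
#'   `counts` (stream totals), `by_class` (class x stream table) and the
#'   `product` subset of `cells`.
#' @export
simulate_enrichment_run <- function(cells,
                                    params = list(),
                                    seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("class_label", "bead_count") %in% names(cells)))
  p <- utils::modifyList(list(dld_transfer = 0.70, macs1_cutoff = 6,
                              macs2_cutoff = 1), params)
  if (p$dld_transfer < 0 || p$dld_transfer > 1)
    .stopf("dld_transfer must be in [0, 1]")
  if (p$macs1_cutoff < 0 || p$macs2_cutoff < 0)
    .stopf("bead cutoffs must be >= 0")

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(substream_seed(seed, "enrichment"))

  n <- nrow(cells)
  passed_dld <- stats::runif(n) < p$dld_transfer
  stream <- rep("dld_waste", n)
  stream[passed_dld & cells$bead_count >= p$macs1_cutoff] <- "macs1_waste"
  stream[passed_dld & cells$bead_count < p$macs1_cutoff &
           cells$bead_count >= p$macs2_cutoff] <- "macs2_waste"
  stream[passed_dld & cells$bead_count < p$macs2_cutoff] <- "product"
  stream <- factor(stream,
                   levels = c("dld_waste", "macs1_waste", "macs2_waste",
                              "product"))
  structure(list(stream = stream,
                 counts = table(stream),
                 by_class = table(cells$class_label, stream),
                 product = cells[stream == "product", , drop = FALSE],
                 params = p),
            class = "enrichment_tally")
}

#' @export
print.enrichment_tally <- function(x, ...) {
  cat("<enrichment_tally>\n")
  print(x$counts)
  invisible(x)
}

#' Write ground-truth population to CSV
#'
#' @param cells data.frame from [sample_population()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write a rendered cell image as a multi-page TIFF with a sidecar
#'
#' One page per channel, in channel order. TIFF pages store intensities
#' normalised to `[0, 1]`; the common scale factor, the channel map and
#' the pixel scale go into a YAML sidecar at `<path>.yaml` so that
#' arbitrary-unit values round-trip exactly.
#'
#' @param image a `cell_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cell_tiff <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  scale_factor <- max(1, vapply(image$channels, max, numeric(1)))
  pages <- lapply(image$channels, function(ch) ch / scale_factor)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(event_id = image$event_id,
                        channel_map = as.list(names(image$channels)),
                        scale_factor = scale_factor,
                        pixel_scale = image$pixel_scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF into a cell image
#'
#' Reads the YAML sidecar written by [write_cell_tiff()] when present;
#' otherwise `channel_map` (and optionally `pixel_scale`, `scale_factor`)
#' must be given.
#'
#' @param path TIFF path (one page per channel).
#' @param channel_map character vector of marker names, one per page;
#'   ignored if a sidecar exists.
#' @param pixel_scale microns per pixel (sidecar overrides).
#' @param scale_factor intensity scale factor (sidecar overrides).
#' @param event_id event identifier (sidecar overrides).
#' @return a `cell_image`.
#' @export
read_cell_tiff <- function(path, channel_map = NULL, pixel_scale = 0.5,
                           scale_factor = 1, event_id = basename(path)) {
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    channel_map <- unlist(meta$channel_map)
    pixel_scale <- meta$pixel_scale
    scale_factor <- meta$scale_factor
    event_id <- meta$event_id
  }
  if (is.null(channel_map))
    .stopf("no sidecar at %s: channel_map must be supplied", sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_map))
    .stopf("TIFF has %d page(s) but channel_map names %d",
           length(pages), length(channel_map))
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    matrix(as.numeric(p) * scale_factor, nrow(p), ncol(p))
  })
  names(channels) <- channel_map
  structure(list(channels = channels, pixel_scale = pixel_scale,
                 event_id = event_id),
            class = "cell_image")
}
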
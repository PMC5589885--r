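#' Read an event table
#'
#' Event tables are UTF-8 CSV with "." decimals. Mandatory columns are
#' `event_id` and `diameter_um`; all other columns (marker expressions,
#' class annotations, flags) are preserved as-is.
#'
#' @param path CSV path.
#' @param required mandatory column names.
#' @return a `population_sample` (a data.frame subclass).
#' @export
read_event_table <- function(path, required = c("event_id", "diameter_um")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("event table %s is missing mandatory column(s): %s",
           path, paste(missing, collapse = ", "))
  if (!nrow(df)) .warnf("event table %s has a header but no events", path)
  class(df) <- c("population_sample", "data.frame")
  df
}

#' Write an event table
#'
#' @param events data.frame of events.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Assembles the full configuration for [run_pipeline()]: generator
#' settings, measurement policy, marker panel, calibration, enrichment
#' stage parameters and run bookkeeping. The configuration round-trips
#' losslessly through YAML via [write_run_config()]/[read_run_config()].
#'
#' @param seed master seed for the run.
#' @param n_cells number of cells to simulate.
#' @param class_mix named class-fraction vector.
#' @param n_render how many of the simulated cells are rendered as images
#'   and measured (the rest keep their ground-truth values); rendering
#'   dominates runtime, so this is kept modest by default.
#' @param disease disease panel for CTC identification.
#' @param blood_volume_ml nominal input blood volume for carryover
#'   accounting.
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L,
                               n_cells = 400L,
                               class_mix = c(WBC = 0.90, CTC = 0.10),
                               n_render = 40L,
                               disease = "breast",
                               blood_volume_ml = 10) {
  structure(list(
    seed = as.integer(seed),
    n_cells = as.integer(n_cells),
    class_mix = as.list(class_mix),
    n_render = as.integer(n_render),
    disease = disease,
    blood_volume_ml = blood_volume_ml,
    pixel_scale = 0.5,
    threshold_policy = "otsu",
    size_threshold_tail = 0.001,
    epcam_threshold = 147,
    calibration = list(mesf_per_au = 520, correct_size = FALSE),
    enrichment = list(dld_transfer = 0.70, macs1_cutoff = 6,
                      macs2_cutoff = 1)
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML path.
#' @return for `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every output so
#' that artifacts can be traced to the exact configuration that produced
#' them.
#'
#' @param config a `run_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> render/quantify -> classify -> stats on synthetic
#' data as configured, writing a reproducible report bundle to `outdir`:
#' `ground_truth.csv`, `events.csv` (measured events), `classified.csv`,
#' `yield_curves.csv` and `stats.json`. Every artifact records the config
#' hash and seed; rerunning with an identical config reproduces the bundle
#' byte for byte.
#'
#' Positivity thresholds for classification are derived at run time from a
#' rendered blank (background-only) control set using
#' [threshold_from_controls()], except EpCAM, which uses the configured
#' CellSearch-equivalent threshold.
#'
#' @param config a `run_config` from [default_run_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return the report bundle, invisibly (list of data.frames plus the
#'   stats list).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = tempdir(),
                         quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  class_mix <- unlist(config$class_mix)

  ## Stage 1: simulate ------------------------------------------------
  scfg <- synth_config(seed = config$seed, pixel_scale = config$pixel_scale)
  cells <- tryCatch(
    sample_population(scfg, config$n_cells, class_mix),
    error = function(e) .stopf("stage 'simulate' failed: %s",
                               conditionMessage(e)))
  write_ground_truth(cells, file.path(outdir, "ground_truth.csv"))
  say("simulate: %d cells (%s)", nrow(cells),
      paste(sprintf("%s=%d", names(table(cells$class_label)),
                    as.integer(table(cells$class_label))), collapse = ", "))

  ## Stage 2: render + quantify ---------------------------------------
  n_render <- min(config$n_render, nrow(cells))
  seg_marker <- function(cl) switch(cl, WBC = "CD45",
                                    CTC = if (identical(config$disease,
                                                        "melanoma"))
                                      "CD146" else "EpCAM",
                                    "DRAQ5")
  measured <- tryCatch({
    rows <- lapply(seq_len(n_render), function(i) {
      cell <- cells[i, ]
      img <- render_cell_image(cell, scfg)
      m <- measure_cell(img, seg_marker(cell$class_label),
                        policy = config$threshold_policy)
      m$class_label <- cell$class_label
      m
    })
    do.call(rbind, rows)
  }, error = function(e) .stopf("stage 'quantify' failed: %s",
                                conditionMessage(e)))
  names(measured)[names(measured) == "diameter_um"] <- "diameter_um_raw"
  measured$diameter_um <- if (isTRUE(config$calibration$correct_size))
    correct_size_bias(measured$diameter_um_raw,
                      intensity = measured$threshold_used)
  else measured$diameter_um_raw
  measured$config_hash <- hash
  measured$seed <- config$seed
  write_event_table(measured, file.path(outdir, "events.csv"))
  say("quantify: %d events measured (threshold policy: %s)",
      nrow(measured), config$threshold_policy)

  ## Stage 3: classify -------------------------------------------------
  classified <- tryCatch({
    ## blank control renders give the per-marker background distribution
    markers <- setdiff(names(cells),
                       c("cell_id", "class_label", "true_diameter_um",
                         "bead_count"))
    blank <- list(cell_id = "blank", true_diameter_um = 8)
    blank[markers] <- 0
    ctrl <- lapply(1:10, function(i) {
      b <- blank; b$cell_id <- sprintf("blank_%02d", i)
      img <- render_cell_image(b, scfg, markers = markers)
      ms <- membrane_mask(segment_cell(
        render_cell_image(utils::modifyList(b, list(DRAQ5 = 200)),
                          scfg, markers = "DRAQ5"), "DRAQ5"))
      vapply(markers, function(mk) membrane_expression(img, mk, ms),
             numeric(1))
    })
    ctrl <- do.call(rbind, ctrl)
    thr <- vapply(markers, function(mk) threshold_from_controls(ctrl[, mk]),
                  numeric(1))
    thr["EpCAM"] <- config$epcam_threshold
    panel <- marker_panel(config$disease, thr[c("DRAQ5", "CD45", "CD66b",
                                                "CD16", "EpCAM")])
    out <- measured
    calls <- t(vapply(seq_len(nrow(out)), function(i)
      call_positivity(out[i, names(panel$thresholds)], panel), logical(
        length(panel$thresholds))))
    out$is_ctc <- vapply(seq_len(nrow(out)), function(i)
      call_ctc(calls[i, ], panel), logical(1))
    out
  }, error = function(e) .stopf("stage 'classify' failed: %s",
                                conditionMessage(e)))
  write_event_table(classified, file.path(outdir, "classified.csv"))
  say("classify: %d events, %d called CTC", nrow(classified),
      sum(classified$is_ctc))

  ## Stage 4: stats + enrichment accounting ----------------------------
  stats_out <- tryCatch({
    wbc_d <- cells$true_diameter_um[cells$class_label == "WBC"]
    size_thr <- suppressWarnings(
      wbc_size_threshold(wbc_d, config$size_threshold_tail))
    ctc <- cells[cells$class_label == "CTC", ]
    run <- simulate_enrichment_run(cells, config$enrichment,
                                   seed = config$seed)
    byc <- run$by_class
    yield <- if ("CTC" %in% rownames(byc))
      relative_yield(byc["CTC", "product"],
                     byc["CTC", c("macs1_waste", "macs2_waste")])
    else NA_real_
    carry <- wbc_carryover(
      if ("WBC" %in% rownames(byc)) byc["WBC", "product"] else 0,
      config$blood_volume_ml)
    curves <- NULL
    st <- list(config_hash = hash, seed = config$seed,
               n_cells = nrow(cells),
               n_measured = nrow(measured),
               size_threshold_um = as.numeric(size_thr),
               epcam_threshold_au = config$epcam_threshold,
               stream_counts = as.list(run$counts),
               ctc_relative_yield = yield,
               wbc_carryover_per_ml = carry)
    if (nrow(ctc)) {
      st$pct_ctc_below_size <- fraction_below(ctc$true_diameter_um,
                                              as.numeric(size_thr))
      st$pct_ctc_below_epcam <- fraction_below(ctc$EpCAM,
                                               config$epcam_threshold)
      st$quadrants <- as.list(quadrant_percentages(
        ctc$true_diameter_um, ctc$EpCAM, as.numeric(size_thr),
        config$epcam_threshold))
      grid_size <- seq(4, 30, by = 0.5)
      grid_ep <- seq(0, 600, by = 10)
      curves <- rbind(
        cbind(axis = "size_um",
              expected_yield_curve(ctc$true_diameter_um, grid_size)),
        cbind(axis = "epcam_au", expected_yield_curve(ctc$EpCAM, grid_ep)))
    }
    if (!is.null(curves))
      utils::write.csv(curves, file.path(outdir, "yield_curves.csv"),
                       row.names = FALSE)
    st
  }, error = function(e) .stopf("stage 'stats' failed: %s",
                                conditionMessage(e)))
  jsonlite::write_json(stats_out, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("stats: size threshold %.2f um, report written to %s",
      stats_out$size_threshold_um, outdir)

  invisible(list(ground_truth = cells, events = measured,
                 classified = classified, stats = stats_out,
                 config_hash = hash))
}
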
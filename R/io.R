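#' Read stitched frames from a multi-page 16-bit grayscale TIFF
#'
#' @param path TIFF file; every page must be single-channel 16-bit.
#' @param fov_ids Optional identifiers; default `page1`, `page2`, ... in
#'   page order.
#' @return List of `image_frame`s with integer pixel counts (0-65535).
#' @export
read_frames <- function(path, fov_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  if (is.null(fov_ids)) fov_ids <- paste0("page", seq_along(pages))
  stopifnot(length(fov_ids) == length(pages))
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    bits <- attr(p, "bits.per.sample")
    if (!is.matrix(p))
      stop(sprintf("page %d is not single-channel grayscale", i))
    if (!is.null(bits) && bits != 16L)
      stop(sprintf("page %d is %d-bit, expected 16-bit", i, bits))
    m <- matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
    .new_frame(m, fov_ids[i])
  })
}

#' Write frames to a multi-page 16-bit grayscale TIFF
#'
#' Round trips with [read_frames()] bit-exactly.
#'
#' @param frames List of `image_frame`s (integer counts 0-65535).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  imgs <- lapply(frames, function(f) .as_pixels(f) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read an affine transform as JSON
#'
#' Stored as `{"matrix": [[a, b, tx], [c, d, ty], [0, 0, 1]]}` at full
#' precision.
#'
#' @param transform An `affine2d`.
#' @param path JSON file path.
#' @return `path` (write) or the `affine2d` (read).
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "affine2d"))
  m <- transform$matrix; dimnames(m) <- NULL
  writeLines(jsonlite::toJSON(list(matrix = m), digits = NA), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  affine2d(obj$matrix)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' Unknown top-level keys are rejected so misspellings cannot silently fall
#' back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file with any subset of the
#'   sections accepted by [run_pipeline()].
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("seed", "sim", "registration", "detection", "colocalization",
             "quantification", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg
}

.default_run_config <- function() {
  list(seed = 1L,
       sim = list(concentrations = c(0, 10, 100, 300, 1000, 20000),
                  fovs_per_concentration = 16L, config = list()),
       registration = list(n_frames = 5L, beads_per_frame = 50L,
                           jitter_sd_px = 0, max_distance_px = 5),
       detection = list(sigma = 0.8, threshold_multiplier = 1.2),
       colocalization = list(enabled = TRUE, radius_px = 1.5),
       quantification = list(signal_kind = "normalized_coloc",
                             n_boot = 1000L),
       out_dir = NULL)
}

.merge_config <- function(user) {
  cfg <- .default_run_config()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
      modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  cfg
}

#' Run the full synthetic two-color colocalization pipeline
#'
#' End to end on simulated data: a titration of two-color frames is
#' generated; fiducial bead frames are simulated, their beads detected, and
#' the detection-to-capture registration estimated and averaged; each field
#' of view has both channels detected, the quality filter applied, and (when
#' colocalization is enabled) pairs counted at the 1.5 px criterion and
#' normalized; counts are aggregated per concentration; the Langmuir
#' calibration is fit on the chosen signal, the limit of detection computed
#' from the blank fields of view, and the out-of-bag bootstrap
#' quantification error estimated. With colocalization disabled the pipeline
#' runs the single-color arm (absolute or cAb-normalized detection counts).
#'
#' @param config Nested list (see [read_run_config()]); omitted sections use
#'   the defaults in the printed protocol: detection sigma 0.8, threshold
#'   multiplier 1.2, colocalization radius 1.5 px, 1000 bootstrap
#'   iterations, concentration ladder 0/10/100/300/1000/20000 pM with 16
#'   fields of view each.
#' @return List: `counts` (per-FOV data frame with QC flags), `summary`
#'   (per-concentration aggregate), `transform`, `calibration`, `lod`,
#'   `maple`, and `config` (the merged configuration). When
#'   `config$out_dir` is set, also writes `counts.csv`, `summary.csv`,
#'   `transform.json`, `calibration.json`, `lod.json`, `maple.csv` and
#'   `manifest.json` there; reruns with the same seed are byte-identical.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .merge_config(config)
  set.seed(cfg$seed)
  sim_args <- cfg$sim$config
  scfg <- do.call(sim_config, sim_args)

  # --- registration from simulated bead frames, localized from the images
  beads <- simulate_bead_frames(
    scfg$true_transform, n_frames = cfg$registration$n_frames,
    beads_per_frame = cfg$registration$beads_per_frame,
    jitter_sd_px = cfg$registration$jitter_sd_px,
    rng_seed = (cfg$seed + 101) %% 2147483647,
    image_height_px = scfg$image_height_px,
    image_width_px = scfg$image_width_px)
  bead_coords <- lapply(beads, function(b) {
    list(capture_xy = detect_spots(b$frame, "capture",
                                   sigma = cfg$detection$sigma,
                                   threshold_multiplier = cfg$detection$threshold_multiplier)$spots[, c("x", "y")],
         detection_xy = detect_spots(b$frame, "detection",
                                     sigma = cfg$detection$sigma,
                                     threshold_multiplier = cfg$detection$threshold_multiplier)$spots[, c("x", "y")])
  })
  transform <- register_channels(bead_coords, cfg$registration$max_distance_px)

  # --- titration, detection, QC, colocalization
  titr <- simulate_titration(scfg, cfg$sim$concentrations,
                             cfg$sim$fovs_per_concentration,
                             rng_seed = (cfg$seed + 202) %% 2147483647)
  coloc_on <- isTRUE(cfg$colocalization$enabled)
  rows <- lapply(titr, function(entry) {
    cab <- detect_spots(entry$frame, "capture", sigma = cfg$detection$sigma,
                        threshold_multiplier = cfg$detection$threshold_multiplier)
    dab <- detect_spots(entry$frame, "detection", sigma = cfg$detection$sigma,
                        threshold_multiplier = cfg$detection$threshold_multiplier)
    qc <- qc_filter(cab, scfg$image_height_px)
    cc <- if (coloc_on) colocalize(cab, dab, transform,
                                   cfg$colocalization$radius_px)$counts
          else data.frame(fov_id = entry$fov_id, cab_count = nrow(cab$spots),
                          dab_count = nrow(dab$spots), coloc_count = NA_integer_)
    cbind(cc, data.frame(concentration_pm = entry$concentration,
                         qc_kept = qc$keep, mean_y_px = qc$mean_y))
  })
  counts <- do.call(rbind, rows)
  if (coloc_on) counts <- normalize_counts(counts)
  else {
    counts$normalized_single <- ifelse(counts$cab_count > 0,
                                       counts$dab_count / counts$cab_count, NA_real_)
    counts$valid <- counts$cab_count > 0
  }

  kept <- counts[counts$qc_kept & counts$valid, , drop = FALSE]
  summary_df <- aggregate_counts(kept, by = "concentration_pm")

  # --- calibration, LOD, quantification error
  kind <- cfg$quantification$signal_kind
  signal <- switch(kind,
                   absolute = kept$dab_count,
                   normalized_single = kept$normalized_single,
                   normalized_coloc = {
                     if (!coloc_on) stop("normalized_coloc requires colocalization to be enabled")
                     kept$normalized_coloc
                   },
                   stop("unknown signal_kind: ", kind))
  pos <- kept$concentration_pm > 0
  calibration <- fit_langmuir(kept$concentration_pm[pos], signal[pos], kind)
  blanks <- signal[!pos]
  lod <- if (length(blanks) >= 2L) compute_lod(calibration, blanks) else NULL
  qmaple <- bootstrap_maple(kept$concentration_pm, signal, kind,
                            n_boot = cfg$quantification$n_boot,
                            rng_seed = (cfg$seed + 303) %% 2147483647)

  res <- list(counts = counts, summary = summary_df, transform = transform,
              calibration = calibration, lod = lod, maple = qmaple,
              config = cfg)
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(res, cfg$out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  write.csv(res$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write_transform(res$transform, file.path(out_dir, "transform.json"))
  cal <- res$calibration
  jsonlite::write_json(
    list(kd_pm = cal$kd, bmax = cal$bmax, sigma_kd_pm = cal$sigma_kd,
         sigma_bmax = cal$sigma_bmax,
         covariance = unname(cal$covariance), signal_kind = cal$signal_kind),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$lod))
    jsonlite::write_json(
      list(lod_signal = res$lod$lod_signal,
           lod_concentration_pm = res$lod$lod_concentration,
           sigma_lod_pm = res$lod$sigma_lod,
           blank_mean = res$lod$blank_mean, blank_sd = res$lod$blank_sd),
      file.path(out_dir, "lod.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(iteration = seq_along(res$maple$maple),
                       maple_percent = res$maple$maple),
            file.path(out_dir, "maple.csv"), row.names = FALSE)
  cfg <- res$config
  cfg$sim$config <- NULL                      # affine2d not JSON-native
  jsonlite::write_json(
    list(package = "smcoloc",
         version = as.character(utils::packageVersion("smcoloc")),
         seed = cfg$seed, config = cfg,
         true_transform = NULL),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}
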
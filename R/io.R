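# Shared I/O: TIFF volumes with JSON pitch sidecars, deterministic CSV
# tables, run configuration and the end-to-end demo pipeline.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image volume as a multi-page TIFF with a JSON sidecar
#'
#' Slices are written as 32-bit float TIFF pages, scaled into [0, 1] by
#' the volume maximum; the scale factor, pitches and channel label go to
#' a JSON sidecar (`<path>.json`) so the volume reads back in physical
#' units.
#'
#' @param vol an [image_volume].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  mx <- max(vol$voxels)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(vol$voxels)[1]),
                  function(iz) vol$voxels[iz, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pitch_xy_nm = vol$pitch_xy, pitch_z_nm = vol$pitch_z,
         channel = vol$channel, intensity_scale = scale,
         dim_zyx = dim(vol$voxels)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume from a multi-page TIFF
#'
#' Pitch metadata comes from the JSON sidecar written by [write_volume];
#' when the sidecar is missing, the supplied (or default 140/300 nm)
#' pitches are used with a warning.
#'
#' @param path TIFF path.
#' @param pitch_xy,pitch_z fallback pitches (nm) when no sidecar exists.
#' @param channel fallback channel label.
#' @return an [image_volume].
#' @export
read_volume <- function(path, pitch_xy = 140, pitch_z = 300,
                        channel = "GFP") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    pitch_xy <- meta$pitch_xy_nm
    pitch_z <- meta$pitch_z_nm
    channel <- meta$channel
    scale <- meta$intensity_scale
  } else {
    warning(sprintf(
      "no pitch sidecar for '%s'; falling back to %g nm xy / %g nm z",
      path, pitch_xy, pitch_z))
  }
  vox <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                          ncol(pages[[1]])))
  for (iz in seq_along(pages)) vox[iz, , ] <- pages[[iz]] * scale
  image_volume(vox, pitch_xy = pitch_xy, pitch_z = pitch_z,
               channel = channel)
}

#' Write a measurement table as deterministic CSV
#'
#' Columns keep their given order; numeric columns are formatted with
#' `format(..., digits = 15)` in the C locale conventions of
#' [utils::write.csv] (decimal points, no grouping), so identical inputs
#' produce byte-identical files and values survive a read round trip.
#'
#' @param records a data.frame (may have zero rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the tunable physical and numerical parameters of the pipeline
#' with their defaults: 140 nm xy / 300 nm z pitches, the 245-nm spot SD
#' cutoff (1.75 pixels), the 1,000 intensity divisor, the 2-um phase
#' threshold, 5 projection slices, 8x/4x upscales, the 75% contour
#' fraction and 100 Monte Carlo replicates.
#'
#' @param pitch_xy,pitch_z voxel pitches (nm).
#' @param divisor normalized-intensity divisor (1000 or 10000).
#' @param sd_max_nm declustering spot-size cutoff (nm).
#' @param phase_threshold_um metaphase/anaphase spindle-length threshold.
#' @param proj_slices z slices in the SPA maximum projection.
#' @param upscale,contour_upscale bilinear upscale factors.
#' @param contour_fraction contour threshold fraction.
#' @param n_mc Monte Carlo replicates.
#' @param n_kinetochores kinetochores per cluster.
#' @param seed RNG seed recorded in every output.
#' @param out_dir output directory for [run_pipeline].
#' @return a list of class `run_config`.
#' @export
run_config <- function(pitch_xy = 140, pitch_z = 300, divisor = 1000,
                       sd_max_nm = 245, phase_threshold_um = 2,
                       proj_slices = 5, upscale = 8, contour_upscale = 4,
                       contour_fraction = 0.75, n_mc = 100,
                       n_kinetochores = 16, seed = 1,
                       out_dir = tempfile("kinspa_run_")) {
  cfg <- list(pitch_xy = pitch_xy, pitch_z = pitch_z, divisor = divisor,
              sd_max_nm = sd_max_nm,
              phase_threshold_um = phase_threshold_um,
              proj_slices = proj_slices, upscale = upscale,
              contour_upscale = contour_upscale,
              contour_fraction = contour_fraction, n_mc = n_mc,
              n_kinetochores = n_kinetochores, seed = as.integer(seed),
              out_dir = out_dir)
  phys <- c("pitch_xy", "pitch_z", "sd_max_nm", "phase_threshold_um",
            "proj_slices", "upscale", "contour_upscale",
            "contour_fraction", "n_mc", "n_kinetochores")
  if (any(unlist(cfg[phys]) <= 0))
    stop("all physical parameters must be > 0")
  if (!divisor %in% c(1000, 10000)) stop("divisor must be 1000 or 10000")
  structure(cfg, class = "run_config")
}

#' Run a pipeline stage on synthetic demo data
#'
#' Drives the analysis stages end-to-end on generator output and writes
#' their artifacts plus a provenance JSON (configuration, seed, package
#' version) to `config$out_dir`. Stages: `"quantify"` (calibrated
#' counting of simulated clusters -> per-spot and summary CSV), `"frap"`
#' (simulated bleach series -> recovery CSV), `"cylinder"` (forward-model
#' round trip -> JSON). `"all"` runs every stage. Identical
#' (config, seed) pairs produce byte-identical outputs.
#'
#' @param config a [run_config].
#' @param stage stage name.
#' @return named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(config, stage = "all") {
  stopifnot(inherits(config, "run_config"))
  stages <- c("quantify", "frap", "cylinder")
  if (identical(stage, "all")) stage <- stages
  if (!all(stage %in% stages))
    stop(sprintf("unknown stage '%s'; available: %s, all",
                 setdiff(stage, stages)[1], paste(stages, collapse = ", ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  calib <- calibration_standard(100)
  if ("quantify" %in% stage) {
    rows <- list()
    for (i in seq_len(10)) {
      copies <- c(1, 4)[(i %% 2) + 1]
      sim <- simulate_cluster_spot(copies, calib = calib,
                                   seed = config$seed * 1000 + i)
      fit <- fit_gaussian_spot(sim$volume, sim$truth$center_nm)
      cp <- copies_from_amplitude(fit$amplitude, calib,
                                  config$n_kinetochores)
      rows[[i]] <- data.frame(
        cell_id = i, phase = c("G1", "anaphase")[(i %% 2) + 1],
        amplitude = fit$amplitude, sd_nm = fit$sd_nm,
        normalized_intensity = normalized_intensity(fit$amplitude,
                                                    config$divisor),
        copies_total = cp$copies_total,
        copies_per_kt = cp$copies_per_kinetochore,
        true_copies_per_kt = copies)
    }
    tab <- do.call(rbind, rows)
    kept <- tab[tab$sd_nm < config$sd_max_nm, , drop = FALSE]
    f <- file.path(config$out_dir, "spots.csv")
    write_tables(kept, f)
    files <- c(files, spots = f)
    message(sprintf("quantify: %d/%d spots kept by the %g nm size filter",
                    nrow(kept), nrow(tab), config$sd_max_nm))
  }
  if ("frap" %in% stage) {
    rows <- lapply(seq_len(6), function(i) {
      tr <- frap_series_truth(post_frac = 0.2,
                              plateau_frac = c(0.6, 0.3)[(i %% 2) + 1])
      ser <- simulate_frap_series(tr, seed = config$seed * 2000 + i)
      cur <- frap_curve(ser$time_min, ser$intensity)
      data.frame(cell_id = i,
                 group = c("wt", "mutant")[(i %% 2) + 1],
                 percent_recovery = percent_recovery(cur)$percent)
    })
    f <- file.path(config$out_dir, "frap_recovery.csv")
    write_tables(do.call(rbind, rows), f)
    files <- c(files, frap = f)
  }
  if ("cylinder" %in% stage) {
    spec <- cylinder_spec()
    prof <- forward_profile(spec)
    est <- estimate_diameter(prof, spec$psf, n_mc = 0)
    f <- file.path(config$out_dir, "cylinder_fit.json")
    jsonlite::write_json(
      list(true_diameter_nm = spec$diameter,
           estimated_diameter_nm = est$diameter_nm,
           lobe_separation_nm = lobe_separation(prof)),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, cylinder = f)
  }
  prov <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed,
         package = "kinspa",
         version = as.character(utils::packageVersion("kinspa"))),
    prov, auto_unbox = TRUE, digits = NA)
  files <- c(files, provenance = prov)
  invisible(files)
}
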
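## Default pipeline parameters; every defaulted value is recorded in the
## run manifest so any run can be reconstructed exactly.
default_config <- function() {
  list(
    preprocess = list(register = FALSE, reference_frame = 1L, max_shift = 3L,
                      denoise = FALSE, spatial_sigma = NULL, range_sigma = 30),
    geometry = list(threshold = NULL, percentile = NULL, min_voxels = 10L,
                    snap_radius = 3L, spur_mm = 3, eps = 1),
    flowquant = list(upsample_factor = 10L, cutoff_hz = 0.1, order = 4L,
                     qc_fraction = 0.05, slope_min = 0.005, method = "ols"),
    seed = 1L
  )
}

merge_config <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]]) && is.list(user[[nm]]))
      user[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    else if (is.null(user[[nm]]))
      user[nm] <- defaults[nm]
  }
  user
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[flowtrace] stage=%s elapsed=%.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full distal-flow quantification pipeline
#'
#' Sequences the stages: load (or synthesize) the 4D volume, optional frame
#' registration and bilateral denoising, temporal MIP, vessel segmentation
#' (threshold or supplied mask), optional ROI restriction, skeletonization,
#' marker-guided path assembly, TAC conditioning, QC, cross-correlation
#' delay estimation, per-segment velocity fits, and flow-pattern
#' classification. All outputs (paths and delays CSV, segments JSON, pattern
#' JSON, manifest JSON) are written to the configured output directory; a
#' run is fully determined by its configuration and seed.
#'
#' @param config a configuration list or the path to a JSON configuration
#'   file. Recognized top-level entries: `input` (with `volume`, `sidecar`,
#'   `mask`, `roi`, `markers`) or `phantom` (with `spec`, a file path or
#'   inline spec), `markers` (inline, 0-based voxel indices, overrides the
#'   file), `preprocess`, `geometry`, `flowquant` parameter blocks,
#'   `output_dir`, `seed`.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list: `paths`, `delays`, `segments`, `pattern`,
#'   `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' does not exist", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(config, default_config())
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("no output directory configured")
  qc <- cfg$flowquant$qc_fraction
  if (qc <= 0 || qc >= 1) stop("flowquant.qc_fraction must be in (0, 1)")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  supplied_mask <- NULL; roi <- NULL; phantom <- NULL
  if (!is.null(cfg$phantom)) {
    spec <- cfg$phantom$spec
    phantom_spec_obj <- if (is.character(spec)) {
      if (!file.exists(spec)) stop(sprintf("phantom spec '%s' does not exist", spec))
      read_phantom_spec(spec)
    } else phantom_spec_from_list(spec)
    dyn <- stage("phantom", render_dynamic(phantom_spec_obj))
    phantom <- phantom_spec_obj
  } else {
    inp <- cfg$input
    if (is.null(inp$volume)) stop("config needs input.volume or a phantom block")
    if (!file.exists(inp$volume))
      stop(sprintf("input volume '%s' does not exist", inp$volume))
    dyn <- stage("load", read_dynamic_cta(inp$volume, inp$sidecar))
    if (!is.null(inp$mask)) supplied_mask <- read_mask(inp$mask)
    if (!is.null(inp$roi)) roi <- read_mask(inp$roi)
  }

  markers <- if (!is.null(cfg$markers)) {
    m <- cfg$markers
    distal <- m$distal
    if (is.matrix(distal)) distal <- asplit(distal, 1) else
      if (!is.list(distal)) distal <- list(distal)
    marker_set(unlist(m$proximal) + 1L, unlist(m$thrombus) + 1L,
               lapply(distal, function(v) unlist(v) + 1L))
  } else {
    mf <- cfg$input$markers
    if (is.null(mf)) stop("no markers given (config 'markers' or input.markers file)")
    if (!file.exists(mf)) stop(sprintf("markers file '%s' does not exist", mf))
    read_markers(mf)
  }

  pp <- cfg$preprocess
  if (isTRUE(pp$register))
    dyn <- stage("register", register_frames(dyn, pp$reference_frame, pp$max_shift))
  if (isTRUE(pp$denoise))
    dyn <- stage("denoise", bilateral_denoise(dyn, pp$spatial_sigma, pp$range_sigma))
  tmip <- stage("tmip", compute_tmip(dyn))

  ge <- cfg$geometry
  mask <- stage("segment", {
    if (!is.null(supplied_mask))
      segment_vessels(tmip, "supplied", mask = supplied_mask)
    else
      segment_vessels(tmip, "threshold", threshold = ge$threshold,
                      percentile = ge$percentile, min_voxels = ge$min_voxels)
  })
  if (!is.null(roi)) mask <- stage("roi", restrict_to_roi(mask, roi))
  graph <- stage("skeletonize", skeletonize(mask, spur_mm = ge$spur_mm))
  paths <- stage("paths",
                 assemble_paths(tmip, graph, markers,
                                snap_radius = ge$snap_radius, eps = ge$eps))

  fq <- cfg$flowquant
  delays_all <- list(); fits <- list(); flags <- character(0)
  fitted_segments <- character(0)
  for (p in seq_along(paths)) {
    pa <- paths[[p]]
    tacs <- stage(sprintf("tacs[%d]", p), extract_tacs(dyn, pa))
    del <- stage(sprintf("delays[%d]", p),
                 compute_delays(tacs, fq$upsample_factor, fq$cutoff_hz,
                                fq$order, fq$qc_fraction))
    delays_all[[p]] <- cbind(path_id = p, segment_id = pa$segment_id, del)
    prof <- delay_profile(pa, del)
    flags <- c(flags, prof$flags)
    for (s in names(prof$series)) {
      if (s %in% fitted_segments) next  # shared segments fitted once
      fitted_segments <- c(fitted_segments, s)
      fits[[length(fits) + 1L]] <-
        fit_segment_velocity(prof$series[[s]], path_id = p, segment_id = s,
                             slope_min = fq$slope_min, method = fq$method)
    }
  }
  delays <- do.call(rbind, delays_all)
  segments <- if (length(fits)) do.call(rbind, fits) else
    fit_segment_velocity(data.frame(arclength_mm = numeric(0),
                                    delay_s = numeric(0)))[0, ]
  pattern <- stage("classify", classify_pattern(segments))

  od <- cfg$output_dir
  files <- list(paths = file.path(od, "paths.csv"),
                delays = file.path(od, "delays.csv"),
                segments = file.path(od, "segments.json"),
                pattern = file.path(od, "pattern.json"),
                manifest = file.path(od, "manifest.json"))
  write_paths_csv(paths, files$paths)
  write.csv(delays, files$delays, row.names = FALSE)
  jsonlite::write_json(segments, files$segments, dataframe = "rows",
                       digits = NA, na = "null")
  jsonlite::write_json(list(pattern = pattern$pattern,
                            daughters = pattern$daughters,
                            notes = c(pattern$notes, flags)),
                       files$pattern, auto_unbox = TRUE, dataframe = "rows",
                       digits = NA, na = "null")
  manifest <- cfg
  manifest$output_dir <- NULL   # runs are comparable across output locations
  manifest$package_version <- as.character(utils::packageVersion("flowtrace"))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(list(paths = paths, delays = delays, segments = segments,
                 pattern = pattern, files = files))
}

#' Generate and write a phantom data set
#'
#' Renders the synthetic 4D volume described by a phantom spec and writes
#' the volume (NIfTI + dt sidecar), the ground-truth vessel mask (uint8
#' NIfTI) and the centerline ground truth (CSV with per-point arc-length,
#' arrival time and segment velocity).
#'
#' @param spec a [phantom_spec()] or path to a phantom spec JSON file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the list of written file paths.
#' @export
make_phantom <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  raster <- rasterize_tree(spec)
  dyn <- render_dynamic(spec, raster)
  files <- list(volume = file.path(out_dir, "volume.nii.gz"),
                sidecar = file.path(out_dir, "volume.json"),
                mask = file.path(out_dir, "mask.nii.gz"),
                truth = file.path(out_dir, "ground_truth.csv"),
                spec = file.path(out_dir, "phantom_spec.json"))
  write_dynamic_cta(dyn, files$volume, files$sidecar)
  write_mask(raster$mask, files$mask)
  write.csv(raster$centerline, files$truth, row.names = FALSE)
  write_phantom_spec(spec, files$spec)
  invisible(files)
}
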
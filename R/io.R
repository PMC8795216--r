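#' Read a 4D dynamic CTA volume from NIfTI
#'
#' Spacing is taken from the NIfTI header; the frame interval comes from the
#' header's 4th pixdim entry unless a JSON sidecar (`{"dt_s": ...}`) is
#' given, which takes precedence.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param sidecar optional JSON sidecar path with the frame interval.
#' @return A [dynamic_cta()].
#' @export
read_dynamic_cta <- function(path, sidecar = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop(sprintf("'%s' is not a 4D volume", path))
  pd <- RNifti::pixdim(img)
  dt <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else NA_real_
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$dt_s)) dt <- as.numeric(sc$dt_s)
  }
  if (is.na(dt) || dt <= 0)
    stop("frame interval not found in header or sidecar")
  dynamic_cta(array(as.numeric(img), d), spacing = pd[1:3], dt = dt)
}

#' Write a 4D dynamic CTA volume as NIfTI plus JSON sidecar
#'
#' @param dyn a [dynamic_cta()].
#' @param path output NIfTI path (.nii.gz).
#' @param sidecar output JSON sidecar path; default replaces the NIfTI
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_dynamic_cta <- function(dyn, path, sidecar = NULL) {
  stopifnot(inherits(dyn, "dynamic_cta"))
  img <- RNifti::asNifti(dyn$data)
  RNifti::pixdim(img) <- c(dyn$spacing, dyn$dt)
  RNifti::writeNifti(img, path)
  if (is.null(sidecar))
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(dt_s = dyn$dt, spacing_mm = dyn$spacing),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a vessel mask as NIfTI (uint8)
#'
#' @param path NIfTI file.
#' @return A [vessel_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop(sprintf("'%s' is not a 3D volume", path))
  pd <- RNifti::pixdim(img)
  vessel_mask(array(img != 0, dim(img)), spacing = pd[1:3])
}

#' @param mask a [vessel_mask()].
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read reference markers from JSON
#'
#' The file format uses 0-based voxel indices
#' (`{"proximal": [i,j,k], "thrombus": [i,j,k], "distal": [[i,j,k], ...]}`);
#' they are converted to R's 1-based indexing on load.
#'
#' @param path JSON file.
#' @return A [marker_set()].
#' @export
read_markers <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$proximal) || is.null(m$thrombus) || is.null(m$distal))
    stop(sprintf("markers file '%s' must contain proximal, thrombus and distal", path))
  distal <- m$distal
  if (is.matrix(distal)) distal <- asplit(distal, 1) else
    if (!is.list(distal)) distal <- list(distal)
  marker_set(unlist(m$proximal) + 1L, unlist(m$thrombus) + 1L,
             lapply(distal, function(v) unlist(v) + 1L))
}

#' Read or write a phantom specification as JSON
#'
#' @param path JSON file.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path))
    stop(sprintf("phantom spec file '%s' does not exist", path))
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_spec_from_list(s)
}

phantom_spec_from_list <- function(s) {
  segs <- s$segments
  if (is.data.frame(segs)) segs <- split(segs, seq_len(nrow(segs)))
  segs <- lapply(segs, function(x) {
    vessel_segment(unlist(x$start_mm), unlist(x$end_mm), x$radius_mm,
                   x$velocity_mm_s,
                   inlet_arrival_s = x$inlet_arrival_s %||% 0,
                   enhancement = x$enhancement %||% 1,
                   static = isTRUE(x$static), name = x$name %||% NULL)
  })
  b <- s$bolus %||% list()
  phantom_spec(grid_shape = unlist(s$grid_shape),
               spacing = unlist(s$spacing %||% c(1, 1, 1)),
               dt = s$dt %||% 2, n_frames = s$n_frames %||% 30,
               segments = unname(segs),
               bolus = bolus_spec(b$amplitude_hu %||% 400,
                                  b$t_peak_s %||% 6, b$shape_alpha %||% 3),
               noise_sigma = s$noise_sigma %||% 10,
               background_hu = s$background_hu %||% 40,
               seed = s$seed %||% 1L)
}

#' @param spec a [phantom_spec()].
#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  segs <- lapply(spec$segments, function(s)
    list(start_mm = s$start_mm, end_mm = s$end_mm, radius_mm = s$radius_mm,
         velocity_mm_s = s$velocity_mm_s, inlet_arrival_s = s$inlet_arrival_s,
         enhancement = s$enhancement, static = s$static, name = s$name))
  jsonlite::write_json(
    list(grid_shape = spec$grid_shape, spacing = spec$spacing, dt = spec$dt,
         n_frames = spec$n_frames, segments = segs,
         bolus = unclass(spec$bolus), noise_sigma = spec$noise_sigma,
         background_hu = spec$background_hu, seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export centerline paths as CSV
#'
#' One row per path voxel: `path_id, ordinal, i, j, k, arclength_mm, label,
#' segment_id` (voxel indices written 0-based, matching the marker files).
#'
#' @param paths list of `centerline_path` data.frames.
#' @param path output CSV file.
#' @export
write_paths_csv <- function(paths, path) {
  df <- do.call(rbind, lapply(paths, as.data.frame))
  df$i <- df$i - 1L; df$j <- df$j - 1L; df$k <- df$k - 1L
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
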
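#' Gamma-variate bolus model
#'
#' First-pass contrast concentration is modelled with the standard
#' gamma-variate curve
#' \deqn{C(\tau) = A (\tau/t_p)^\alpha \exp(\alpha (1 - \tau/t_p))}
#' for \eqn{\tau > 0} and 0 otherwise, normalized so that the peak value is
#' `A` at \eqn{\tau = t_p}.
#'
#' @param tau time since bolus arrival (s); vectorized.
#' @param amplitude_hu peak enhancement A (HU).
#' @param t_peak_s time to peak (s).
#' @param shape_alpha shape exponent.
#' @return Enhancement in HU, same length as `tau`.
#' @export
gamma_variate <- function(tau, amplitude_hu = 400, t_peak_s = 6, shape_alpha = 3) {
  out <- numeric(length(tau))
  pos <- tau > 0
  r <- tau[pos] / t_peak_s
  out[pos] <- amplitude_hu * r^shape_alpha * exp(shape_alpha * (1 - r))
  out
}

#' Bolus specification
#'
#' @param amplitude_hu peak enhancement (HU), > 0.
#' @param t_peak_s time to peak (s), > 0.
#' @param shape_alpha gamma-variate shape exponent, > 0.
#' @return An object of class `bolus_spec`.
#' @export
bolus_spec <- function(amplitude_hu = 400, t_peak_s = 6, shape_alpha = 3) {
  if (amplitude_hu <= 0) stop("'amplitude_hu' must be > 0")
  if (t_peak_s <= 0) stop("'t_peak_s' must be > 0")
  if (shape_alpha <= 0) stop("'shape_alpha' must be > 0")
  structure(list(amplitude_hu = amplitude_hu, t_peak_s = t_peak_s,
                 shape_alpha = shape_alpha), class = "bolus_spec")
}

#' Vessel segment specification
#'
#' A straight tube between two world-coordinate points, with a signed
#' contrast propagation velocity. Positive velocity means contrast enters at
#' `start_mm` and travels toward `end_mm` (anterograde, away from the tree
#' root); negative velocity means contrast enters at `end_mm` and travels
#' back toward `start_mm` (retrograde, as with leptomeningeal collateral
#' supply). `inlet_arrival_s` is the bolus arrival time at whichever end the
#' contrast enters. `enhancement` scales the local contrast amplitude in
#' `[0, 1]`; values < 1 emulate a permeable thrombus sub-interval whose
#' in-thrombus attenuation stays below the proximal level.
#'
#' @param start_mm,end_mm 3D world coordinates (mm).
#' @param radius_mm tube radius (mm).
#' @param velocity_mm_s signed propagation speed (mm/s); 0 only with
#'   `static = TRUE` (instantaneous enhancement of the whole segment).
#' @param inlet_arrival_s bolus arrival time (s) at the contrast-entry end.
#' @param enhancement amplitude scale factor in `[0, 1]`.
#' @param static logical; a static segment enhances everywhere at
#'   `inlet_arrival_s` with no transport.
#' @param name optional segment label.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(start_mm, end_mm, radius_mm, velocity_mm_s,
                           inlet_arrival_s = 0, enhancement = 1,
                           static = FALSE, name = NULL) {
  start_mm <- as.numeric(start_mm); end_mm <- as.numeric(end_mm)
  if (length(start_mm) != 3L || length(end_mm) != 3L)
    stop("'start_mm' and 'end_mm' must be 3D points")
  L <- sqrt(sum((end_mm - start_mm)^2))
  if (L <= 0) stop("segment length must be > 0")
  if (radius_mm <= 0) stop("'radius_mm' must be > 0")
  if (!static && velocity_mm_s == 0)
    stop("'velocity_mm_s' must be non-zero unless static = TRUE")
  if (enhancement < 0 || enhancement > 1)
    stop("'enhancement' must be in [0, 1]")
  structure(list(start_mm = start_mm, end_mm = end_mm, radius_mm = radius_mm,
                 velocity_mm_s = velocity_mm_s,
                 inlet_arrival_s = inlet_arrival_s,
                 enhancement = enhancement, static = static,
                 length_mm = L, name = name),
            class = "vessel_segment")
}

#' Phantom specification
#'
#' Full description of a synthetic vascular tree, bolus model, noise and
#' sampling, from which a 4D dynamic CTA volume with exact ground truth can
#' be rendered. Defaults mirror typical clinical dynamic CTA sampling
#' (2 s frame interval, 30 frames) at reduced grid size.
#'
#' Segments must form a connected tree: the first segment is the root, and
#' every later segment must start (or end) at an endpoint of an earlier
#' segment. The tube radius must be at least the largest voxel spacing so
#' that the tube is resolvable on the grid.
#'
#' @param grid_shape integer length-3, voxel counts (nx, ny, nz).
#' @param spacing voxel spacing (mm), length 3.
#' @param dt frame interval (s).
#' @param n_frames number of frames (>= 2).
#' @param segments list of [vessel_segment()] forming a connected tree.
#' @param bolus a [bolus_spec()].
#' @param noise_sigma SD of additive Gaussian noise (HU), >= 0.
#' @param background_hu baseline attenuation (HU).
#' @param vessel_hu_peak peak contrast enhancement (HU); overrides the bolus
#'   amplitude when given.
#' @param seed integer RNG seed for the noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing = c(1, 1, 1), dt = 2,
                         n_frames = 30, segments, bolus = bolus_spec(),
                         noise_sigma = 10, background_hu = 40,
                         vessel_hu_peak = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("'grid_shape' must be 3 voxel counts >= 2")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (dt <= 0) stop("'dt' must be > 0")
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (!length(segments)) segments <- list()
  if (!all(vapply(segments, inherits, TRUE, "vessel_segment")))
    stop("'segments' must be a list of vessel_segment objects")
  if (!is.null(vessel_hu_peak)) bolus$amplitude_hu <- vessel_hu_peak
  spec <- structure(list(grid_shape = grid_shape, spacing = spacing,
                         dt = dt, n_frames = as.integer(n_frames),
                         segments = segments, bolus = bolus,
                         noise_sigma = noise_sigma,
                         background_hu = background_hu,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_tree(spec)
  spec
}

## checks resolvability, grid containment and tree connectivity;
## returns per-segment arc-length from the tree root at the segment start
validate_phantom_tree <- function(spec) {
  segs <- spec$segments
  if (!length(segs)) return(numeric(0))
  ext <- (spec$grid_shape - 1L) * spec$spacing
  root_dist <- numeric(length(segs))
  ends <- list()  # endpoints seen so far with their root distance
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$radius_mm < max(spec$spacing))
      stop(sprintf("segment %d: radius %.3g mm is below the largest voxel spacing %.3g mm (not resolvable)",
                   i, s$radius_mm, max(spec$spacing)))
    for (p in list(s$start_mm, s$end_mm))
      if (any(p < 0) || any(p > ext))
        stop(sprintf("segment %d lies outside the grid (point %s mm, grid extent %s mm)",
                     i, paste(signif(p, 4), collapse = ","),
                     paste(signif(ext, 4), collapse = ",")))
    if (i == 1L) {
      root_dist[i] <- 0
    } else {
      hit <- NA_real_
      for (e in ends) {
        if (sqrt(sum((s$start_mm - e$pt)^2)) < 1e-6) { hit <- e$d; break }
      }
      if (is.na(hit))
        stop(sprintf("segment %d does not start at an endpoint of an earlier segment; the tree must be connected", i))
      root_dist[i] <- hit
    }
    ends <- c(ends, list(list(pt = s$start_mm, d = root_dist[i]),
                         list(pt = s$end_mm, d = root_dist[i] + s$length_mm)))
  }
  root_dist
}

#' Rasterize a phantom vascular tree
#'
#' Produces the binary vessel mask (a voxel is foreground iff its center lies
#' within `radius_mm` of any segment axis) and the exact centerline ground
#' truth sampled at the smallest voxel spacing, with per-point arc-length
#' from the tree root and bolus arrival time.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `mask` (a [vessel_mask()]), `centerline` (data.frame:
#'   segment_id, x_mm, y_mm, z_mm, arc_mm within segment, root_dist_mm,
#'   arrival_s, velocity_mm_s), and internal nearest-segment fields used by
#'   [arrival_time_field()].
#' @export
rasterize_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  root_dist <- validate_phantom_tree(spec)
  d <- spec$grid_shape
  sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  mask <- array(FALSE, d)
  best_d <- array(Inf, d)
  seg_id <- array(NA_integer_, d)
  seg_s <- array(NA_real_, d)   # arc-length from segment start (mm)
  cl <- vector("list", length(spec$segments))
  step <- min(sp)
  for (i in seq_along(spec$segments)) {
    s <- spec$segments[[i]]
    a <- s$start_mm; b <- s$end_mm; L <- s$length_mm
    u <- (b - a) / L
    t <- (X - a[1]) * u[1] + (Y - a[2]) * u[2] + (Z - a[3]) * u[3]
    t <- pmin(pmax(t, 0), L)
    dist <- sqrt((X - (a[1] + t * u[1]))^2 +
                 (Y - (a[2] + t * u[2]))^2 +
                 (Z - (a[3] + t * u[3]))^2)
    inside <- dist <= s$radius_mm
    mask <- mask | inside
    upd <- inside & (dist < best_d)
    best_d[upd] <- dist[upd]
    seg_id[upd] <- i
    seg_s[upd] <- t[upd]
    svals <- seq(0, L, by = step)
    if (svals[length(svals)] < L) svals <- c(svals, L)
    cl[[i]] <- data.frame(
      segment_id = i,
      x_mm = a[1] + svals * u[1], y_mm = a[2] + svals * u[2],
      z_mm = a[3] + svals * u[3],
      arc_mm = svals,
      root_dist_mm = root_dist[i] + svals,
      arrival_s = segment_arrival(s, svals),
      velocity_mm_s = s$velocity_mm_s)
  }
  centerline <- if (length(cl)) do.call(rbind, cl) else
    data.frame(segment_id = integer(0), x_mm = numeric(0), y_mm = numeric(0),
               z_mm = numeric(0), arc_mm = numeric(0),
               root_dist_mm = numeric(0), arrival_s = numeric(0),
               velocity_mm_s = numeric(0))
  list(mask = vessel_mask(mask, sp), centerline = centerline,
       seg_id = seg_id, seg_s = seg_s)
}

## arrival time at arc-length s (from segment start) for one segment
segment_arrival <- function(seg, s_mm) {
  if (seg$static) return(rep(seg$inlet_arrival_s, length(s_mm)))
  if (seg$velocity_mm_s > 0)
    seg$inlet_arrival_s + s_mm / seg$velocity_mm_s
  else
    seg$inlet_arrival_s + (seg$length_mm - s_mm) / abs(seg$velocity_mm_s)
}

#' Ground-truth bolus arrival time field
#'
#' For every mask voxel, the time at which the contrast bolus front reaches
#' it: `inlet_arrival_s + s / |v|`, with `s` the arc-length from the
#' contrast-entry end of its segment. For retrograde segments the entry end
#' is the distal end, so arrival decreases toward the root; along any
#' segment the derivative of arrival with respect to root distance is the
#' signed `1 / velocity_mm_s`.
#'
#' @param spec a [phantom_spec()].
#' @param raster optional result of [rasterize_tree()] (recomputed if absent).
#' @return 3D numeric array of arrival times (s), `NA` outside the mask.
#' @export
arrival_time_field <- function(spec, raster = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(raster)) raster <- rasterize_tree(spec)
  arr <- array(NA_real_, spec$grid_shape)
  for (i in seq_along(spec$segments)) {
    sel <- which(raster$seg_id == i)
    if (!length(sel)) next
    arr[sel] <- segment_arrival(spec$segments[[i]], raster$seg_s[sel])
  }
  arr
}

#' Render a synthetic 4D dynamic CTA volume
#'
#' Voxel value at frame `k` (time `(k-1)*dt`) is
#' `background_hu + [in mask] * enhancement * bolus(t - arrival) + noise`.
#' The noise stream is drawn from a private RNG seeded with `spec$seed`, so
#' two renders of the same spec are bit-identical and the session RNG state
#' is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @param raster optional result of [rasterize_tree()].
#' @return A [dynamic_cta()]; the rasterization is attached as
#'   `attr(, "raster")` and the arrival field as `attr(, "arrival")`.
#' @export
render_dynamic <- function(spec, raster = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(raster)) raster <- rasterize_tree(spec)
  arrival <- arrival_time_field(spec, raster)
  d <- spec$grid_shape
  nt <- spec$n_frames
  enh <- array(0, d)
  for (i in seq_along(spec$segments)) {
    sel <- which(raster$seg_id == i)
    if (length(sel)) enh[sel] <- spec$segments[[i]]$enhancement
  }
  inmask <- which(!is.na(arrival))
  arr <- array(spec$background_hu, c(d, nt))
  nvox <- prod(d)
  b <- spec$bolus
  for (k in seq_len(nt)) {
    t <- (k - 1) * spec$dt
    vals <- gamma_variate(t - arrival[inmask], b$amplitude_hu, b$t_peak_s,
                          b$shape_alpha)
    arr[(k - 1L) * nvox + inmask] <- spec$background_hu +
      enh[inmask] * vals
  }
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sigma), dim(arr))
  }
  dyn <- dynamic_cta(arr, spec$spacing, spec$dt)
  attr(dyn, "raster") <- raster
  attr(dyn, "arrival") <- arrival
  dyn
}
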
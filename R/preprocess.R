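#' 4D dynamic CTA container
#'
#' Wraps a 4D Hounsfield-unit array indexed `(x, y, z, t)` together with its
#' voxel spacing, frame interval and world origin. Frame `k` (1-based in R)
#' occurs at time `(k - 1) * dt` seconds; world coordinates of voxel
#' `(i, j, k)` are `origin + (index - 1) * spacing`.
#'
#' @param data 4D numeric array of attenuation values (HU), axes x, y, z, t.
#' @param spacing numeric length-3, voxel spacing in mm (must be > 0).
#' @param dt frame interval in seconds (must be > 0).
#' @param origin world coordinates (mm) of voxel (1, 1, 1).
#' @return An object of class `dynamic_cta`.
#' @export
dynamic_cta <- function(data, spacing, dt, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a dynamic CTA needs at least 2 frames")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive frame interval (s)")
  structure(list(data = data, spacing = spacing, dt = as.numeric(dt),
                 origin = as.numeric(origin)),
            class = "dynamic_cta")
}

#' @export
print.dynamic_cta <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_cta> %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, dt %.3g s\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$dt))
  invisible(x)
}

#' Static 3D volume container
#'
#' A 3D scalar volume (e.g. a temporal MIP) on the same grid as the dynamic
#' series it was derived from.
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm.
#' @param origin world coordinates (mm) of voxel (1, 1, 1).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Temporal maximum intensity projection
#'
#' Collapses the time axis by taking, for every voxel, the maximum
#' attenuation over all frames. Vessels appear at their peak enhancement,
#' which makes the t-MIP the natural substrate for vessel segmentation and
#' intensity-guided path finding.
#'
#' @param dyn a [dynamic_cta()].
#' @return A [volume3d()] with the voxelwise temporal maximum.
#' @export
compute_tmip <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_cta"))
  nt <- dim(dyn$data)[4]
  m <- dyn$data[, , , 1, drop = TRUE]
  dim(m) <- dim(dyn$data)[1:3]
  for (k in seq_len(nt)[-1]) {
    fr <- dyn$data[, , , k, drop = TRUE]
    dim(fr) <- dim(m)
    m <- pmax(m, fr)
  }
  volume3d(m, dyn$spacing, dyn$origin)
}

## integer-shift a 3D array; exposed voxels filled with `fill`
shift_array3 <- function(a, s, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      if (s[ax] >= d[ax]) return(out)
      dst[[ax]] <- (1L + s[ax]):d[ax]
      src[[ax]] <- 1L:(d[ax] - s[ax])
    } else {
      if (-s[ax] >= d[ax]) return(out)
      dst[[ax]] <- 1L:(d[ax] + s[ax])
      src[[ax]] <- (1L - s[ax]):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Align frames by translation
#'
#' Registers every frame of a dynamic series to a reference frame by
#' exhaustive search over integer voxel translations, maximizing the Pearson
#' correlation on the overlapping region. Head motion between dynamic CTA
#' frames is typically sub-voxel to a few voxels, so translation-only
#' alignment suffices for delay estimation; pre-registered data can skip this
#' step entirely.
#'
#' @param dyn a [dynamic_cta()].
#' @param reference_frame 1-based index of the reference frame.
#' @param max_shift maximum translation searched, in voxels per axis.
#' @param min_gain a non-zero shift is applied only if it improves the
#'   correlation over the unshifted frame by at least this much.
#' @param min_cor a non-zero shift additionally requires the best correlation
#'   to reach this level; frames sharing no structure with the reference
#'   (e.g. pre-bolus noise) are left alone rather than shifted to a spurious
#'   correlation maximum.
#' @return A [dynamic_cta()] with aligned frames; the per-frame shifts that
#'   were applied are available as `attr(, "shifts")` (frames x 3 matrix).
#' @export
register_frames <- function(dyn, reference_frame = 1L, max_shift = 3L,
                            min_gain = 0.05, min_cor = 0.2) {
  stopifnot(inherits(dyn, "dynamic_cta"))
  nt <- dim(dyn$data)[4]
  if (reference_frame < 1L || reference_frame > nt)
    stop("'reference_frame' out of range")
  ref <- dyn$data[, , , reference_frame, drop = TRUE]
  dim(ref) <- dim(dyn$data)[1:3]
  shifts <- matrix(0L, nt, 3L,
                   dimnames = list(NULL, c("dx", "dy", "dz")))
  offs <- as.matrix(expand.grid(dx = -max_shift:max_shift,
                                dy = -max_shift:max_shift,
                                dz = -max_shift:max_shift))
  out <- dyn$data
  ref_sd <- sd(ref)
  for (k in seq_len(nt)) {
    if (k == reference_frame) next
    fr <- dyn$data[, , , k, drop = TRUE]
    dim(fr) <- dim(ref)
    if (ref_sd == 0 || sd(fr) == 0) {
      warning(sprintf("frame %d or reference is constant; shift set to 0", k))
      next
    }
    best <- c(0L, 0L, 0L); best_cor <- -Inf
    for (r in seq_len(nrow(offs))) {
      s <- offs[r, ]
      sh <- shift_array3(fr, s)
      ok <- !is.na(sh)
      if (sum(ok) < 8L) next
      cc <- suppressWarnings(stats::cor(sh[ok], ref[ok]))
      if (is.na(cc)) next
      ## prefer the smaller translation on exact ties
      if (cc > best_cor + 1e-12 ||
          (abs(cc - best_cor) <= 1e-12 && sum(s^2) < sum(best^2))) {
        best_cor <- cc; best <- s
      }
    }
    cor0 <- suppressWarnings(stats::cor(as.numeric(fr), as.numeric(ref)))
    if (is.na(cor0) || best_cor - cor0 < min_gain || best_cor < min_cor)
      best <- c(0L, 0L, 0L)
    shifts[k, ] <- best
    if (any(best != 0L)) {
      sh <- shift_array3(fr, best, fill = NA_real_)
      sh[is.na(sh)] <- median(fr)
      out[, , , k] <- sh
    }
  }
  res <- dynamic_cta(out, dyn$spacing, dyn$dt, dyn$origin)
  attr(res, "shifts") <- shifts
  res
}

#' Edge-preserving bilateral denoising
#'
#' Smooths a volume (or every frame of a dynamic series) with a bilateral
#' filter: each output voxel is a weighted mean of its neighbours, with
#' weights that decay both with spatial distance (Gaussian, `spatial_sigma`
#' in mm) and with intensity difference (Gaussian, `range_sigma` in HU). The
#' range term prevents smoothing across vessel/tissue edges, which would blur
#' the very attenuation contrasts that delay estimation relies on. With
#' `range_sigma = Inf` the filter degenerates to plain truncated-Gaussian
#' smoothing.
#'
#' @param x a [volume3d()] or [dynamic_cta()].
#' @param spatial_sigma spatial kernel width in mm; default one voxel
#'   (the largest spacing component).
#' @param range_sigma intensity kernel width in HU.
#' @return The same type as `x`, smoothed.
#' @export
bilateral_denoise <- function(x, spatial_sigma = NULL, range_sigma = 30) {
  if (inherits(x, "dynamic_cta")) {
    out <- x$data
    for (k in seq_len(dim(x$data)[4])) {
      fr <- x$data[, , , k, drop = TRUE]
      dim(fr) <- dim(x$data)[1:3]
      out[, , , k] <- bilateral3(fr, x$spacing, spatial_sigma, range_sigma)
    }
    return(dynamic_cta(out, x$spacing, x$dt, x$origin))
  }
  stopifnot(inherits(x, "volume3d"))
  volume3d(bilateral3(x$data, x$spacing, spatial_sigma, range_sigma),
           x$spacing, x$origin)
}

bilateral3 <- function(a, spacing, spatial_sigma, range_sigma) {
  if (is.null(spatial_sigma)) spatial_sigma <- max(spacing)
  if (!is.numeric(spatial_sigma) || spatial_sigma <= 0)
    stop("'spatial_sigma' must be > 0 (mm)")
  if (!is.numeric(range_sigma) || range_sigma <= 0)
    stop("'range_sigma' must be > 0 (HU)")
  rad <- pmax(1L, as.integer(ceiling(2 * spatial_sigma / spacing)))
  num <- array(0, dim(a))
  den <- array(0, dim(a))
  for (ox in -rad[1]:rad[1]) for (oy in -rad[2]:rad[2]) for (oz in -rad[3]:rad[3]) {
    d2 <- sum((c(ox, oy, oz) * spacing)^2)
    ws <- exp(-d2 / (2 * spatial_sigma^2))
    sh <- shift_array3(a, c(ox, oy, oz))
    ok <- !is.na(sh)
    if (is.finite(range_sigma)) {
      w <- ws * exp(-(sh - a)^2 / (2 * range_sigma^2))
    } else {
      w <- array(ws, dim(a))
    }
    w[!ok] <- 0
    sh[!ok] <- 0
    num <- num + w * sh
    den <- den + w
  }
  num / den
}
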
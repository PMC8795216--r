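#' Time attenuation curve
#'
#' One voxel's attenuation versus time. Raw TACs live on the native frame
#' grid; [condition_tac()] turns them into interpolated, low-pass-filtered,
#' baseline-subtracted curves suitable for delay estimation.
#'
#' @param times sample times (s), strictly increasing.
#' @param values attenuation (HU), same length as `times`.
#' @param voxel voxel index `c(i, j, k)`.
#' @param arclength_mm arc-length from the proximal marker (mm).
#' @param state `"raw"` or `"conditioned"`.
#' @return An object of class `tac`.
#' @export
tac <- function(times, values, voxel = NULL, arclength_mm = NA_real_,
                state = "raw") {
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 voxel = voxel, arclength_mm = arclength_mm, state = state),
            class = "tac")
}

#' Extract TACs along a centerline path
#'
#' @param dyn a [dynamic_cta()].
#' @param path a `centerline_path` from [assemble_paths()] or
#'   [min_cost_path()].
#' @return A list of raw [tac()] objects, one per path voxel, each carrying
#'   its arc-length from the proximal marker.
#' @export
extract_tacs <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_cta"))
  d <- dim(dyn$data)
  if (any(path$i < 1 | path$i > d[1] | path$j < 1 | path$j > d[2] |
          path$k < 1 | path$k > d[3]))
    stop("path contains voxels outside the volume")
  times <- (seq_len(d[4]) - 1) * dyn$dt
  lapply(seq_len(nrow(path)), function(r) {
    tac(times, dyn$data[path$i[r], path$j[r], path$k[r], ],
        voxel = c(path$i[r], path$j[r], path$k[r]),
        arclength_mm = path$arclength_mm[r])
  })
}

#' Condition a TAC for delay estimation
#'
#' Subtracts the pre-arrival baseline (mean of the native frames before the
#' curve first rises above 10% of its range), resamples the curve to
#' `dt / upsample_factor` by cubic spline interpolation, and applies a
#' zero-phase (forward-backward) Butterworth low-pass filter. Zero-phase
#' filtering is essential: any filter phase delay would masquerade as a flow
#' delay. The default 0.1 Hz cutoff is far above the sub-0.05 Hz content of
#' a first-pass bolus, so the bolus shape is untouched while frame-to-frame
#' noise is suppressed.
#'
#' @param x a raw [tac()].
#' @param upsample_factor integer >= 1; temporal upsampling factor.
#' @param cutoff_hz low-pass cutoff (Hz); must be below the Nyquist
#'   frequency of the upsampled grid.
#' @param order Butterworth filter order.
#' @return A conditioned [tac()] on the upsampled grid.
#' @export
condition_tac <- function(x, upsample_factor = 10L, cutoff_hz = 0.1,
                          order = 4L) {
  stopifnot(inherits(x, "tac"))
  if (!identical(x$state, "raw")) stop("'x' must be a raw TAC")
  upsample_factor <- as.integer(upsample_factor)
  if (upsample_factor < 1L) stop("'upsample_factor' must be >= 1")
  dt <- x$times[2] - x$times[1]
  dtu <- dt / upsample_factor
  nyq <- 1 / (2 * dtu)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3g Hz is at or above the upsampled Nyquist %.3g Hz",
                 cutoff_hz, nyq))
  v <- x$values
  rng <- diff(range(v))
  if (rng > 0) {
    thr <- min(v) + 0.1 * rng
    first_up <- which(v > thr)[1]
    base <- if (!is.na(first_up) && first_up > 1L)
      mean(v[seq_len(first_up - 1L)]) else v[1]
  } else base <- v[1]
  v <- v - base
  tu <- seq(x$times[1], x$times[length(x$times)], by = dtu)
  vu <- if (upsample_factor == 1L) v else
    spline(x$times, v, xout = tu, method = "natural")$y
  ## zero-phase Butterworth; edge-replicate padding suppresses the
  ## forward-backward filter's startup transients
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  npad <- min(length(vu), as.integer(ceiling(2 / (cutoff_hz * dtu))))
  vp <- c(rep(vu[1], npad), vu, rep(vu[length(vu)], npad))
  vf <- signal::filtfilt(bf, vp)[npad + seq_along(vu)]
  tac(tu, vf, voxel = x$voxel, arclength_mm = x$arclength_mm,
      state = "conditioned")
}

#' Quality-control discard of weakly enhancing TACs
#'
#' Flags TACs whose maximum is less than a fraction (default 5%) of the most
#' proximal TAC's maximum; such voxels received too little contrast for a
#' reliable delay estimate. The comparison is strict: a TAC at exactly the
#' threshold is kept.
#'
#' @param tacs list of conditioned [tac()] objects.
#' @param proximal_reference the conditioned proximal reference [tac()].
#' @param fraction discard threshold as a fraction of the reference maximum.
#' @return `tacs` with a logical `valid` attribute per element (and a
#'   `qc_reason` on discarded ones).
#' @export
qc_discard <- function(tacs, proximal_reference, fraction = 0.05) {
  ref_max <- max(proximal_reference$values)
  if (ref_max <= 0)
    stop("proximal reference TAC has non-positive maximum; cannot apply QC")
  thr <- fraction * ref_max
  lapply(tacs, function(t) {
    ok <- max(t$values) >= thr
    attr(t, "valid") <- ok
    if (!ok)
      attr(t, "qc_reason") <- sprintf("max %.3g HU < %.3g%% of proximal max %.3g HU",
                                      max(t$values), 100 * fraction, ref_max)
    t
  })
}

#' Cross-correlation time delay between two TACs
#'
#' The delay is the lag maximizing the normalized (Pearson) cross-correlation
#' over the overlapping support, optionally refined to sub-sample precision
#' by quadratic interpolation through the peak and its two neighbours.
#' Positive delay means `x` lags the reference (later bolus arrival).
#' Normalization makes the estimate invariant to positive amplitude scaling.
#'
#' @param x a conditioned [tac()].
#' @param reference the conditioned reference [tac()], on the same time grid.
#' @param max_lag_s lag search bound (s); default half the record duration.
#' @param refine logical; quadratic sub-sample peak refinement.
#' @return A list of class `delay_point`: `delay_s`, `correlation_peak`,
#'   `valid`, `arclength_mm`, and a `reason` when invalid.
#' @export
xcorr_delay <- function(x, reference, max_lag_s = NULL, refine = TRUE) {
  stopifnot(inherits(x, "tac"), inherits(reference, "tac"))
  n <- length(x$values)
  if (n != length(reference$values))
    stop("TAC and reference must be on the same time grid")
  dtg <- x$times[2] - x$times[1]
  if (is.null(max_lag_s)) max_lag_s <- (x$times[n] - x$times[1]) / 2
  bad <- function(reason) structure(
    list(delay_s = NA_real_, correlation_peak = NA_real_, valid = FALSE,
         arclength_mm = x$arclength_mm, reason = reason),
    class = "delay_point")
  if (var(x$values) == 0) return(bad("zero-variance TAC"))
  if (var(reference$values) == 0) return(bad("zero-variance reference"))
  L <- min(n - 3L, as.integer(floor(max_lag_s / dtg)))
  if (L < 0L) return(bad("record too short for the lag search"))
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- x$values[(1 + l):n]; b <- reference$values[1:(n - l)]
    } else {
      a <- x$values[1:(n + l)]; b <- reference$values[(1 - l):n]
    }
    if (length(a) < 3L) return(NA_real_)
    sa <- sd(a); sb <- sd(b)
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1)
  if (all(is.na(cc))) return(bad("no valid lag"))
  peak <- max(cc, na.rm = TRUE)
  at <- which(!is.na(cc) & cc >= peak - 1e-12)
  ## tie-break: smallest |lag|, then the smaller (more negative) lag
  at <- at[order(abs(lags[at]), lags[at])][1]
  delay <- lags[at] * dtg
  if (refine && at > 1L && at < length(lags) &&
      !is.na(cc[at - 1]) && !is.na(cc[at + 1])) {
    den <- cc[at - 1] - 2 * cc[at] + cc[at + 1]
    if (den < 0) {
      frac <- 0.5 * (cc[at - 1] - cc[at + 1]) / den
      frac <- max(-0.5, min(0.5, frac))
      delay <- delay + frac * dtg
    }
  }
  structure(list(delay_s = delay, correlation_peak = cc[at], valid = TRUE,
                 arclength_mm = x$arclength_mm, reason = NA_character_),
            class = "delay_point")
}

#' Delay estimates for every voxel along a path
#'
#' Convenience wrapper: conditions the raw TACs, applies the QC discard rule
#' against the most proximal voxel's TAC, and estimates each voxel's delay
#' relative to that reference.
#'
#' @param tacs list of raw [tac()]s from [extract_tacs()] (ordered from the
#'   proximal marker).
#' @param upsample_factor,cutoff_hz,order passed to [condition_tac()].
#' @param qc_fraction passed to [qc_discard()].
#' @param max_lag_s,refine passed to [xcorr_delay()].
#' @return A data.frame: `arclength_mm`, `delay_s`, `valid`, `corr_peak`,
#'   `reason`.
#' @export
compute_delays <- function(tacs, upsample_factor = 10L, cutoff_hz = 0.1,
                           order = 4L, qc_fraction = 0.05, max_lag_s = NULL,
                           refine = TRUE) {
  cond <- lapply(tacs, condition_tac, upsample_factor = upsample_factor,
                 cutoff_hz = cutoff_hz, order = order)
  ref <- cond[[1]]
  cond <- qc_discard(cond, ref, qc_fraction)
  rows <- lapply(cond, function(t) {
    if (!isTRUE(attr(t, "valid")))
      return(data.frame(arclength_mm = t$arclength_mm, delay_s = NA_real_,
                        valid = FALSE, corr_peak = NA_real_,
                        reason = attr(t, "qc_reason")))
    dp <- xcorr_delay(t, ref, max_lag_s = max_lag_s, refine = refine)
    data.frame(arclength_mm = t$arclength_mm, delay_s = dp$delay_s,
               valid = dp$valid, corr_peak = dp$correlation_peak,
               reason = if (dp$valid) NA_character_ else dp$reason)
  })
  do.call(rbind, rows)
}

#' Per-segment delay-versus-distance profiles
#'
#' Groups the valid delay points of a path by mother/daughter segment,
#' excluding invalid points, and flags segments with fewer than 3 valid
#' points (too few for a regression).
#'
#' @param path a `centerline_path` with `segment_id` labels (from
#'   [assemble_paths()]).
#' @param delays data.frame from [compute_delays()], one row per path voxel.
#' @return A list with `series` (named list of data.frames `arclength_mm`,
#'   `delay_s` per segment) and `flags` (segments excluded for having < 3
#'   valid points).
#' @export
delay_profile <- function(path, delays) {
  if (nrow(path) != nrow(delays))
    stop("'delays' must have one row per path voxel")
  seg <- path$segment_id
  fit_segs <- unique(seg[seg == "mother" | grepl("^daughter", seg)])
  series <- list(); flags <- character(0)
  for (s in fit_segs) {
    sel <- seg == s & delays$valid
    df <- data.frame(arclength_mm = delays$arclength_mm[sel],
                     delay_s = delays$delay_s[sel])
    df <- df[order(df$arclength_mm), , drop = FALSE]
    if (nrow(df) < 3L) {
      flags <- c(flags, sprintf("segment '%s': only %d valid points, excluded from fitting",
                                s, nrow(df)))
    } else {
      series[[s]] <- df
    }
  }
  list(series = series, flags = flags)
}

#' Fit a per-segment velocity
#'
#' Regresses delay (s) on arc-length (mm); the inverse of the slope is the
#' average contrast velocity along the segment (mm/s), signed: positive
#' slope (delay increasing with distance) means anterograde flow, negative
#' slope retrograde flow. Slopes inside the dead-band `slope_min` are
#' reported as unresolved: at a 2 s frame interval over typical (<= 100 mm)
#' path lengths, shallower slopes are below the temporal quantization floor
#' and their sign is noise.
#'
#' @param series data.frame with `arclength_mm` and `delay_s`.
#' @param path_id,segment_id identifiers carried into the result.
#' @param slope_min direction dead-band (s/mm).
#' @param method `"ols"` or `"theilsen"` (median of pairwise slopes; robust
#'   to outlier-heavy profiles).
#' @return A one-row data.frame of class `segment_flow`: `path_id`,
#'   `segment_id`, `slope_s_per_mm`, `velocity_mm_s`, `direction`,
#'   `n_points`, `r_squared`, `residual_sd_s`.
#' @export
fit_segment_velocity <- function(series, path_id = NA, segment_id = NA,
                                 slope_min = 0.005,
                                 method = c("ols", "theilsen")) {
  method <- match.arg(method)
  n <- nrow(series)
  mk <- function(slope, direction, r2, rsd) {
    data.frame(path_id = path_id, segment_id = segment_id,
               slope_s_per_mm = slope,
               velocity_mm_s = if (is.na(slope)) NA_real_ else 1 / slope,
               direction = direction, n_points = n,
               r_squared = r2, residual_sd_s = rsd,
               stringsAsFactors = FALSE)
  }
  if (n < 3L)
    return(mk(NA_real_, "unresolved", NA_real_, NA_real_))
  if (method == "ols") {
    fit <- lm(delay_s ~ arclength_mm, data = series)
    slope <- unname(coef(fit)[2])
    res <- stats::residuals(fit)
    sst <- sum((series$delay_s - mean(series$delay_s))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
    rsd <- sd(res)
  } else {
    ij <- utils::combn(n, 2)
    dx <- series$arclength_mm[ij[2, ]] - series$arclength_mm[ij[1, ]]
    dy <- series$delay_s[ij[2, ]] - series$delay_s[ij[1, ]]
    ok <- dx != 0
    slope <- median(dy[ok] / dx[ok])
    inter <- median(series$delay_s - slope * series$arclength_mm)
    res <- series$delay_s - inter - slope * series$arclength_mm
    sst <- sum((series$delay_s - mean(series$delay_s))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
    rsd <- sd(res)
  }
  if (is.na(slope)) return(mk(NA_real_, "unresolved", r2, rsd))
  dir <- if (slope > slope_min) "anterograde"
         else if (slope < -slope_min) "retrograde"
         else "unresolved"
  mk(slope, dir, r2, rsd)
}

#' Classify the distal flow pattern
#'
#' Votes over the resolved daughter-segment directions: all anterograde is
#' Pattern I (residual flow through a permeable thrombus reaches the distal
#' territory), all retrograde is Pattern II (collateral supply fills the
#' distal branches toward the occlusion), and a mixture is Pattern III.
#' Unresolved segments are listed in the notes and excluded from the vote;
#' with no resolved daughter the result is "indeterminate".
#'
#' @param segment_flows data.frame of stacked [fit_segment_velocity()] rows.
#' @return A list of class `flow_pattern`: `pattern` (`"I"`, `"II"`,
#'   `"III"`, or `"indeterminate"`), `daughters` (the daughter rows), and
#'   `notes`.
#' @export
classify_pattern <- function(segment_flows) {
  d <- segment_flows[grepl("^daughter", segment_flows$segment_id), ,
                     drop = FALSE]
  notes <- character(0)
  unres <- d$segment_id[d$direction == "unresolved"]
  if (length(unres))
    notes <- c(notes, sprintf("unresolved daughter segments excluded from the vote: %s",
                              paste(unique(unres), collapse = ", ")))
  dirs <- unique(d$direction[d$direction %in% c("anterograde", "retrograde")])
  pattern <- if (!length(dirs)) "indeterminate"
    else if (identical(dirs, "anterograde")) "I"
    else if (identical(dirs, "retrograde")) "II"
    else "III"
  structure(list(pattern = pattern, daughters = d, notes = notes),
            class = "flow_pattern")
}

#' @export
print.flow_pattern <- function(x, ...) {
  cat(sprintf("<flow_pattern> Pattern %s\n", x$pattern))
  if (nrow(x$daughters))
    for (r in seq_len(nrow(x$daughters)))
      cat(sprintf("  %s/%s: %s, v = %.3g mm/s (n = %d, R^2 = %.3g)\n",
                  x$daughters$path_id[r], x$daughters$segment_id[r],
                  x$daughters$direction[r], x$daughters$velocity_mm_s[r],
                  x$daughters$n_points[r], x$daughters$r_squared[r]))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
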
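#' Plot a TAC waterfall along a path
#'
#' Draws every voxel's time attenuation curve, colour-graded by arc-length
#' from the proximal marker, so that the bolus front's progression (or
#' regression) along the vessel is visible at a glance.
#'
#' @param tacs list of [tac()] objects (raw or conditioned).
#' @param main plot title.
#' @export
plot_tacs <- function(tacs, main = "Time attenuation curves") {
  stopifnot(length(tacs) > 0)
  arc <- vapply(tacs, function(t) t$arclength_mm, 1)
  cols <- grDevices::hcl.colors(length(tacs), "Zissou 1")[rank(arc, ties.method = "first")]
  ylim <- range(vapply(tacs, function(t) range(t$values), numeric(2)))
  graphics::plot(NA, xlim = range(tacs[[1]]$times), ylim = ylim,
                 xlab = "time [s]", ylab = "attenuation [HU]", main = main)
  for (i in seq_along(tacs))
    graphics::lines(tacs[[i]]$times, tacs[[i]]$values, col = cols[i])
  invisible(NULL)
}

#' Plot delay versus distance with per-segment fits
#'
#' @param delays data.frame from [compute_delays()] (with `segment_id`
#'   column, as written by [run_pipeline()]).
#' @param segments data.frame of per-segment fits.
#' @param main plot title.
#' @export
plot_delay_profile <- function(delays, segments,
                               main = "Time delay vs. distance") {
  ok <- delays$valid & !is.na(delays$delay_s)
  graphics::plot(delays$arclength_mm[ok], delays$delay_s[ok],
                 pch = 16, cex = 0.6, col = "grey30",
                 xlab = "distance from proximal marker [mm]",
                 ylab = "time delay [s]", main = main)
  segs <- segments[!is.na(segments$slope_s_per_mm), , drop = FALSE]
  cols <- grDevices::hcl.colors(max(1L, nrow(segs)), "Dark 3")
  for (r in seq_len(nrow(segs))) {
    sel <- ok & delays$segment_id == segs$segment_id[r]
    if (!any(sel)) next
    xs <- range(delays$arclength_mm[sel])
    fit <- lm(delay_s ~ arclength_mm,
              data = delays[sel, c("arclength_mm", "delay_s")])
    graphics::lines(xs, stats::predict(fit, data.frame(arclength_mm = xs)),
                    col = cols[r], lwd = 2)
    graphics::text(mean(xs), mean(stats::predict(fit, data.frame(arclength_mm = xs))),
                   sprintf("%s: %.3g mm/s", segs$segment_id[r],
                           segs$velocity_mm_s[r]),
                   pos = 3, col = cols[r], cex = 0.8)
  }
  invisible(NULL)
}
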
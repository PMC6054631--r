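#' Plot the ROI intensity trace
#'
#' Mean ROI intensity over time with the bolus (blue) and after-bolus
#' (yellow) windows shaded.
#'
#' @param seq an [image_sequence()].
#' @param roi an [roi_mask()].
#' @param windows optional [analysis_windows()].
#' @return invisibly, the intensity trace.
#' @export
plot_intensity_trace <- function(seq, roi, windows = NULL) {
  y <- roi_intensity_trace(seq, roi)
  t <- seq$frame_times
  graphics::plot(t, y, type = "l", lwd = 1.5, xlab = "time [s]",
                 ylab = "mean ROI intensity [a.u.]",
                 main = "Contrast inflow: ROI intensity")
  shade_windows(t, windows)
  graphics::lines(t, y, lwd = 1.5)
  invisible(y)
}

#' Plot the estimated deformation over time
#'
#' Per-frame mean landmark displacement (solid) with a one-standard-
#' deviation band, windows shaded.
#'
#' @param trace a [displacement_trace()].
#' @param windows optional [analysis_windows()].
#' @param px plot in pixel units instead of mm.
#' @return invisibly, the per-frame means.
#' @export
plot_displacement_trace <- function(trace, windows = NULL, px = FALSE) {
  m <- if (px) trace$per_landmark_px else trace$per_landmark
  mu <- colMeans(m); sdv <- apply(m, 2L, sd)
  t <- trace$frame_times
  graphics::plot(t, mu, type = "n", ylim = range(0, mu + sdv),
                 xlab = "time [s]",
                 ylab = sprintf("estimated deformation [%s]",
                                if (px) "px" else "mm"),
                 main = "Estimated wall deformation (ground truth: none)")
  shade_windows(t, windows)
  graphics::polygon(c(t, rev(t)), c(mu + sdv, rev(pmax(mu - sdv, 0))),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.3))
  graphics::lines(t, mu, lwd = 1.5)
  invisible(mu)
}

#' Overlaid displacement histograms for two groups
#'
#' Histogram comparison of per-landmark window-mean displacements (e.g.
#' straight tube vs one-sided aneurysm during contrast inflow).
#'
#' @param trace a [displacement_trace()] (single-trace variant), or use
#'   `traceB` for the two-structure comparison.
#' @param windows an [analysis_windows()].
#' @param traceB optional second trace.
#' @return invisibly, `NULL`.
#' @export
plot_window_histograms <- function(trace, windows, traceB = NULL) {
  b <- rowMeans(trace$per_landmark[, windows$bolus_frames, drop = FALSE])
  a <- if (is.null(traceB))
    rowMeans(trace$per_landmark[, windows$after_frames, drop = FALSE])
  else rowMeans(traceB$per_landmark[, windows$bolus_frames, drop = FALSE])
  brk <- pretty(c(a, b), 30)
  hb <- graphics::hist(b, breaks = brk, plot = FALSE)
  ha <- graphics::hist(a, breaks = brk, plot = FALSE)
  ylim <- c(0, max(hb$counts, ha$counts))
  lab <- if (is.null(traceB)) c("bolus", "after bolus")
         else c(trace$meta$structure %||% "A", traceB$meta$structure %||% "B")
  graphics::plot(hb, col = grDevices::adjustcolor("steelblue", 0.6),
                 ylim = ylim, xlab = "displacement [mm]",
                 main = "Displacement distributions")
  graphics::plot(ha, col = grDevices::adjustcolor("goldenrod", 0.6),
                 add = TRUE)
  graphics::legend("topright", fill = c("steelblue", "goldenrod"),
                   legend = lab, bty = "n")
  invisible(NULL)
}

shade_windows <- function(t, windows) {
  if (is.null(windows)) return(invisible(NULL))
  usr <- graphics::par("usr")
  shade <- function(frames, col) {
    if (!length(frames)) return()
    graphics::rect(min(t[frames]), usr[3L], max(t[frames]), usr[4L],
                   border = NA, col = grDevices::adjustcolor(col, 0.15))
  }
  shade(windows$bolus_frames, "steelblue")
  shade(windows$after_frames, "goldenrod")
  invisible(NULL)
}
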
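#' Bolus and after-bolus analysis windows
#'
#' Frame-index sets (1-based; the reference frame 1 is never eligible)
#' over which displacements are compared: during contrast-bolus passage
#' versus after bolus decay.
#'
#' @param bolus_frames,after_frames disjoint, non-empty integer frame sets
#'   in `[2, T]`.
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(bolus_frames, after_frames) {
  bolus_frames <- sort(unique(as.integer(bolus_frames)))
  after_frames <- sort(unique(as.integer(after_frames)))
  if (!length(bolus_frames) || !length(after_frames))
    stop("both windows must be non-empty", call. = FALSE)
  if (any(bolus_frames < 2L) || any(after_frames < 2L))
    stop("windows must exclude the reference frame (indices >= 2)",
         call. = FALSE)
  if (length(intersect(bolus_frames, after_frames)))
    stop("bolus and after-bolus windows must be disjoint", call. = FALSE)
  structure(list(bolus_frames = bolus_frames, after_frames = after_frames),
            class = "analysis_windows")
}

#' Derive analysis windows from a bolus profile
#'
#' The bolus window collects frames whose normalized gamma-variate
#' enhancement is at least `bolus_threshold` (default 0.25) of the peak;
#' the after-bolus window collects frames at least three decay constants
#' (`3 * beta`) past the bolus peak whose enhancement has fallen below
#' `after_threshold` (default 0.25, the complement of the bolus rule, so
#' the windows are disjoint by construction).
#'
#' @param profile a [bolus_profile()].
#' @param frame_times acquisition times in seconds (frame 1 = reference).
#' @param bolus_threshold,after_threshold enhancement fractions.
#' @return An [analysis_windows()].
#' @export
derive_windows <- function(profile, frame_times, bolus_threshold = 0.25,
                           after_threshold = 0.25) {
  stopifnot(inherits(profile, "bolus_profile"))
  g <- gamma_variate(frame_times - profile$t_arrival, profile$alpha,
                     profile$beta)
  idx <- seq_along(frame_times)
  bolus <- idx[g >= bolus_threshold & idx >= 2L]
  t_after <- profile$t_arrival + profile$alpha * profile$beta +
    3 * profile$beta
  after <- idx[frame_times >= t_after & g < after_threshold & idx >= 2L]
  after <- setdiff(after, bolus)
  analysis_windows(bolus, after)
}

#' Mean ROI intensity per frame
#'
#' @param seq an [image_sequence()].
#' @param roi an [roi_mask()] matching the frame shape.
#' @return numeric vector, one mean intensity per frame.
#' @export
roi_intensity_trace <- function(seq, roi) {
  stopifnot(inherits(seq, "image_sequence"), inherits(roi, "roi_mask"))
  if (!all(dim(roi$mask) == dim(seq$frames)[1:2]))
    stop("ROI shape does not match the frames", call. = FALSE)
  apply(seq$frames, 3L, function(f) mean(f[roi$mask]))
}

ttest_result <- function(statistic, dof, p, kind, n_units, unit,
                         note = NULL) {
  structure(list(statistic = statistic, dof = dof, p = p, kind = kind,
                 n_units = n_units, unit = unit, note = note),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test (%s): t(%s) = %.4g, p = %.3g\n", x$kind, x$unit,
              paste(format(x$dof), collapse = ", "), x$statistic, x$p))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# paired t on a difference vector, guarding the zero-variance case
paired_t <- function(d) {
  n <- length(d)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, dof = n - 1L, p = 1,
                                  note = "zero variance, zero mean"))
    return(list(t = sign(mean(d)) * Inf, dof = n - 1L, p = 0,
                note = "zero variance of differences"))
  }
  tt <- t.test(d, mu = 0)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, note = NULL)
}

#' Compare bolus vs after-bolus displacement (paired t-test)
#'
#' Tests whether displacements during the bolus window exceed those after
#' bolus decay. Pairing units: `"landmark_mean"` (default) averages each
#' landmark's displacement over each window, giving `N` pairs;
#' `"landmark_frame"` pools landmark-by-frame values after truncating both
#' windows to their common length, pairing by landmark and within-window
#' frame rank. The test is two-sided.
#'
#' @param trace a [displacement_trace()].
#' @param windows an [analysis_windows()].
#' @param unit `"landmark_mean"` or `"landmark_frame"`.
#' @return A `ttest_result` with `statistic`, `dof`, `p`, `kind`,
#'   `n_units`, `unit`; plus attribute `means` with the two window means.
#' @export
window_compare <- function(trace, windows,
                           unit = c("landmark_mean", "landmark_frame")) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(windows, "analysis_windows"))
  unit <- match.arg(unit)
  Tn <- ncol(trace$per_landmark)
  if (max(windows$bolus_frames, windows$after_frames) > Tn)
    stop("window indices exceed the number of frames", call. = FALSE)
  b <- trace$per_landmark[, windows$bolus_frames, drop = FALSE]
  a <- trace$per_landmark[, windows$after_frames, drop = FALSE]
  note <- NULL
  if (unit == "landmark_mean") {
    x <- rowMeans(b); y <- rowMeans(a)
  } else {
    k <- min(ncol(b), ncol(a))
    if (ncol(b) != ncol(a))
      note <- sprintf("windows truncated to %d frames each", k)
    x <- as.vector(b[, seq_len(k)]); y <- as.vector(a[, seq_len(k)])
  }
  res <- paired_t(x - y)
  out <- ttest_result(res$t, res$dof, res$p, "paired", length(x), unit,
                      note = if (is.null(note)) res$note else
                        paste(c(res$note, note), collapse = "; "))
  attr(out, "means") <- c(bolus = mean(x), after = mean(y))
  out
}

#' Compare two structures' displacements (two-sample t-test)
#'
#' Welch (default) or pooled two-sample t-test on per-landmark window-mean
#' displacements of two traces over the same frame window, e.g. one-sided
#' aneurysm vs straight tube during contrast inflow. The two per-unit
#' samples are attached for histogram plotting.
#'
#' @param traceA,traceB [displacement_trace()] objects.
#' @param window integer frame set (e.g. `windows$bolus_frames`).
#' @param kind `"two_sample_welch"` or `"two_sample_pooled"`.
#' @return A `ttest_result`; attribute `samples` holds the two per-landmark
#'   distributions.
#' @export
compare_structures <- function(traceA, traceB, window,
                               kind = c("two_sample_welch",
                                        "two_sample_pooled")) {
  stopifnot(inherits(traceA, "displacement_trace"),
            inherits(traceB, "displacement_trace"))
  kind <- match.arg(kind)
  window <- as.integer(window)
  x <- rowMeans(traceA$per_landmark[, window, drop = FALSE])
  y <- rowMeans(traceB$per_landmark[, window, drop = FALSE])
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least 3 landmarks per group", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    out <- ttest_result(if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                        length(x) + length(y) - 2L, if (eq) 1 else 0,
                        kind, c(length(x), length(y)), "landmark_mean",
                        note = "zero variance in both groups")
  } else {
    tt <- t.test(x, y, var.equal = (kind == "two_sample_pooled"))
    out <- ttest_result(unname(tt$statistic), unname(tt$parameter),
                        tt$p.value, kind, c(length(x), length(y)),
                        "landmark_mean")
  }
  attr(out, "samples") <- list(A = x, B = y)
  out
}

#' Correlate intensity change with estimated deformation
#'
#' Pearson correlation between the absolute first difference of the ROI
#' intensity trace and the per-frame mean displacement, optionally at a
#' frame lag (displacement shifted `lag` frames later than the intensity
#' change). Frame 1 drops out through the differencing.
#'
#' @param intensity_trace numeric, mean ROI intensity per frame (length T).
#' @param displacement_aggregate numeric, mean displacement per frame
#'   (length T), e.g. `colMeans(trace$per_landmark)`.
#' @param lag integer frame lag (default 0).
#' @return Pearson r; `NA` (with a warning) when either series has zero
#'   variance.
#' @export
correlate_intensity_deformation <- function(intensity_trace,
                                            displacement_aggregate,
                                            lag = 0L) {
  stopifnot(length(intensity_trace) == length(displacement_aggregate))
  lag <- as.integer(lag)
  di <- abs(diff(intensity_trace))           # frames 2..T
  dm <- displacement_aggregate[-1L]
  if (lag > 0L) {
    di <- di[seq_len(length(di) - lag)]
    dm <- dm[-seq_len(lag)]
  } else if (lag < 0L) {
    di <- di[-seq_len(-lag)]
    dm <- dm[seq_len(length(dm) + lag)]
  }
  if (sd(di) == 0 || sd(dm) == 0) {
    warning("zero-variance input; correlation undefined")
    return(NA_real_)
  }
  cor(di, dm)
}

#' Summary table over modality, size and structure
#'
#' Aggregates a list of displacement traces into the per-cell summary of a
#' full phantom study: for each (modality, size, structure) cell, the mean
#' and standard deviation across landmarks of the per-landmark window-mean
#' displacement, during and after the bolus.
#'
#' @param traces list of [displacement_trace()] whose `meta` carries
#'   `modality`, `size_mm` and `structure`.
#' @param windows an [analysis_windows()] applied to every trace.
#' @return data frame with columns `modality, size_mm, structure,
#'   mean_bolus, std_bolus, mean_after, std_after` (mm). Missing cells are
#'   simply absent.
#' @export
build_summary <- function(traces, windows) {
  stopifnot(is.list(traces), inherits(windows, "analysis_windows"))
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "displacement_trace"))
    b <- rowMeans(tr$per_landmark[, windows$bolus_frames, drop = FALSE])
    a <- rowMeans(tr$per_landmark[, windows$after_frames, drop = FALSE])
    data.frame(modality = tr$meta$modality %||% NA_character_,
               size_mm = tr$meta$size_mm %||% NA_real_,
               structure = tr$meta$structure %||% tr$roi_label[1L],
               mean_bolus = mean(b), std_bolus = sd(b),
               mean_after = mean(a), std_after = sd(a))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
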
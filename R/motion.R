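#' Propagate landmarks through a transform
#'
#' Maps each reference-frame landmark through a B-spline deformation,
#' preserving order. A landmark outside the transform support is an error
#' naming the landmark index (no extrapolation).
#'
#' @param landmarks a [sample_landmarks()] result.
#' @param transform a [bspline_transform()].
#' @return `N x 2` matrix of propagated world coordinates (mm).
#' @export
propagate_landmarks <- function(landmarks, transform) {
  stopifnot(inherits(landmarks, "landmark_set"))
  bspline_displace(transform, landmark_coords(landmarks))
}

#' Per-landmark, per-frame displacement trace
#'
#' Converts a per-frame list of transforms into the wall-motion measure:
#' for every landmark `n` and frame `t`, the Euclidean distance in mm
#' between the original and the propagated landmark position, plus the
#' same quantity in units of the in-plane pixel spacing.
#'
#' @param landmarks a [sample_landmarks()] result.
#' @param transforms list of [bspline_transform()], one per frame; element
#'   1 must be the identity (the reference frame).
#' @param grid a [grid_spec()] (supplies the in-plane spacing).
#' @param frame_times acquisition times in seconds, one per transform.
#' @param meta optional named list of metadata (structure, modality, size)
#'   carried into summaries.
#' @return An object of class `displacement_trace` with fields
#'   `per_landmark` (N x T, mm), `per_landmark_px`, `frame_times`,
#'   `roi_label`, `spacing`, `meta`.
#' @export
displacement_trace <- function(landmarks, transforms, grid,
                               frame_times = seq_along(transforms) - 1,
                               meta = list()) {
  stopifnot(inherits(landmarks, "landmark_set"), is.list(transforms),
            inherits(grid, "grid_spec"))
  if (!is_identity(transforms[[1L]]))
    stop("transforms[[1]] must be the identity (reference frame)",
         call. = FALSE)
  if (length(frame_times) != length(transforms))
    stop("`frame_times` must match the number of transforms", call. = FALSE)
  p0 <- landmark_coords(landmarks)
  Tn <- length(transforms)
  disp <- matrix(0, nrow(p0), Tn)
  for (i in seq_len(Tn)) {
    if (i > 1L || !is_identity(transforms[[i]])) {
      p <- bspline_displace(transforms[[i]], p0)
      disp[, i] <- sqrt(rowSums((p - p0)^2))
    }
  }
  structure(list(per_landmark = disp,
                 per_landmark_px = disp / grid$spacing[1L],
                 frame_times = as.numeric(frame_times),
                 roi_label = landmarks$points$roi_label,
                 spacing = grid$spacing[1L],
                 meta = meta),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(
    "displacement_trace: %d landmarks x %d frames; mean %.4g mm (%.4g px), max %.4g mm\n",
    nrow(x$per_landmark), ncol(x$per_landmark), mean(x$per_landmark),
    mean(x$per_landmark_px), max(x$per_landmark)))
  invisible(x)
}

# per-frame mean displacement across landmarks (mm)
frame_means <- function(trace) colMeans(trace$per_landmark)

#' Tidy data frame of a displacement trace
#'
#' One row per landmark and frame, the on-disk contract of the report
#' stage: `landmark_id, roi_label, frame, time_s, disp_mm, disp_px`.
#'
#' @param x a [displacement_trace()].
#' @param ... unused.
#' @return data frame in long format.
#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  N <- nrow(x$per_landmark); Tn <- ncol(x$per_landmark)
  data.frame(landmark_id = rep(seq_len(N), times = Tn),
             roi_label = rep(x$roi_label, times = Tn),
             frame = rep(seq_len(Tn), each = N),
             time_s = rep(x$frame_times, each = N),
             disp_mm = as.vector(x$per_landmark),
             disp_px = as.vector(x$per_landmark_px))
}
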
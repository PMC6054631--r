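#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernel pair to a 2D frame with
#' edge-replicate padding and returns `sqrt(Gx^2 + Gy^2)`.
#'
#' @param frame numeric matrix of intensities.
#' @return matrix of gradient magnitudes, same shape.
#' @export
sobel_edges <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a numeric 2D matrix", call. = FALSE)
  if (any(!is.finite(frame))) stop("`frame` must be finite", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  # replicate-pad by one pixel
  p <- frame[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]
  sh <- function(di, dj) p[seq_len(H) + 1L + di, seq_len(W) + 1L + dj]
  # x = column direction, y = row direction
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

#' Region-of-interest mask
#'
#' @param mask logical matrix, `TRUE` inside the ROI; must be non-empty.
#' @param label structure identifier.
#' @param source `"manual_box"` or `"auto_from_provenance"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi", source = "manual_box") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  source <- match.arg(source, c("manual_box", "auto_from_provenance"))
  structure(list(mask = mask, label = label, source = source),
            class = "roi_mask")
}

#' Rectangular ROI from pixel bounds
#'
#' @param grid a [grid_spec()].
#' @param rows,cols integer ranges (1-based, inclusive) of the box.
#' @param label structure identifier.
#' @return An [roi_mask()].
#' @export
roi_box <- function(grid, rows, cols, label = "roi") {
  m <- matrix(FALSE, grid$shape[1L], grid$shape[2L])
  m[min(rows):max(rows), min(cols):max(cols)] <- TRUE
  roi_mask(m, label = label, source = "manual_box")
}

#' Automatic ROI from simulator provenance
#'
#' For simulated sequences, replaces the manual per-structure ROI: the
#' bounding box of the rasterized wall-and-lumen support, dilated by
#' `dilation_mm` on every side (clamped to the image).
#'
#' @param seq an [image_sequence()] carrying simulator provenance.
#' @param dilation_mm dilation of the tight bounding box in mm (default 2).
#' @return An [roi_mask()] with source `"auto_from_provenance"`.
#' @export
auto_roi <- function(seq, dilation_mm = 2) {
  stopifnot(inherits(seq, "image_sequence"))
  prov <- seq$provenance
  if (!is.list(prov) || is.null(prov$geometry))
    stop(paste("sequence has no simulator provenance;",
               "supply a manual ROI via roi_box()"), call. = FALSE)
  maps <- rasterize_structure(prov$geometry, seq$grid)
  support <- maps$lumen + maps$wall > 0
  ri <- range(which(rowSums(support) > 0))
  ci <- range(which(colSums(support) > 0))
  dr <- round(dilation_mm / seq$grid$spacing[2L])
  dc <- round(dilation_mm / seq$grid$spacing[1L])
  rows <- c(max(1L, ri[1L] - dr), min(nrow(support), ri[2L] + dr))
  cols <- c(max(1L, ci[1L] - dc), min(ncol(support), ci[2L] + dc))
  m <- matrix(FALSE, nrow(support), ncol(support))
  m[rows[1L]:rows[2L], cols[1L]:cols[2L]] <- TRUE
  roi_mask(m, label = prov$geometry$kind, source = "auto_from_provenance")
}

#' Sample edge landmarks within an ROI
#'
#' Reproduces the automatic (pseudo-)landmark generation: eligible pixels
#' are ROI pixels whose Sobel magnitude reaches the `threshold_quantile`
#' percentile of magnitudes within the ROI (the recorded edge-threshold
#' rule); `n` of them are drawn uniformly without
#' replacement under the given seed. Ties at the threshold are resolved by
#' row-major pixel order before sampling, and the sampler is fully
#' deterministic for fixed inputs.
#'
#' @param edge_map gradient-magnitude matrix (from [sobel_edges()]).
#' @param roi an [roi_mask()] of the same shape.
#' @param grid a [grid_spec()] giving the world coordinates.
#' @param n number of landmarks (default 150).
#' @param seed integer sampling seed.
#' @param threshold_quantile magnitude percentile within the ROI that
#'   defines "edge points" (default 0.80).
#' @return An object of class `landmark_set`: data frame `points` with
#'   columns `roi_label`, `x_mm`, `y_mm`, `x_px`, `y_px` (0-based pixel
#'   indices of pixel centres), plus the seed and threshold rule.
#' @export
sample_landmarks <- function(edge_map, roi, grid, n = 150L, seed = 1L,
                             threshold_quantile = 0.80) {
  stopifnot(is.matrix(edge_map), inherits(roi, "roi_mask"),
            inherits(grid, "grid_spec"),
            all(dim(edge_map) == dim(roi$mask)))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  thr <- quantile(edge_map[roi$mask], threshold_quantile, names = FALSE,
                  type = 7)
  eligible <- which(roi$mask & edge_map >= thr)        # column-major
  ij <- arrayInd(eligible, dim(edge_map))
  # row-major pixel order (row, then column) as the documented tie-break
  ord <- order(ij[, 1L], ij[, 2L])
  eligible <- eligible[ord]
  if (length(eligible) < n)
    stop(sprintf("only %d eligible edge pixels in ROI '%s' (need %d)",
                 length(eligible), roi$label, n), call. = FALSE)
  sel <- with_seed(derive_seed(seed, "landmarks"),
                   eligible[sample.int(length(eligible), n)])
  ij <- arrayInd(sel, dim(edge_map))
  xy <- px_to_world(grid, cbind(ij[, 2L] - 1L, ij[, 1L] - 1L))
  points <- data.frame(roi_label = roi$label, x_mm = xy[, 1L],
                       y_mm = xy[, 2L], x_px = ij[, 2L] - 1L,
                       y_px = ij[, 1L] - 1L)
  structure(list(points = points, n_requested = n, seed = seed,
                 edge_threshold_rule = sprintf(
                   "magnitude >= %.4g (q%.2f of Sobel magnitude within ROI)",
                   thr, threshold_quantile)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points in ROI '%s' (seed %d)\n  rule: %s\n",
              nrow(x$points), x$points$roi_label[1L], x$seed,
              x$edge_threshold_rule))
  invisible(x)
}

landmark_coords <- function(landmarks) {
  as.matrix(landmarks$points[, c("x_mm", "y_mm")])
}

#' Write landmarks as CSV plus JSON sidecar
#'
#' @param landmarks a [sample_landmarks()] result.
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(landmarks$points, path, row.names = FALSE)
  jsonlite::write_json(list(seed = landmarks$seed,
                            n_requested = landmarks$n_requested,
                            edge_threshold_rule = landmarks$edge_threshold_rule),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
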
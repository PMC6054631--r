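#' Free-form deformation transform with cubic B-splines
#'
#' A dense deformation parameterized by x/y displacements (mm) at a regular
#' control-point grid, interpolated with the cubic B-spline tensor product.
#' The transform maps reference-frame (fixed) world points into the target
#' (moving) frame. It is the identity iff all coefficients are zero.
#'
#' @param grid_origin world position (mm) of control point (0, 0), `c(x, y)`.
#' @param grid_spacing control-point spacing in mm, `c(x, y)` (scalar
#'   recycled).
#' @param grid_shape number of control points per axis, `c(nx, ny)`.
#' @param coef_x,coef_y displacement (mm) at each control point along x and
#'   y, matrices of dim `c(nx, ny)`; default all zero (identity).
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_shape,
                              coef_x = NULL, coef_y = NULL) {
  grid_spacing <- as.numeric(grid_spacing)
  if (length(grid_spacing) == 1L) grid_spacing <- rep(grid_spacing, 2L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 4L))
    stop("`grid_shape` needs at least 4 control points per axis", call. = FALSE)
  if (any(grid_spacing <= 0)) stop("`grid_spacing` must be positive", call. = FALSE)
  z <- matrix(0, grid_shape[1L], grid_shape[2L])
  if (is.null(coef_x)) coef_x <- z
  if (is.null(coef_y)) coef_y <- z
  coef_x <- as.matrix(coef_x); coef_y <- as.matrix(coef_y)
  if (!all(dim(coef_x) == grid_shape) || !all(dim(coef_y) == grid_shape))
    stop("coefficient matrices must have dim `grid_shape`", call. = FALSE)
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = grid_spacing, grid_shape = grid_shape,
                 coef_x = coef_x, coef_y = coef_y),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  mx <- max(abs(c(x$coef_x, x$coef_y)))
  cat(sprintf("bspline_transform: %d x %d control points, spacing (%.3g, %.3g) mm, max |coef| %.4g mm%s\n",
              x$grid_shape[1L], x$grid_shape[2L], x$grid_spacing[1L],
              x$grid_spacing[2L], mx, if (mx == 0) " (identity)" else ""))
  invisible(x)
}

#' Identity transform covering an image grid
#'
#' Builds an all-zero-coefficient transform whose control grid covers the
#' image domain with the margin the cubic basis requires (every image point
#' has a full 4x4 control neighbourhood).
#'
#' @param grid a [grid_spec()] describing the image domain.
#' @param spacing_mm control-point spacing in mm (scalar or `c(x, y)`).
#' @return A [bspline_transform()] with zero coefficients.
#' @export
identity_transform <- function(grid, spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  ax <- grid_axes(grid)
  x0 <- ax$x[1L]; x1 <- ax$x[length(ax$x)]
  y0 <- ax$y[1L]; y1 <- ax$y[length(ax$y)]
  nx <- ceiling((x1 - x0) / spacing_mm[1L]) + 4L
  ny <- ceiling((y1 - y0) / spacing_mm[2L]) + 4L
  bspline_transform(grid_origin = c(x0 - 2 * spacing_mm[1L],
                                    y0 - 2 * spacing_mm[2L]),
                    grid_spacing = spacing_mm,
                    grid_shape = c(nx, ny))
}

is_identity <- function(transform)
  all(transform$coef_x == 0) && all(transform$coef_y == 0)

#' Map points through a B-spline transform
#'
#' Exact tensor-product evaluation of the displacement at arbitrary world
#' points: `p' = p + sum over the 4x4 control neighbourhood of
#' coefficient * B3(u) * B3(v)`.
#'
#' @param transform a [bspline_transform()].
#' @param points numeric `N x 2` matrix (or length-2 vector) of world
#'   coordinates in mm.
#' @return `N x 2` matrix of displaced points (mm). Points outside the
#'   transform support raise an error (no extrapolation).
#' @export
bspline_displace <- function(transform, points) {
  stopifnot(inherits(transform, "bspline_transform"))
  points <- rbind(points)
  storage.mode(points) <- "double"
  cpp_bspline_displace(points, transform$grid_origin, transform$grid_spacing,
                       transform$coef_x, transform$coef_y)
}

# Resample a frame through a transform (cubic interpolation).
# direction "forward": the image CONTENT moves by the transform's
# displacement (resampling through the fixed-point inverse), so a point
# propagated by the same transform tracks the moved content — the
# convention shared with the registration output.
# direction "backward": plain pull-back resampling out(p) = img(p + u(p)).
warp_image <- function(frame, grid, transform,
                       direction = c("forward", "backward")) {
  stopifnot(inherits(transform, "bspline_transform"))
  direction <- match.arg(direction)
  fun <- if (direction == "forward") cpp_warp_image_forward else cpp_warp_image
  fun(frame, grid$origin, grid$spacing, transform$grid_origin,
      transform$grid_spacing, transform$coef_x, transform$coef_y)
}

#' Serialize transforms to JSON
#'
#' @param transforms a [bspline_transform()] or list thereof.
#' @param path output file.
#' @param metadata optional list stored alongside (config echo, convergence
#'   flags).
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path, metadata = NULL) {
  if (inherits(transforms, "bspline_transform")) transforms <- list(transforms)
  payload <- list(
    transforms = lapply(transforms, function(tr) list(
      grid_origin = tr$grid_origin, grid_spacing = tr$grid_spacing,
      grid_shape = tr$grid_shape,
      coef_x = as.vector(tr$coef_x), coef_y = as.vector(tr$coef_y))),
    metadata = metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#' @param path JSON file.
#' @return list with elements `transforms` (list of [bspline_transform()])
#'   and `metadata`.
#' @export
read_transforms <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  trs <- payload$transforms
  if (is.data.frame(trs)) trs <- split(trs, seq_len(nrow(trs)))
  out <- lapply(seq_along(trs), function(i) {
    tr <- as.list(trs[[i]])
    shape <- as.integer(unlist(tr$grid_shape))
    bspline_transform(unlist(tr$grid_origin), unlist(tr$grid_spacing), shape,
                      matrix(unlist(tr$coef_x), shape[1L], shape[2L]),
                      matrix(unlist(tr$coef_y), shape[1L], shape[2L]))
  })
  list(transforms = out, metadata = payload$metadata)
}
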
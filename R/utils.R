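#' @useDynLib phantomflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd t.test cor pt
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic stages of the package go through this, so a seed in a
# config fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label,
# so that e.g. noise, sampling and optimisation never share a stream.
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x)) else as.integer(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("`%s` must be a single %s number",
                        name, if (strict) "positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}

#' Image sampling grid
#'
#' Describes how pixel indices of a 2D frame map to world coordinates in
#' millimetres. Indices are 0-based and refer to pixel centres:
#' `x_mm = origin[1] + j * spacing[1]` for column `j` and
#' `y_mm = origin[2] + i * spacing[2]` for row `i`.
#'
#' @param shape integer length-2, image size as `c(rows, cols)` (H, W).
#' @param spacing numeric length-1 or -2, pixel size in mm as `c(x, y)`;
#'   a scalar is recycled (isotropic in-plane grid).
#' @param origin numeric length-2, world position (mm) of the centre of
#'   pixel `(0, 0)`. Default centres the grid on the world origin.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers c(rows, cols)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive (mm per pixel, c(x, y))", call. = FALSE)
  if (is.null(origin)) {
    # centre of the field of view at world (0, 0)
    origin <- -c((shape[2L] - 1L) * spacing[1L],
                 (shape[1L] - 1L) * spacing[2L]) / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite numbers (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d px, spacing (%.4g, %.4g) mm, origin (%.4g, %.4g) mm\n",
              x$shape[1L], x$shape[2L], x$spacing[1L], x$spacing[2L],
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

# world <-> 0-based pixel coordinates (columns: x, y)
world_to_px <- function(grid, xy) {
  xy <- rbind(xy)
  cbind((xy[, 1L] - grid$origin[1L]) / grid$spacing[1L],
        (xy[, 2L] - grid$origin[2L]) / grid$spacing[2L])
}

px_to_world <- function(grid, ij) {
  ij <- rbind(ij)
  cbind(grid$origin[1L] + ij[, 1L] * grid$spacing[1L],
        grid$origin[2L] + ij[, 2L] * grid$spacing[2L])
}

# world coordinates of every pixel centre: list(x = length-W, y = length-H)
grid_axes <- function(grid) {
  list(x = grid$origin[1L] + (seq_len(grid$shape[2L]) - 1) * grid$spacing[1L],
       y = grid$origin[2L] + (seq_len(grid$shape[1L]) - 1) * grid$spacing[2L])
}
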
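#' Registration configuration
#'
#' Parameters of the multi-resolution free-form-deformation registration.
#' Defaults: a 3-level pyramid (image downsampling 4x / 2x / 1x), a control
#' grid of 8 pixels at the finest level coarsened 4x / 2x / 1x across
#' levels, 32 histogram bins, 200 stochastic-gradient iterations per level
#' with 2048 random samples each.
#'
#' @param pyramid_levels number of resolution levels (default 3).
#' @param grid_spacing_schedule multiplier on the finest control-grid
#'   spacing per level, coarse to fine; length `pyramid_levels`.
#' @param finest_grid_px finest control-point spacing in pixels (>= 2).
#' @param mi_bins histogram bins for the mutual-information metric.
#' @param iterations_per_level optimizer iterations per level.
#' @param step_init initial optimizer step in mm (decays within a level).
#' @param sample_count random metric samples per iteration.
#' @param seed integer seed controlling metric sampling.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(pyramid_levels = 3L,
                                grid_spacing_schedule = NULL,
                                finest_grid_px = 8,
                                mi_bins = 32L,
                                iterations_per_level = 200L,
                                step_init = 0.7,
                                sample_count = 2048L,
                                seed = 1L) {
  pyramid_levels <- as.integer(pyramid_levels)
  if (pyramid_levels < 1L) stop("`pyramid_levels` must be >= 1", call. = FALSE)
  if (is.null(grid_spacing_schedule))
    grid_spacing_schedule <- 2^((pyramid_levels - 1L):0L)
  if (length(grid_spacing_schedule) != pyramid_levels)
    stop("`grid_spacing_schedule` must have one entry per level", call. = FALSE)
  if (finest_grid_px < 2) stop("finest control spacing must be >= 2 px",
                               call. = FALSE)
  stopifnot(mi_bins >= 2, iterations_per_level >= 1, sample_count >= 1,
            step_init > 0)
  structure(list(pyramid_levels = pyramid_levels,
                 grid_spacing_schedule = as.numeric(grid_spacing_schedule),
                 finest_grid_px = finest_grid_px,
                 mi_bins = as.integer(mi_bins),
                 iterations_per_level = as.integer(iterations_per_level),
                 step_init = step_init,
                 sample_count = as.integer(sample_count),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' @export
print.registration_config <- function(x, ...) {
  cat(sprintf(
    "registration_config: %d levels, finest grid %.3g px, %d bins, %d iters x %d samples, seed %d\n",
    x$pyramid_levels, x$finest_grid_px, x$mi_bins, x$iterations_per_level,
    x$sample_count, x$seed))
  invisible(x)
}

# Deterministic, evenly spaced evaluation points (world mm), <= n_max.
# Offset off the pixel centres: sampling exactly on the grid would read
# raw pixel values under the identity but interpolated (noise-smoothed)
# values under any deformation, biasing model selection away from the
# identity (the classic grid-aligned interpolation artifact of MI).
eval_points <- function(grid, n_max = 16384L) {
  H <- grid$shape[1L]; W <- grid$shape[2L]
  stride <- max(1L, ceiling(sqrt(H * W / n_max)))
  ax <- grid_axes(grid)
  xs <- ax$x[seq(1L, W - 1L, by = stride)]
  ys <- ax$y[seq(1L, H - 1L, by = stride)]
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  # Deterministic low-discrepancy (Weyl) subpixel offsets: evaluation at
  # continuous positions avoids the phase-locked degeneracy of regular
  # sampling (for noise-free axis-aligned structures a phase-aligned grid
  # collapses the joint histogram onto a curve, making MI shift-invariant),
  # and the level smoothing keeps interpolation from favouring off-grid
  # candidate transforms on noisy pairs.
  k <- seq_len(nrow(pts))
  pts[, 1L] <- pts[, 1L] + ((k * 0.6180339887) %% 1) * grid$spacing[1L]
  pts[, 2L] <- pts[, 2L] + ((k * 0.7548776662) %% 1) * grid$spacing[2L]
  pts
}

#' Mutual information between two frames under a transform
#'
#' Estimates the mutual information (in bits) between the fixed image
#' sampled at `sample_points` and the moving image sampled at the
#' transformed points, from a joint histogram with hard linear binning over
#' each image's sampled min-max range; sample points falling outside either
#' domain (after transformation) are discarded. Returned negated, as the
#' quantity the registration minimizes.
#'
#' @param fixed,moving numeric matrices of equal size.
#' @param grid a [grid_spec()] shared by both images.
#' @param transform a [bspline_transform()] or `NULL` for identity.
#' @param bins histogram bins (>= 2).
#' @param sample_points `N x 2` world coordinates (mm); default a dense
#'   regular subsample of the grid.
#' @return Negated mutual information (scalar). Attributes `mi`,
#'   `h_fixed`, `h_moving` (bits) and `n_eff` (retained samples) carry the
#'   decomposition. A degenerate intensity range yields 0.
#' @export
mutual_information <- function(fixed, moving, grid, transform = NULL,
                               bins = 32L, sample_points = NULL) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)), inherits(grid, "grid_spec"))
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  if (is.null(sample_points)) sample_points <- eval_points(grid, 16384L)
  sample_points <- rbind(sample_points)
  storage.mode(sample_points) <- "double"
  if (is.null(transform)) {
    res <- cpp_mi_hard(fixed, moving, grid$origin, grid$spacing,
                       sample_points, as.integer(bins),
                       NULL, NULL, NULL, NULL)
  } else {
    stopifnot(inherits(transform, "bspline_transform"))
    res <- cpp_mi_hard(fixed, moving, grid$origin, grid$spacing,
                       sample_points, as.integer(bins),
                       transform$coef_x, transform$coef_y,
                       transform$grid_origin, transform$grid_spacing)
  }
  structure(-res$mi, mi = res$mi, h_fixed = res$h_fixed,
            h_moving = res$h_moving, n_eff = res$n_eff)
}

# Gaussian smooth + subsample a frame by an integer factor. Every level is
# smoothed — the finest included — so the metric compares intrinsically
# smooth images and linear interpolation adds no appreciable extra
# smoothing at off-grid sample positions.
downsample_frame <- function(frame, grid, factor) {
  if (factor == 1L)
    return(list(frame = gaussian_blur(frame, 0.7), grid = grid))
  sm <- gaussian_blur(frame, factor / 2)
  ri <- seq(1L, nrow(frame), by = factor)
  ci <- seq(1L, ncol(frame), by = factor)
  g <- grid_spec(c(length(ri), length(ci)), grid$spacing * factor,
                 origin = grid$origin)
  list(frame = sm[ri, ci, drop = FALSE], grid = g)
}

#' Register one frame pair with multi-resolution FFD
#'
#' Registers `moving` to `fixed` coarse-to-fine: at each pyramid level the
#' images are smoothed and downsampled, the previous level's transform is
#' resampled onto the finer control grid, and the negated Parzen-window
#' mutual information is minimized by stochastic gradient descent with an
#' analytic metric gradient (checkpointed best-iterate acceptance, so the
#' returned transform is never worse than its initialization under the
#' checkpoint evaluation). The result maps fixed-frame points into the
#' moving frame.
#'
#' @param fixed,moving numeric matrices on the same grid.
#' @param grid a [grid_spec()].
#' @param config a [registration_config()].
#' @param seed_offset integer mixed into the config seed (used by
#'   [register_sequence()] to decorrelate frames deterministically).
#' @return A [bspline_transform()] with attribute `metadata`: per-level MI
#'   traces, full-resolution MI of identity vs. result, a `converged`
#'   flag, and mean effective sample counts.
#' @export
register_pair <- function(fixed, moving, grid, config = registration_config(),
                          seed_offset = 0L) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)), inherits(grid, "grid_spec"),
            inherits(config, "registration_config"))
  L <- config$pyramid_levels
  factors <- 2^((L - 1L):0L)
  transform <- NULL
  level_meta <- vector("list", L)
  for (l in seq_len(L)) {
    f <- as.integer(factors[l])
    dsf <- downsample_frame(fixed, grid, f)
    dsm <- downsample_frame(moving, grid, f)
    spacing_mm <- config$finest_grid_px * grid$spacing *
      config$grid_spacing_schedule[l]
    level_t <- identity_transform(grid, spacing_mm)
    if (!is.null(transform)) {
      # initialize from the coarser level: sample its displacement field
      # at the new control points (support-clamped)
      cp <- control_points(level_t)
      disp <- safe_displacement(transform, cp)
      level_t$coef_x <- matrix(disp[, 1L], level_t$grid_shape[1L])
      level_t$coef_y <- matrix(disp[, 2L], level_t$grid_shape[1L])
    }
    with_seed(derive_seed(config$seed, "ffd", seed_offset, l), {
      res <- cpp_ffd_optimize(dsf$frame, dsm$frame, dsf$grid$origin,
                              dsf$grid$spacing, level_t$coef_x,
                              level_t$coef_y, level_t$grid_origin,
                              level_t$grid_spacing, config$mi_bins,
                              config$iterations_per_level,
                              config$sample_count, config$step_init,
                              eval_points(dsf$grid), 20L)
    })
    level_t$coef_x <- res$coef_x
    level_t$coef_y <- res$coef_y
    transform <- level_t
    level_meta[[l]] <- list(factor = f, mi_init = res$mi_init,
                            mi_best = res$mi_best, trace = res$trace,
                            n_eff_mean = res$n_eff_mean)
  }
  # full-resolution acceptance: never return a transform that scores a
  # worse Parzen MI than the identity on the deterministic evaluation set
  ep <- eval_points(grid)
  fx <- downsample_frame(fixed, grid, 1L)$frame
  mv <- downsample_frame(moving, grid, 1L)$frame
  idt <- identity_transform(grid, config$finest_grid_px * grid$spacing)
  mi_id <- cpp_mi_parzen(fx, mv, grid$origin, grid$spacing, ep,
                         config$mi_bins, idt$coef_x, idt$coef_y,
                         idt$grid_origin, idt$grid_spacing)
  mi_fin <- cpp_mi_parzen(fx, mv, grid$origin, grid$spacing, ep,
                          config$mi_bins, transform$coef_x, transform$coef_y,
                          transform$grid_origin, transform$grid_spacing)
  # parsimony rule, as in the per-level selection: a deformation must beat
  # the identity by more than the evaluation noise to be accepted
  kept_identity <- FALSE
  if (mi_fin < mi_id + 0.018) {
    transform <- idt
    mi_fin <- mi_id
    kept_identity <- TRUE
  }
  attr(transform, "metadata") <- list(
    levels = level_meta, mi_identity = mi_id, mi_final = mi_fin,
    kept_identity = kept_identity,
    converged = mi_fin >= mi_id, config = config, seed_offset = seed_offset)
  transform
}

control_points <- function(transform) {
  nx <- transform$grid_shape[1L]; ny <- transform$grid_shape[2L]
  xs <- transform$grid_origin[1L] + (seq_len(nx) - 1) * transform$grid_spacing[1L]
  ys <- transform$grid_origin[2L] + (seq_len(ny) - 1) * transform$grid_spacing[2L]
  # column-major order of the coefficient matrices: x varies fastest
  cbind(rep(xs, times = ny), rep(ys, each = nx))
}

# displacement at points, zero outside the support (used for grid refit)
safe_displacement <- function(transform, pts) {
  n <- nrow(pts)
  out <- matrix(0, n, 2L)
  lo <- transform$grid_origin + transform$grid_spacing
  hi <- transform$grid_origin +
    (transform$grid_shape - 3L) * transform$grid_spacing
  inside <- pts[, 1L] >= lo[1L] & pts[, 1L] <= hi[1L] &
    pts[, 2L] >= lo[2L] & pts[, 2L] <= hi[2L]
  if (any(inside)) {
    disp <- bspline_displace(transform, pts[inside, , drop = FALSE])
    out[inside, ] <- disp - pts[inside, , drop = FALSE]
  }
  out
}

#' Register every frame of a sequence to the first frame
#'
#' Each frame is registered independently to frame 1 (the reference), the
#' standard design for bolus sequences: errors of one frame never propagate
#' to the next, and a convergence flag per frame is collected instead of
#' aborting the sequence.
#'
#' @param seq an [image_sequence()].
#' @param config a [registration_config()].
#' @param verbose print per-frame progress.
#' @return A list of [bspline_transform()] of length `T`; element 1 is the
#'   exact identity. Attribute `metadata` collects per-frame registration
#'   metadata.
#' @export
register_sequence <- function(seq, config = registration_config(),
                              verbose = FALSE) {
  stopifnot(inherits(seq, "image_sequence"))
  Tn <- n_frames(seq)
  fixed <- seq$frames[, , 1L]
  out <- vector("list", Tn)
  out[[1L]] <- identity_transform(seq$grid,
                                  config$finest_grid_px * seq$grid$spacing)
  meta <- vector("list", Tn)
  for (i in 2:Tn) {
    out[[i]] <- register_pair(fixed, seq$frames[, , i], seq$grid, config,
                              seed_offset = i)
    meta[[i]] <- attr(out[[i]], "metadata")
    if (verbose)
      message(sprintf("frame %d/%d: MI %.4f -> %.4f%s", i, Tn,
                      meta[[i]]$mi_identity, meta[[i]]$mi_final,
                      if (meta[[i]]$kept_identity) " (identity kept)" else ""))
  }
  attr(out, "metadata") <- meta
  out
}
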
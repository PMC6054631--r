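# Shared fixtures: built in code, small enough to keep the suite fast.

twist_grid <- function(n = 96L) grid_spec(c(n, n), 1.3)

# noise-free straight-tube sequence on the TWIST grid (cached per session)
tube_sequence <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- render_sequence(
        phantom_geometry("straight_tube", inner_diameter = 4), twist_grid(),
        bolus_profile(), imaging_model("twist_mri", noise_sigma = 0),
        n_frames = 5, seed = 7)
    cache
  }
})

tube_frame <- function() tube_sequence()$frames[, , 1L]

tube_landmarks <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seq0 <- tube_sequence()
      cache <<- sample_landmarks(sobel_edges(tube_frame()), auto_roi(seq0),
                                 seq0$grid, n = 150, seed = 3)
    }
    cache
  }
})

# two-frame container around a single reference frame
two_frame_sequence <- function(frame, grid, provenance = "external") {
  image_sequence(array(rep(frame, 2L), c(dim(frame), 2L)), grid, c(0, 1),
                 provenance = provenance)
}

# independent dense-basis oracle for the cubic B-spline tensor product:
# sums over ALL control points instead of the 4x4 support window
b3 <- function(s) {
  s <- abs(s)
  ifelse(s < 1, (4 - 6 * s^2 + 3 * s^3) / 6,
         ifelse(s < 2, (2 - s)^3 / 6, 0))
}

dense_bspline_displace <- function(transform, pts) {
  nx <- transform$grid_shape[1L]; ny <- transform$grid_shape[2L]
  out <- pts
  for (r in seq_len(nrow(pts))) {
    u <- (pts[r, 1L] - transform$grid_origin[1L]) / transform$grid_spacing[1L]
    v <- (pts[r, 2L] - transform$grid_origin[2L]) / transform$grid_spacing[2L]
    ux <- uy <- 0
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      w <- b3(u - (i - 1L)) * b3(v - (j - 1L))
      ux <- ux + w * transform$coef_x[i, j]
      uy <- uy + w * transform$coef_y[i, j]
    }
    out[r, ] <- pts[r, ] + c(ux, uy)
  }
  out
}

# brute-force joint-histogram mutual information oracle (bits), mirroring
# the module's sampling contract but implemented independently in R
oracle_mi <- function(fixed, moving, grid, pts, bins = 32L,
                      transform = NULL) {
  bilin <- function(img, p) {
    x <- (p[, 1L] - grid$origin[1L]) / grid$spacing[1L]
    y <- (p[, 2L] - grid$origin[2L]) / grid$spacing[2L]
    ok <- x >= 0 & y >= 0 & x <= ncol(img) - 1 & y <= nrow(img) - 1
    j <- pmin(floor(x), ncol(img) - 2); i <- pmin(floor(y), nrow(img) - 2)
    tx <- x - j; ty <- y - i
    v <- (1 - tx) * (1 - ty) * img[cbind(i + 1, j + 1)] +
      tx * (1 - ty) * img[cbind(i + 1, j + 2)] +
      (1 - tx) * ty * img[cbind(i + 2, j + 1)] +
      tx * ty * img[cbind(i + 2, j + 2)]
    v[!ok] <- NA
    v
  }
  fv <- bilin(fixed, pts)
  tp <- if (is.null(transform)) pts else bspline_displace(transform, pts)
  mv <- bilin(moving, tp)
  keep <- !is.na(fv) & !is.na(mv)
  fv <- fv[keep]; mv <- mv[keep]
  if (diff(range(fv)) == 0 || diff(range(mv)) == 0) return(0)
  bin <- function(v) pmin(floor((v - min(v)) / diff(range(v)) * bins), bins - 1L)
  joint <- table(factor(bin(fv), levels = 0:(bins - 1L)),
                 factor(bin(mv), levels = 0:(bins - 1L))) / length(fv)
  pf <- rowSums(joint); pm <- colSums(joint)
  num <- joint / outer(pf, pm)
  sum(ifelse(joint > 0, joint * log2(num), 0))
}
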
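#' Parametric vascular phantom structure
#'
#' Describes one vessel-like structure of the digital flow phantom. Six
#' geometry families are available, mirroring a modular physical flow
#' phantom: a straight tube, a stenosed tube, a planar projection of a
#' helix, a bifurcation, and one- and two-sided saccular aneurysms. All
#' structures are tubes of inner diameter `inner_diameter` with a solid
#' wall of thickness `wall_thickness`; aneurysm kinds add a spherical dome
#' (rendered as a disk in the 2D mid-plane) of diameter `aneurysm_diameter`
#' whose neck opens into the parent tube.
#'
#' The structure is laid out along the world x axis, centred on the world
#' origin. Axial run-through of the image border is intentional (a vessel
#' crossing the field of view); transverse overflow is an error at
#' rasterization time.
#'
#' @param kind one of `"straight_tube"`, `"stenosis"`, `"helix"`,
#'   `"bifurcation"`, `"one_sided_aneurysm"`, `"two_sided_aneurysm"`.
#' @param inner_diameter lumen diameter in mm (typically 2, 3 or 4).
#' @param wall_thickness wall thickness in mm, default 1.
#' @param aneurysm_diameter dome diameter in mm; default twice the inner
#'   diameter. Used only by the aneurysm kinds.
#' @param stenosis_fraction minimum lumen diameter as a fraction of
#'   `inner_diameter`, in (0, 1); stenosis kind only. Default 0.4.
#' @param length axial extent in mm. The default (160 mm) exceeds typical
#'   fields of view so the vessel runs through the image.
#' @return An object of class `phantom_geometry`.
#' @seealso [rasterize_structure()], [structure_signed_distance()]
#' @export
phantom_geometry <- function(kind = c("straight_tube", "stenosis", "helix",
                                      "bifurcation", "one_sided_aneurysm",
                                      "two_sided_aneurysm"),
                             inner_diameter = 4,
                             wall_thickness = 1,
                             aneurysm_diameter = 2 * inner_diameter,
                             stenosis_fraction = 0.4,
                             length = 160) {
  kind <- match.arg(kind)
  stopifnot_scalar_pos(inner_diameter, "inner_diameter")
  stopifnot_scalar_pos(wall_thickness, "wall_thickness")
  stopifnot_scalar_pos(aneurysm_diameter, "aneurysm_diameter")
  stopifnot_scalar_pos(length, "length")
  if (!is.numeric(stenosis_fraction) || length(stenosis_fraction) != 1L ||
      stenosis_fraction <= 0 || stenosis_fraction >= 1)
    stop("`stenosis_fraction` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(kind = kind,
                 inner_diameter = inner_diameter,
                 wall_thickness = wall_thickness,
                 aneurysm_diameter = aneurysm_diameter,
                 stenosis_fraction = stenosis_fraction,
                 length = length),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("phantom_geometry: %s, inner diameter %.3g mm, wall %.3g mm\n",
              x$kind, x$inner_diameter, x$wall_thickness))
  if (grepl("aneurysm", x$kind))
    cat(sprintf("  aneurysm dome diameter %.3g mm\n", x$aneurysm_diameter))
  if (x$kind == "stenosis")
    cat(sprintf("  stenosis fraction %.3g\n", x$stenosis_fraction))
  invisible(x)
}

# signed distance (mm) from points to a capsule (segment a-b with radius r);
# negative inside the lumen
sdf_capsule <- function(x, y, a, b, r) {
  bax <- b[1L] - a[1L]; bay <- b[2L] - a[2L]
  den <- bax * bax + bay * bay
  h <- pmin(pmax(((x - a[1L]) * bax + (y - a[2L]) * bay) / den, 0), 1)
  sqrt((x - (a[1L] + h * bax))^2 + (y - (a[2L] + h * bay))^2) - r
}

sdf_disk <- function(x, y, c, r) sqrt((x - c[1L])^2 + (y - c[2L])^2) - r

#' Signed distance to the lumen of a phantom structure
#'
#' Evaluates, at arbitrary world coordinates, the signed distance in mm to
#' the lumen boundary of a structure: negative inside the lumen, zero on
#' the lumen/wall interface, and equal to `wall_thickness` on the
#' wall/background interface. For the variable-radius kinds (stenosis,
#' helix) the transverse distance `|y - y_c(x)| - r(x)` is used, which is
#' exact for the straight tube and a close approximation where the
#' centerline or radius varies slowly.
#'
#' @param geometry a [phantom_geometry()].
#' @param x,y numeric vectors of equal length, world coordinates in mm.
#' @return numeric vector of signed distances in mm.
#' @export
structure_signed_distance <- function(geometry, x, y) {
  stopifnot(inherits(geometry, "phantom_geometry"), length(x) == length(y))
  R <- geometry$inner_diameter / 2
  L <- geometry$length
  switch(geometry$kind,
    straight_tube = sdf_capsule(x, y, c(-L / 2, 0), c(L / 2, 0), R),
    stenosis = {
      # cosine-tapered throat over an axial extent of 4 diameters
      Ls <- 4 * geometry$inner_diameter
      dip <- ifelse(abs(x) < Ls / 2,
                    0.5 * (1 + cos(pi * x / (Ls / 2))), 0)
      r <- R * (1 - (1 - geometry$stenosis_fraction) * dip)
      d <- abs(y) - r
      pmax(d, abs(x) - L / 2)                     # axial end caps
    },
    helix = {
      # planar projection of a helix: sinusoidally undulating centerline
      A <- geometry$inner_diameter
      lam <- L / 3
      d <- abs(y - A * sin(2 * pi * x / lam)) - R
      pmax(d, abs(x) - L / 2)
    },
    bifurcation = {
      ang <- 25 * pi / 180
      Rb <- 0.8 * R                               # daughter branches
      half <- L / 2
      d1 <- sdf_capsule(x, y, c(-half, 0), c(0, 0), R)
      d2 <- sdf_capsule(x, y, c(0, 0), c(half, half * tan(ang)), Rb)
      d3 <- sdf_capsule(x, y, c(0, 0), c(half, -half * tan(ang)), Rb)
      pmin(d1, d2, d3)
    },
    one_sided_aneurysm = {
      ra <- geometry$aneurysm_diameter / 2
      dt <- sdf_capsule(x, y, c(-L / 2, 0), c(L / 2, 0), R)
      # dome centre set so the neck overlaps the parent lumen by ra/2
      da <- sdf_disk(x, y, c(0, R + ra / 2), ra)
      pmin(dt, da)
    },
    two_sided_aneurysm = {
      ra <- geometry$aneurysm_diameter / 2
      dt <- sdf_capsule(x, y, c(-L / 2, 0), c(L / 2, 0), R)
      pmin(dt,
           sdf_disk(x, y, c(0,  R + ra / 2), ra),
           sdf_disk(x, y, c(0, -R - ra / 2), ra))
    })
}

#' Rasterize a phantom structure into partial-volume maps
#'
#' Computes, for every pixel of a [grid_spec()], the area fraction covered
#' by the lumen and by the wall annulus of a structure, by supersampling
#' each pixel with an `supersample` x `supersample` grid of subpixel
#' centres. The two fractions sum to at most 1 per pixel.
#'
#' @param geometry a [phantom_geometry()].
#' @param grid a [grid_spec()].
#' @param supersample subpixel samples per axis (>= 4).
#' @return A list with matrices `lumen` and `wall` (each `shape[1] x
#'   shape[2]`, values in \[0, 1\]) and the inputs echoed.
#' @details The structure must fit the field of view transversely (wall
#'   included); a structure touching the top or bottom image row is an
#'   error. Axial run-through (left/right borders) is permitted, matching
#'   a vessel crossing the image.
#' @export
rasterize_structure <- function(geometry, grid, supersample = 4L) {
  stopifnot(inherits(geometry, "phantom_geometry"), inherits(grid, "grid_spec"))
  s <- as.integer(supersample)
  if (s < 4L) stop("`supersample` must be >= 4", call. = FALSE)
  H <- grid$shape[1L]; W <- grid$shape[2L]
  ax <- grid_axes(grid)
  off <- ((seq_len(s) - 0.5) / s - 0.5)           # subpixel offsets in px
  xs <- rep(ax$x, each = s) + rep(off * grid$spacing[1L], times = W)
  ys <- rep(ax$y, each = s) + rep(off * grid$spacing[2L], times = H)
  # (H*s) x (W*s) evaluation, rows = y
  X <- matrix(rep(xs, each = H * s), nrow = H * s)
  Y <- matrix(rep(ys, times = W * s), nrow = H * s)
  d <- structure_signed_distance(geometry, as.vector(X), as.vector(Y))
  d <- matrix(d, nrow = H * s)
  pool <- function(m) {
    # mean over s x s blocks
    m1 <- rowsum(m, rep(seq_len(H), each = s)) / s
    t(rowsum(t(m1), rep(seq_len(W), each = s)) / s)
  }
  lumen <- unname(pool((d < 0) * 1))
  wall <- unname(pool((d >= 0 & d < geometry$wall_thickness) * 1))
  if (any(lumen[c(1L, H), ] > 0) || any(wall[c(1L, H), ] > 0))
    stop(sprintf(
      "structure '%s' (inner diameter %.3g mm) exceeds the transverse field of view of a %d x %d grid at %.3g mm spacing",
      geometry$kind, geometry$inner_diameter, H, W, grid$spacing[2L]),
      call. = FALSE)
  list(lumen = lumen, wall = wall, geometry = geometry, grid = grid)
}
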
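#' Write an image sequence as NIfTI
#'
#' Stores the frames as a 3D NIfTI volume (third dimension = time) with
#' the in-plane spacing in the header, plus a JSON provenance sidecar
#' (`<path>.json`) holding grid, frame times and — for simulated data —
#' geometry, bolus profile, imaging model and seed.
#'
#' @param seq an [image_sequence()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  dt <- if (length(seq$frame_times) > 1L) diff(seq$frame_times)[1L] else 1
  img <- RNifti::asNifti(seq$frames,
                         pixdim = c(seq$grid$spacing[2L],
                                    seq$grid$spacing[1L], dt))
  RNifti::writeNifti(img, path)
  prov <- seq$provenance
  side <- list(grid = unclass(seq$grid), frame_times = seq$frame_times,
               provenance = if (is.list(prov)) prov_to_list(prov) else prov)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

prov_to_list <- function(prov) {
  out <- prov
  for (f in c("geometry", "profile", "model"))
    if (!is.null(out[[f]])) out[[f]] <- unclass(out[[f]])
  out$true_transforms <- NULL  # serialized separately via write_transforms()
  out
}

#' Read an image sequence written by [write_sequence()] or external NIfTI
#'
#' @param path NIfTI file. If a `<path>.json` sidecar exists, grid, frame
#'   times and provenance are restored from it; otherwise spacing is taken
#'   from the NIfTI header, frame times from the temporal pixdim, and the
#'   provenance is `"external"`.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume (2D+t sequence)", call. = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    grid <- grid_spec(side$grid$shape, side$grid$spacing, side$grid$origin)
    prov <- side$provenance
    if (is.list(prov)) {
      if (!is.null(prov$geometry))
        prov$geometry <- do.call(phantom_geometry, prov$geometry)
      if (!is.null(prov$profile))
        prov$profile <- do.call(bolus_profile, prov$profile)
      if (!is.null(prov$model)) {
        m <- prov$model
        prov$model <- imaging_model(m$modality, m$spacing, m$psf_sigma,
                                    m$noise_model, m$noise_sigma,
                                    m$background, m$wall_intensity)
      }
    }
    image_sequence(arr, grid, side$frame_times, provenance = prov)
  } else {
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- c(1, 1, 1)
    grid <- grid_spec(dim(arr)[1:2], c(pd[2L], pd[1L]))
    dt <- if (length(pd) >= 3L && pd[3L] > 0) pd[3L] else 1
    image_sequence(arr, grid, (seq_len(dim(arr)[3L]) - 1L) * dt,
                   provenance = "external")
  }
}
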
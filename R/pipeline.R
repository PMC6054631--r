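#' End-to-end run configuration
#'
#' Bundles every stage of a phantom experiment: simulation (or an external
#' sequence path plus manual ROI), landmark generation, registration and
#' the window analysis. Every stochastic stage carries an explicit seed;
#' a config round-trips unchanged through [write_run_config()] /
#' [read_run_config()].
#'
#' @param structure geometry kind (see [phantom_geometry()]), or `NULL`
#'   when `input_path` is given.
#' @param inner_diameter lumen diameter in mm.
#' @param modality imaging preset (see [imaging_model()]).
#' @param n_frames frames to simulate.
#' @param frame_interval seconds between frames.
#' @param image_size pixels per axis of the (square) simulated image.
#' @param bolus named list of [bolus_profile()] overrides (e.g.
#'   `list(gate_depth = 0)`); `static = TRUE` renders a constant lumen
#'   (no bolus, gate off).
#' @param static logical; render a no-bolus control sequence.
#' @param seed master seed; stage seeds derive from it.
#' @param n_landmarks landmarks per ROI (default 150).
#' @param registration a [registration_config()]; its seed is overridden
#'   by the derived stage seed unless set explicitly here.
#' @param windows `NULL` to derive from the bolus profile, or a list
#'   `list(bolus_frames=, after_frames=)`.
#' @param unit pairing unit for the window comparison.
#' @param input_path optional external NIfTI sequence (skips simulation).
#' @param roi optional manual ROI spec `list(rows=, cols=, label=)` for
#'   external sequences.
#' @return An object of class `run_config`.
#' @export
run_config <- function(structure = "one_sided_aneurysm", inner_diameter = 4,
                       modality = "twist_mri", n_frames = 60L,
                       frame_interval = 0.5, image_size = 96L,
                       bolus = list(), static = FALSE, seed = 1L,
                       n_landmarks = 150L,
                       registration = registration_config(),
                       windows = NULL,
                       unit = "landmark_mean",
                       input_path = NULL, roi = NULL) {
  structure(list(structure = structure, inner_diameter = inner_diameter,
                 modality = modality, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 image_size = as.integer(image_size), bolus = bolus,
                 static = isTRUE(static), seed = as.integer(seed),
                 n_landmarks = as.integer(n_landmarks),
                 registration = registration, windows = windows,
                 unit = unit, input_path = input_path, roi = roi),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config a [run_config()].
#' @param path YAML file.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$registration <- unclass(x$registration)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$registration <- do.call(registration_config, x$registration)
  do.call(run_config, x)
}

build_profile <- function(config) {
  if (config$static) {
    base <- bolus_profile(gate_depth = 0)
    args <- utils::modifyList(list(peak = base$baseline, gate_depth = 0),
                              config$bolus)
  } else args <- config$bolus
  do.call(bolus_profile, args)
}

#' Run one phantom experiment end to end
#'
#' simulate (or load) -> Sobel landmarks -> FFD registration -> landmark
#' propagation -> window statistics, writing every artifact to `out_dir`:
#' the sequence (`sequence.nii.gz`), landmarks (`landmarks.csv` + sidecar),
#' transforms (`transforms.json`), the displacement trace (`trace.csv`),
#' the report (`report.json`), diagnostic plots (PNG, best effort) and a
#' `manifest.json` with config echo, stage status and artifact checksums.
#' Re-running an identical config reproduces identical CSV bytes.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the in-memory results (`sequence`,
#'   `landmarks`, `transforms`, `trace`, `windows`, `report`).
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = jsonlite::fromJSON(jsonlite::toJSON(
    prep_config_json(config), auto_unbox = TRUE, digits = NA)),
    package_version = as.character(packageVersion("phantomflow")),
    stages = list())
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    res <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, out_dir)
      stop(sprintf("stage '%s' failed: %s (artifacts so far in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  seq <- stage("simulate", {
    if (!is.null(config$input_path)) {
      read_sequence(config$input_path)
    } else {
      geom <- phantom_geometry(config$structure,
                               inner_diameter = config$inner_diameter)
      model <- imaging_model(config$modality)
      grid <- grid_spec(rep(config$image_size, 2L), model$spacing)
      render_sequence(geom, grid, build_profile(config), model,
                      n_frames = config$n_frames,
                      frame_interval = config$frame_interval,
                      seed = derive_seed(config$seed, "render"))
    }
  })
  stage("write_sequence",
        write_sequence(seq, file.path(out_dir, "sequence.nii.gz")))

  roi <- stage("roi", {
    if (!is.null(config$roi))
      roi_box(seq$grid, config$roi$rows, config$roi$cols,
              label = config$roi$label %||% "roi")
    else auto_roi(seq)
  })

  landmarks <- stage("landmarks", {
    lm <- sample_landmarks(sobel_edges(seq$frames[, , 1L]), roi, seq$grid,
                           n = config$n_landmarks,
                           seed = derive_seed(config$seed, "landmarks"))
    write_landmarks(lm, file.path(out_dir, "landmarks.csv"))
    lm
  })

  transforms <- stage("register", {
    rc <- config$registration
    rc$seed <- derive_seed(config$seed, "register")
    tr <- register_sequence(seq, rc, verbose = verbose)
    write_transforms(tr, file.path(out_dir, "transforms.json"),
                     metadata = list(config = unclass(rc)))
    tr
  })

  trace <- stage("quantify", {
    tr <- displacement_trace(landmarks, transforms, seq$grid,
                             frame_times = seq$frame_times,
                             meta = list(modality = config$modality,
                                         size_mm = config$inner_diameter,
                                         structure = config$structure))
    write.csv(as.data.frame(tr), file.path(out_dir, "trace.csv"),
              row.names = FALSE)
    tr
  })

  report <- stage("report", {
    intensity <- roi_intensity_trace(seq, roi)
    windows <- resolve_windows(config, seq)
    rep <- list(
      n_frames = n_frames(seq),
      mean_disp_px = mean(trace$per_landmark_px),
      max_disp_px = max(trace$per_landmark_px),
      intensity_trace = intensity)
    if (!is.null(windows)) {
      wc <- window_compare(trace, windows, unit = config$unit)
      rep$windows <- unclass(windows)
      rep$window_test <- unclass(wc)
      rep$window_means <- as.list(attr(wc, "means"))
      rep$correlation_r <- correlate_intensity_deformation(
        intensity, frame_means(trace))
    }
    rep$verdict <- if (rep$max_disp_px < 0.05) "no fictitious motion"
                   else "fictitious motion detected"
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    make_report_plots(seq, roi, trace,
                      resolve_windows(config, seq), out_dir, manifest)
    rep
  })

  files <- c("sequence.nii.gz", "landmarks.csv", "transforms.json",
             "trace.csv", "report.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  write_manifest(manifest, out_dir)
  windows <- resolve_windows(config, seq)
  invisible(list(sequence = seq, roi = roi, landmarks = landmarks,
                 transforms = transforms, trace = trace, windows = windows,
                 report = report))
}

prep_config_json <- function(config) {
  x <- unclass(config)
  x$registration <- unclass(x$registration)
  x
}

resolve_windows <- function(config, seq) {
  if (!is.null(config$windows))
    return(analysis_windows(config$windows$bolus_frames,
                            config$windows$after_frames))
  if (config$static || !is.list(seq$provenance) ||
      is.null(seq$provenance$profile)) return(NULL)
  tryCatch(derive_windows(seq$provenance$profile, seq$frame_times),
           error = function(e) NULL)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

# best-effort PNG diagnostics; failure is recorded, never fatal
make_report_plots <- function(seq, roi, trace, windows, out_dir, manifest) {
  tryCatch({
    grDevices::png(file.path(out_dir, "report_plots.png"),
                   width = 1200, height = 800, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    plot_intensity_trace(seq, roi, windows)
    plot_displacement_trace(trace, windows)
    if (!is.null(windows)) plot_window_histograms(trace, windows)
  }, error = function(e) invisible(NULL))
}

#' Run a grid of experiments and assemble the summary table
#'
#' Executes independent [run_experiment()] runs (one per config) into
#' subdirectories of `out_dir` and aggregates their traces with
#' [build_summary()]. A failing cell is recorded in the grid manifest and
#' does not affect the other cells.
#'
#' @param configs non-empty list of [run_config()].
#' @param out_dir output directory.
#' @param windows an [analysis_windows()] for the summary; `NULL` derives
#'   windows from the first successful bolus run.
#' @param verbose print progress.
#' @return The summary data frame (also written to `summary.csv`), with
#'   attribute `failures` naming failed cells.
#' @export
run_grid <- function(configs, out_dir, windows = NULL, verbose = FALSE) {
  if (!is.list(configs) || !length(configs))
    stop("`configs` must be a non-empty list of run_config objects",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- list(); failures <- character()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cell <- sprintf("%s_%gmm_%s_%02d", cfg$modality, cfg$inner_diameter,
                    cfg$structure, i)
    res <- tryCatch(run_experiment(cfg, file.path(out_dir, cell),
                                   verbose = verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cell, conditionMessage(res)))
      next
    }
    traces[[cell]] <- res$trace
    if (is.null(windows) && !is.null(res$windows)) windows <- res$windows
  }
  if (is.null(windows))
    stop("no analysis windows available (all static runs?); supply `windows`",
         call. = FALSE)
  summary <- build_summary(traces, windows)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(cells = names(traces), failures = failures),
                       file.path(out_dir, "grid_manifest.json"),
                       auto_unbox = TRUE)
  attr(summary, "failures") <- failures
  summary
}
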
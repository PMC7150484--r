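#' Read a directory of numbered frames
#'
#' Frames are read in zero-padded filename order (plain lexicographic sort,
#' locale-independent) and rescaled to [0, 1]. PNG and TIFF are supported;
#' multi-channel images are averaged to grayscale.
#'
#' @param path directory containing the frame images.
#' @param pattern filename regexp, default PNG/TIFF extensions.
#' @return list of numeric matrices.
#' @export
read_frame_stack <- function(path, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE), method = "radix")
  # a simulate run writes frames and masks side by side; skip the masks
  files <- files[!grepl("^(mask|track)_", basename(files))]
  if (length(files) == 0L) stop("no frame images found in ", path)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- tryCatch(read_image(files[i]),
                    error = function(e)
                      stop("unreadable frame image: ", files[i],
                           " (", conditionMessage(e), ")"))
    if (i > 1L && !all(dim(img) == dim(frames[[1]])))
      stop("frame shape mismatch at ", files[i])
    frames[[i]] <- img
  }
  frames
}

read_image <- function(file) {
  lower <- tolower(file)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(file)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF frames")
    tiff::readTIFF(file)
  } else stop("unsupported image format: ", file)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  pmin(pmax(img, 0), 1)
}

#' Write frames as zero-padded 8-bit PNG files
#'
#' @param frames list of numeric matrices in [0, 1].
#' @param path output directory (created if needed).
#' @param prefix filename prefix; files are `prefix_%05d.png`, numbered
#'   from 0.
#' @return character vector of written paths, invisibly.
#' @export
write_frames <- function(frames, path, prefix = "frame") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(frames))
  for (i in seq_along(frames)) {
    out[i] <- file.path(path, sprintf("%s_%05d.png", prefix, i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1), out[i])
  }
  invisible(out)
}

#' Write and read binary mask sequences
#'
#' Masks use the 0/255 PNG convention. On read, a gray image is binarized
#' at 128 with a warning; an all-zero mask is preserved.
#'
#' @param masks list of binary 0/1 matrices.
#' @param path directory.
#' @param prefix filename prefix (`prefix_%05d.png`).
#' @return `write_masks`: written paths, invisibly. `read_masks`: list of
#'   0/1 matrices.
#' @export
write_masks <- function(masks, path, prefix = "mask") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(masks))
  for (i in seq_along(masks)) {
    out[i] <- file.path(path, sprintf("%s_%05d.png", prefix, i - 1L))
    png::writePNG((masks[[i]] > 0) * 1, out[i])
  }
  invisible(out)
}

#' @rdname write_masks
#' @param pattern filename regexp for reading.
#' @export
read_masks <- function(path, prefix = "mask", pattern = NULL) {
  if (is.null(pattern)) pattern <- paste0("^", prefix, "_.*\\.png$")
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE),
                method = "radix")
  if (length(files) == 0L) stop("no mask images found in ", path)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    vals <- unique(as.vector(img))
    if (!all(vals %in% c(0, 1))) {
      warning("non-binary mask ", basename(f), ": binarizing at 128/255")
    }
    (img >= 0.5) * 1
  })
}

#' Build a run configuration
#'
#' Programmatic equivalent of the YAML run configuration: a phantom (or a
#' frames directory plus initial mask), preprocessing, tracker, monitor and
#' planner settings, and the seed that owns all randomness of the run.
#'
#' @param phantom `NULL`, or a list of [phantom_config()] arguments.
#' @param frames_dir,init_mask_path input paths when not simulating.
#' @param pixel_spacing_mm pixel size in mm/pixel.
#' @param preprocess list of [preprocess_params()] arguments.
#' @param tracker list of [acwe_params()] arguments, plus the key
#'   `operator` (`"k15"` or `"k3"`) and optional `k15_single_orientation`.
#' @param monitor list of [monitor_state()] arguments plus `enabled`.
#' @param planner list with `spacing_mm` (focus pitch) and
#'   `slice_spacing_mm`.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = list(), frames_dir = NULL,
                       init_mask_path = NULL, pixel_spacing_mm = 0.35,
                       preprocess = list(), tracker = list(),
                       monitor = list(enabled = TRUE),
                       planner = list(spacing_mm = 5, slice_spacing_mm = 5),
                       seed = 1L) {
  cfg <- list(phantom = phantom, frames_dir = frames_dir,
              init_mask_path = init_mask_path,
              pixel_spacing_mm = pixel_spacing_mm,
              preprocess = preprocess, tracker = tracker,
              monitor = monitor, planner = planner, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

known_config_keys <- list(
  top = c("phantom", "frames_dir", "init_mask_path", "pixel_spacing_mm",
          "preprocess", "tracker", "monitor", "planner", "seed"),
  preprocess = c("kappa_radius", "roi_stat_k", "window"),
  tracker = c("mu", "nu", "lambda1", "lambda2", "iters_per_frame",
              "operator", "k15_single_orientation", "overflow_tau",
              "overflow_scope"),
  monitor = c("enabled", "cadence", "mi_threshold", "bins", "search_range",
              "alpha", "stable_checkpoints_required", "template_pad"),
  planner = c("spacing_mm", "slice_spacing_mm"))

#' Read a YAML run configuration
#'
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  reject_unknown <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L)
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  reject_unknown(y, known_config_keys$top, "top level")
  for (sec in c("preprocess", "tracker", "monitor", "planner"))
    if (!is.null(y[[sec]]))
      reject_unknown(y[[sec]], known_config_keys[[sec]], sec)
  do.call(run_config, y)
}

#' Write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

tracker_params_from_config <- function(tr) {
  tr <- tr %||% list()
  op <- tr$operator %||% "k15"
  oset <- if (identical(op, "k3")) k3()
          else k15(single_orientation = tr$k15_single_orientation)
  args <- tr[setdiff(names(tr), c("operator", "k15_single_orientation"))]
  do.call(acwe_params, c(args, list(operator_set = oset)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full guidance pipeline
#'
#' Executes simulate (or load) -> preprocess -> track (with movement
#' monitoring) -> plan -> evaluate, and optionally writes all artifacts:
#' per-frame mask PNGs, `plan.json`, `report.json` and a JSON-lines run
#' log.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param out_dir optional output directory for artifacts.
#' @return list of class `hifu_run`: the `track` (a `hifu_track`), the
#'   `plan` (a `focus_plan`), the `report` (a [tracking_report()], `NULL`
#'   without ground truth), and the resolved `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  truth <- NULL
  if (!is.null(config$frames_dir)) {
    frames <- read_frame_stack(config$frames_dir)
    if (is.null(config$init_mask_path))
      stop("init_mask_path is required when frames_dir is given")
    init <- read_masks(dirname(config$init_mask_path),
                       pattern = paste0("^", basename(config$init_mask_path), "$"))[[1]]
    spacing <- config$pixel_spacing_mm
  } else {
    ph_args <- config$phantom %||% list()
    if (is.null(ph_args$seed)) ph_args$seed <- config$seed
    pc <- do.call(phantom_config, ph_args)
    seq <- generate_phantom_sequence(pc)
    frames <- seq$frames
    truth <- seq$truth_masks
    init <- seq$truth_masks[[1]]
    spacing <- pc$pixel_spacing_mm
  }
  pre <- do.call(preprocess_params, config$preprocess %||% list())
  params <- tracker_params_from_config(config$tracker)
  mon_cfg <- config$monitor %||% list(enabled = TRUE)
  enabled <- mon_cfg$enabled %||% TRUE
  mon_arg <- if (!enabled) FALSE
             else mon_cfg[setdiff(names(mon_cfg), "enabled")]
  if (is.list(mon_arg) && length(mon_arg) == 0L) mon_arg <- TRUE
  track <- track_lesion(frames, init, params = params, pre = pre,
                        monitor = mon_arg, spacing_mm = spacing)
  pl_cfg <- config$planner %||% list()
  plan <- assemble_3d(
    list(list(slice_index = 0L, lesion_mask = track$masks[[length(track$masks)]])),
    slice_spacing_mm = pl_cfg$slice_spacing_mm %||% 5,
    spacing_mm = pl_cfg$spacing_mm %||% 5,
    pixel_spacing_mm = spacing)
  report <- if (!is.null(truth)) tracking_report(track$masks, truth, spacing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_masks(track$masks, file.path(out_dir, "masks"), prefix = "track")
    write_plan_json(plan, file.path(out_dir, "plan.json"))
    if (!is.null(report)) {
      jsonlite::write_json(
        list(per_frame = report$per_frame, summary = report$summary),
        file.path(out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
      utils::write.csv(report$per_frame,
                       file.path(out_dir, "report_per_frame.csv"),
                       row.names = FALSE)
    }
    log_lines <- vapply(seq_len(nrow(track$log)), function(i)
      jsonlite::toJSON(as.list(track$log[i, ]), auto_unbox = TRUE,
                       digits = NA, na = "null"), character(1))
    writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
    contours <- do.call(rbind, lapply(seq_along(track$masks), function(i) {
      b <- boundary_pixels(track$masks[[i]])
      if (nrow(b)) data.frame(frame = i - 1L, row = b[, 1], col = b[, 2])
    }))
    utils::write.csv(contours, file.path(out_dir, "contours.csv"),
                     row.names = FALSE)
  }
  structure(list(track = track, plan = plan, report = report,
                 config = config),
            class = "hifu_run")
}

#' @export
print.hifu_run <- function(x, ...) {
  print(x$track)
  print(x$plan)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
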
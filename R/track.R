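#' Track a lesion through an ultrasound frame sequence
#'
#' The central fitting function of the package. Starting from an initial
#' contour (typically resampled from a preoperative segmentation via
#' [init_from_preop()]), each incoming frame is preprocessed
#' ([preprocess_frame()]), checked for unexpected large movement at the
#' monitor cadence ([check_motion()]), and the binary contour embedding is
#' evolved by guarded MACWE iterations ([evolve_frame()]). While the
#' monitor is alarmed, contour evolution pauses and only the
#' NCC-derived moving force translates the contour; sonication permission
#' is withdrawn until the scene is stable again.
#'
#' @param frames list of numeric matrices in [0, 1] (one per frame).
#' @param init_mask binary 0/1 matrix, the initial contour embedding for
#'   the first frame.
#' @param params an [acwe_params()].
#' @param pre a [preprocess_params()].
#' @param monitor `TRUE` (default) to enable the movement monitor with
#'   default settings, `FALSE` to disable, or a list of arguments passed to
#'   [monitor_state()] (e.g. `list(cadence = 10, mi_threshold = 0.6)`).
#' @param spacing_mm pixel size in mm/pixel (stored for reporting).
#' @return An object of class `hifu_track` with components `masks` (list of
#'   per-frame embeddings), `log` (per-frame data frame: decision, MI,
#'   guard activations, applied shifts, alarm and sonication-permission
#'   flags), `monitor` (final monitor state or `NULL`), `params`, `pre`,
#'   `spacing_mm`, and `frames_pre` (the preprocessed frames).
#' @seealso [tracking_report()] to score against ground truth,
#'   [assemble_3d()] to plan sonication foci on the result.
#' @export
track_lesion <- function(frames, init_mask, params = acwe_params(),
                         pre = preprocess_params(), monitor = TRUE,
                         spacing_mm = 1) {
  stopifnot(length(frames) >= 1L)
  if (sum(init_mask) == 0) stop("initial mask is empty")
  n <- length(frames)
  masks <- vector("list", n)
  frames_pre <- vector("list", n)
  log <- data.frame(frame = seq_len(n) - 1L,
                    decision = "not_checked", mi = NA_real_,
                    guard_activations = 0L, degenerate = FALSE,
                    shift_r = 0L, shift_c = 0L,
                    alarm = FALSE, sonication_permitted = TRUE,
                    stringsAsFactors = FALSE)
  mon <- NULL
  mon_enabled <- !isFALSE(monitor)
  u <- (init_mask > 0) * 1
  for (i in seq_len(n)) {
    t <- i - 1L
    fd <- denoise_morphological(frames[[i]], pre$kappa_radius)
    if (i == 1L && is.null(pre$window)) {
      # resolve the enhancement window once, from the initial-contour ROI
      # on the first denoised frame, and hold it fixed for the whole run:
      # the scene's echogenicity classes do not change over a sequence,
      # and a stationary mapping keeps inter-frame MI comparable
      v <- fd[init_mask > 0]
      pre$window <- c(mean(v) - pre$roi_stat_k * stats::sd(v),
                      mean(v) + pre$roi_stat_k * stats::sd(v))
      if (any(!is.finite(pre$window)) || diff(pre$window) <= 0)
        stop("degenerate window: zero-variance initial ROI")
    }
    fp <- linear_enhance(fd, init_mask, pre)
    frames_pre[[i]] <- fp
    if (mon_enabled && is.null(mon)) {
      args <- if (is.list(monitor)) monitor else list()
      mon <- do.call(monitor_state,
                     c(list(reference_frame = fp, init_mask = u,
                            match_frame = fd), args))
    }
    if (mon_enabled) {
      chk <- check_motion(mon, fp, t)
      mon <- chk$state
      log$decision[i] <- chk$decision
      log$mi[i] <- chk$mi
      if (chk$decision == "alarm" && all(mon$pending_force == 0) &&
          mon$force_step == 0L) {
        match <- tryCatch(
          ncc_match(fd, mon$template, mon$template_box, mon$search_range),
          error = function(e) NULL)
        if (!is.null(match))
          mon <- set_moving_force(mon, match$position, u)
      }
    }
    if (mon_enabled && mon$alarm) {
      r <- apply_moving_force(u, mon)
      u <- r$u; mon <- r$state
      log$shift_r[i] <- r$shift[1]; log$shift_c[i] <- r$shift[2]
    } else {
      u <- evolve_frame(u, fp, params)
      log$guard_activations[i] <- attr(u, "guard_activations")
      log$degenerate[i] <- attr(u, "degenerate")
      attributes(u) <- list(dim = dim(u))
    }
    if (mon_enabled) {
      log$alarm[i] <- mon$alarm
      log$sonication_permitted[i] <- mon$sonication_permitted
    }
    masks[[i]] <- u
  }
  structure(list(masks = masks, log = log, monitor = mon,
                 params = params, pre = pre, spacing_mm = spacing_mm,
                 frames_pre = frames_pre),
            class = "hifu_track")
}

#' @export
print.hifu_track <- function(x, ...) {
  n <- length(x$masks)
  n_alarm <- sum(x$log$alarm)
  n_guard <- sum(x$log$guard_activations)
  cat(sprintf("MACWE lesion track: %d frames, operator set of %d segment(s) (length %s)\n",
              n, length(x$params$operator_set),
              paste(unique(attr(x$params$operator_set, "lengths")),
                    collapse = "/")))
  cat(sprintf("  %d frame(s) under movement alarm, %d overflow-guard activation(s)\n",
              n_alarm, n_guard))
  areas <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("  contour area: first %d px, last %d px\n",
              as.integer(areas[1]), as.integer(areas[n])))
  invisible(x)
}

#' Summarize a lesion track
#'
#' @param object a `hifu_track`.
#' @param truth optional list of ground-truth masks; when given, DSC, IoU
#'   and Hausdorff summaries are included.
#' @param ... unused.
#' @return a list of class `summary.hifu_track`.
#' @export
summary.hifu_track <- function(object, truth = NULL, ...) {
  areas <- vapply(object$masks, sum, numeric(1))
  out <- list(n_frames = length(object$masks),
              area_px = summary(areas),
              n_checkpoints = sum(object$log$decision != "not_checked"),
              n_alarm_frames = sum(object$log$alarm),
              guard_activations = sum(object$log$guard_activations),
              report = NULL)
  if (!is.null(truth))
    out$report <- tracking_report(object$masks, truth, object$spacing_mm)
  class(out) <- "summary.hifu_track"
  out
}

#' @export
print.summary.hifu_track <- function(x, ...) {
  cat(sprintf("Lesion track over %d frames (%d MI checkpoints, %d alarm frames, %d guard activations)\n",
              x$n_frames, x$n_checkpoints, x$n_alarm_frames,
              x$guard_activations))
  cat("Contour area (px):\n"); print(x$area_px)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Plot a tracked frame with its contour
#'
#' @param x a `hifu_track`.
#' @param frame 1-based frame number to show.
#' @param frames optional list of original frames to draw under the
#'   contour; defaults to the stored preprocessed frames.
#' @param truth optional truth mask list to overlay (dashed).
#' @param ... passed to [graphics::image()].
#' @export
plot.hifu_track <- function(x, frame = length(x$masks), frames = NULL,
                            truth = NULL, ...) {
  img <- if (is.null(frames)) x$frames_pre[[frame]] else frames[[frame]]
  # orient so that row 1 is at the top
  disp <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  graphics::image(seq_len(ncol(img)), seq_len(nrow(img)), disp,
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "col", ylab = "row", useRaster = TRUE, ...)
  add_mask_contour <- function(m, lty) {
    mm <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
    graphics::contour(seq_len(ncol(m)), seq_len(nrow(m)), mm,
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      lwd = 2, lty = lty, col = "red")
  }
  add_mask_contour(x$masks[[frame]], 1)
  if (!is.null(truth)) add_mask_contour(truth[[frame]], 2)
  invisible(x)
}
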
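#' Configure an ultrasound speckle phantom
#'
#' Builds the configuration for a synthetic B-mode-like frame sequence: a
#' hypoechoic deformable elliptical lesion with optional brighter internal
#' sub-structures, an optional anechoic bladder-like distractor, fully
#' developed multiplicative speckle, and a motion schedule combining linear
#' drift, respiration-like oscillation and rare large jumps. Every frame
#' comes with an exact ground-truth lesion mask, so the phantom serves as a
#' self-contained test bed for tracking, motion monitoring and planning.
#'
#' Coordinates are 1-based `(row, col)` with origin at the top-left pixel,
#' matching R matrix indexing; frame *time* `t` runs from 0 (first frame)
#' to `n_frames - 1` so that motion laws read naturally.
#'
#' @param image_height,image_width frame size in pixels.
#' @param pixel_spacing_mm physical pixel size, mm/pixel (isotropic).
#' @param n_frames number of frames (>= 1).
#' @param lesion_center0 `(row, col)` of the lesion centre at t = 0.
#' @param lesion_axes0 `(a, b)` semi-axes in pixels (rows, cols).
#' @param lesion_intensity,background_intensity mean echogenicity in [0,1];
#'   the lesion is hypoechoic, so typically below the background.
#' @param internal_blobs list of `list(offset = c(dr, dc), radius, intensity)`
#'   internal sub-structures; offsets are relative to the lesion centre and
#'   move rigidly with it. Blobs are painted only inside the lesion and are
#'   part of the ground-truth lesion interior (the clinical target is the
#'   outer contour, not internal structure).
#' @param bladder optional `list(center = c(row, col), axes = c(a, b),
#'   intensity)`; a static anechoic ellipse mimicking the bladder.
#' @param speckle_shape gamma shape parameter k of the unit-mean
#'   multiplicative speckle (scale 1/k); larger k means less noise.
#' @param drift_px_per_frame `(dr, dc)` linear drift per frame.
#' @param oscillation `(amplitude_px, period_frames)`; sinusoidal motion of
#'   the lesion centre along the row (axial) direction.
#' @param jumps list of `list(frame = t, displacement = c(dr, dc))`; the
#'   displacement applies from frame `t` onward (abrupt patient movement).
#' @param deform_amplitude fractional modulation of both semi-axes at the
#'   oscillation period, in [0, 1).
#' @param allow_truncation if `TRUE` the lesion may extend beyond the image
#'   and the truth mask is clipped to the field of view (used to study
#'   contour overflow on incomplete lesions); default `FALSE` enforces that
#'   the lesion stays fully inside for all frames.
#' @param dark_band optional `list(side, width, intensity)` with `side` one
#'   of `"left"`, `"right"`, `"top"`, `"bottom"`: paints a near-anechoic
#'   band along that image edge, emulating the black region beyond the
#'   imaging fan of a sector probe. The band overrides all other content;
#'   lesion area under the band is considered outside the field of view
#'   and is excluded from the truth masks.
#' @param seed integer seed owning all randomness of the sequence.
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_phantom_sequence()], [render_frame()]
#' @export
phantom_config <- function(image_height = 220L, image_width = 220L,
                           pixel_spacing_mm = 0.35,
                           n_frames = 60L,
                           lesion_center0 = c(110, 110),
                           lesion_axes0 = c(50, 40),
                           lesion_intensity = 0.35,
                           background_intensity = 0.6,
                           internal_blobs = list(
                             list(offset = c(0, 33), radius = 9, intensity = 0.62),
                             list(offset = c(0, -33), radius = 9, intensity = 0.62)),
                           bladder = list(center = c(55, 180),
                                          axes = c(18, 14), intensity = 0.06),
                           speckle_shape = 30,
                           drift_px_per_frame = c(0.05, 0.1),
                           oscillation = c(1.5, 25),
                           jumps = list(),
                           deform_amplitude = 0.05,
                           allow_truncation = FALSE,
                           dark_band = NULL,
                           seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              pixel_spacing_mm = pixel_spacing_mm,
              n_frames = as.integer(n_frames),
              lesion_center0 = as.numeric(lesion_center0),
              lesion_axes0 = as.numeric(lesion_axes0),
              lesion_intensity = lesion_intensity,
              background_intensity = background_intensity,
              internal_blobs = internal_blobs,
              bladder = bladder,
              speckle_shape = speckle_shape,
              drift_px_per_frame = as.numeric(drift_px_per_frame),
              oscillation = as.numeric(oscillation),
              jumps = jumps,
              deform_amplitude = deform_amplitude,
              allow_truncation = isTRUE(allow_truncation),
              dark_band = dark_band,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$image_height >= 8L, cfg$image_width >= 8L,
            cfg$pixel_spacing_mm > 0, cfg$n_frames >= 1L,
            length(cfg$lesion_center0) == 2L, length(cfg$lesion_axes0) == 2L,
            cfg$speckle_shape > 0,
            cfg$deform_amplitude >= 0, cfg$deform_amplitude < 1,
            length(cfg$oscillation) == 2L, cfg$oscillation[2] > 0)
  if (any(cfg$lesion_axes0 <= 0))
    stop("degenerate lesion axes: both semi-axes must be positive")
  ints <- c(cfg$lesion_intensity, cfg$background_intensity,
            vapply(cfg$internal_blobs, function(b) b$intensity, numeric(1)),
            if (!is.null(cfg$bladder)) cfg$bladder$intensity)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")
  for (j in cfg$jumps)
    if (j$frame < 0 || j$frame >= cfg$n_frames)
      stop("jump frame index out of range: ", j$frame)
  if (!is.null(cfg$dark_band)) {
    b <- cfg$dark_band
    if (!b$side %in% c("left", "right", "top", "bottom"))
      stop("dark_band side must be left/right/top/bottom")
    stopifnot(b$width >= 1, b$intensity >= 0, b$intensity <= 1)
  }
  invisible(cfg)
}

# region covered by the out-of-fan dark band (FALSE everywhere if none)
band_region <- function(h, w, band) {
  m <- matrix(FALSE, h, w)
  if (is.null(band)) return(m)
  wd <- as.integer(band$width)
  if (band$side == "left") m[, seq_len(min(wd, w))] <- TRUE
  else if (band$side == "right") m[, max(1L, w - wd + 1L):w] <- TRUE
  else if (band$side == "top") m[seq_len(min(wd, h)), ] <- TRUE
  else m[max(1L, h - wd + 1L):h, ] <- TRUE
  m
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("Speckle phantom: %dx%d px (%.2f mm/px), %d frames, seed %d\n",
              x$image_height, x$image_width, x$pixel_spacing_mm,
              x$n_frames, x$seed))
  cat(sprintf("  lesion: centre (%.1f, %.1f), semi-axes (%.1f, %.1f), intensity %.2f on %.2f\n",
              x$lesion_center0[1], x$lesion_center0[2],
              x$lesion_axes0[1], x$lesion_axes0[2],
              x$lesion_intensity, x$background_intensity))
  cat(sprintf("  speckle shape %.1f; %d internal blob(s); bladder %s; %d jump(s)\n",
              x$speckle_shape, length(x$internal_blobs),
              if (is.null(x$bladder)) "absent" else "present",
              length(x$jumps)))
  invisible(x)
}

#' Lesion centre and axes at a given frame time
#'
#' Evaluates the deterministic motion schedule: linear drift, sinusoidal
#' (respiration-like) oscillation along the row axis, accumulated jump
#' displacements, and sinusoidal semi-axis modulation.
#'
#' @param config a [phantom_config()].
#' @param t frame time, 0-based (0 = first frame), `0 <= t < n_frames`.
#' @return `list(center = c(row, col), axes = c(a, b))`.
#' @export
lesion_geometry <- function(config, t) {
  if (t < 0 || t >= config$n_frames)
    stop("frame time out of range: ", t)
  amp <- config$oscillation[1]; per <- config$oscillation[2]
  center <- config$lesion_center0 +
    config$drift_px_per_frame * t +
    c(amp * sin(2 * pi * t / per), 0)
  for (j in config$jumps)
    if (j$frame <= t) center <- center + j$displacement
  axes <- config$lesion_axes0 *
    (1 + config$deform_amplitude * sin(2 * pi * t / per))
  list(center = center, axes = axes)
}

# ellipse interior test on the pixel grid (1-based centres)
ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

disk_mask <- function(h, w, center, radius)
  ellipse_mask(h, w, center, c(radius, radius))

# run expr with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-frame seed below 2^31
frame_seed <- function(seed, t) (seed * 1000003L + t * 7919L) %% 2147483647L

render_template <- function(config, t) {
  h <- config$image_height; w <- config$image_width
  geo <- lesion_geometry(config, t)
  tpl <- matrix(config$background_intensity, h, w)
  les <- ellipse_mask(h, w, geo$center, geo$axes)
  tpl[les] <- config$lesion_intensity
  for (b in config$internal_blobs) {
    bm <- disk_mask(h, w, geo$center + b$offset, b$radius) & les
    tpl[bm] <- b$intensity
  }
  if (!is.null(config$bladder)) {
    bl <- ellipse_mask(h, w, config$bladder$center, config$bladder$axes)
    tpl[bl] <- config$bladder$intensity
  }
  if (!is.null(config$dark_band)) {
    br <- band_region(h, w, config$dark_band)
    tpl[br] <- config$dark_band$intensity
    les <- les & !br
  }
  list(template = tpl, lesion_mask = les)
}

#' Render a single phantom frame
#'
#' Paints the noiseless template (background, lesion ellipse, internal
#' blobs, bladder) at the frame-`t` geometry, then multiplies by unit-mean
#' gamma speckle (shape `speckle_shape`, scale `1/speckle_shape`) and clips
#' to [0, 1]. Bit-reproducible given `(seed, t)`.
#'
#' @inheritParams lesion_geometry
#' @param noiseless if `TRUE`, skip the speckle (the infinite-shape limit).
#' @return numeric matrix in [0, 1].
#' @export
render_frame <- function(config, t, noiseless = FALSE) {
  tpl <- render_template(config, t)$template
  if (noiseless) return(tpl)
  k <- config$speckle_shape
  speckle <- with_private_seed(frame_seed(config$seed, t), {
    matrix(stats::rgamma(length(tpl), shape = k, scale = 1 / k),
           nrow(tpl), ncol(tpl))
  })
  pmin(pmax(tpl * speckle, 0), 1)
}

#' Generate a full phantom sequence with ground truth
#'
#' @inheritParams lesion_geometry
#' @param noiseless if `TRUE`, frames are the noiseless templates.
#' @return An object of class `phantom_sequence`: `frames` (list of
#'   matrices), `truth_masks` (list of 0/1 matrices: the exact lesion
#'   ellipse interiors, internal blobs included), `events` (data frame of
#'   configured jumps: `frame`, `kind`, `dr`, `dc`), and the `config`.
#' @export
generate_phantom_sequence <- function(config, noiseless = FALSE) {
  h <- config$image_height; w <- config$image_width
  frames <- vector("list", config$n_frames)
  masks <- vector("list", config$n_frames)
  for (t in seq_len(config$n_frames) - 1L) {
    geo <- lesion_geometry(config, t)
    if (!config$allow_truncation) {
      lo <- geo$center - geo$axes; hi <- geo$center + geo$axes
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > h || hi[2] > w)
        stop(sprintf("lesion leaves the image at frame time %d; set allow_truncation = TRUE if intended", t))
    }
    frames[[t + 1L]] <- render_frame(config, t, noiseless = noiseless)
    m <- (ellipse_mask(h, w, geo$center, geo$axes) &
            !band_region(h, w, config$dark_band)) * 1
    if (sum(m) == 0)
      stop(sprintf("truth mask empty at frame time %d (lesion fully outside the field of view)", t))
    masks[[t + 1L]] <- m
  }
  events <- if (length(config$jumps) == 0L) {
    data.frame(frame = integer(0), kind = character(0),
               dr = numeric(0), dc = numeric(0))
  } else {
    data.frame(frame = vapply(config$jumps, `[[`, numeric(1), "frame"),
               kind = "jump",
               dr = vapply(config$jumps, function(j) j$displacement[1], numeric(1)),
               dc = vapply(config$jumps, function(j) j$displacement[2], numeric(1)))
  }
  structure(list(frames = frames, truth_masks = masks,
                 events = events, config = config),
            class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cat(sprintf("Phantom sequence: %d frames of %dx%d px, %d movement event(s)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              nrow(x$events)))
  invisible(x)
}

# centroid of a binary mask, (row, col)
mask_centroid <- function(u) {
  idx <- which(u > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("centroid of an empty mask is undefined")
  colMeans(idx)[c("row", "col")]
}
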
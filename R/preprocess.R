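#' Preprocessing parameters
#'
#' @param kappa_radius radius in pixels of the disk structuring element used
#'   by the morphological speckle suppression (>= 1).
#' @param roi_stat_k multiplier `k` for the ROI-derived intensity window
#'   `[m - k s, m + k s]`, where `m` and `s` are the mean and standard
#'   deviation of the (denoised) frame inside the initial lesion mask.
#' @param window optional explicit intensity window `c(low, high)`; when
#'   given it overrides the ROI-derived window.
#' @return a validated list of class `preprocess_params`.
#' @export
preprocess_params <- function(kappa_radius = 2L, roi_stat_k = 2,
                              window = NULL) {
  stopifnot(kappa_radius >= 1)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    if (window[1] >= window[2])
      stop("explicit window must satisfy low < high")
  }
  structure(list(kappa_radius = as.integer(kappa_radius),
                 roi_stat_k = roi_stat_k, window = window),
            class = "preprocess_params")
}

#' Morphological speckle suppression
#'
#' Ultrasound speckle has spatial structure rather than independent
#' per-pixel noise, so frames are smoothed with a grayscale morphological
#' opening followed by a closing over a disk, which removes bright and dark
#' granules smaller than the disk while preserving region edges.
#'
#' @param frame numeric matrix with values in [0, 1].
#' @param kappa_radius disk radius in pixels.
#' @return denoised matrix in [0, 1].
#' @export
denoise_morphological <- function(frame, kappa_radius = 2L) {
  if (any(!is.finite(frame))) stop("frame contains non-finite pixels")
  stopifnot(kappa_radius >= 1)
  off <- disk_offsets(kappa_radius)
  opened <- gray_dilate(gray_erode(frame, off), off)
  gray_erode(gray_dilate(opened, off), off)
}

#' Linear intensity enhancement around the lesion window
#'
#' Maps intensities affinely so that the window `[low, high]` spans [0, 1],
#' clipping outside. By default the window is derived from the statistics of
#' the frame inside the initial lesion mask, which stretches the contrast
#' around the lesion's gray level and pushes the anechoic bladder-like
#' distractor to 0 and the bright background toward 1.
#'
#' @param frame numeric matrix in [0, 1].
#' @param init_mask binary mask of the initial lesion region (same shape).
#' @param params a [preprocess_params()].
#' @return enhanced matrix in [0, 1].
#' @export
linear_enhance <- function(frame, init_mask, params = preprocess_params()) {
  if (!all(dim(frame) == dim(init_mask)))
    stop("frame and init_mask shapes differ")
  if (sum(init_mask) == 0) stop("init_mask is empty")
  win <- params$window
  if (is.null(win)) {
    v <- frame[init_mask > 0]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("degenerate window: zero-variance ROI and no explicit window")
    win <- c(m - params$roi_stat_k * s, m + params$roi_stat_k * s)
  }
  pmin(pmax((frame - win[1]) / (win[2] - win[1]), 0), 1)
}

#' Full frame preprocessing
#'
#' The composite preprocessing applied to every incoming ultrasound frame
#' before contour evolution: morphological speckle suppression with a disk
#' of radius `kappa_radius`, then the ROI-windowed linear enhancement. The
#' denoised statistics feed the window, so the order is fixed.
#'
#' @inheritParams linear_enhance
#' @return preprocessed matrix in [0, 1].
#' @export
preprocess_frame <- function(frame, init_mask, params = preprocess_params()) {
  linear_enhance(denoise_morphological(frame, params$kappa_radius),
                 init_mask, params)
}
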
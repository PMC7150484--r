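#' Reference phantom configurations
#'
#' The validation suite of the package is built on four phantom presets,
#' each exercising one aspect of the guidance pipeline:
#'
#' * `"standard"`: the default [phantom_config()] — a large deformable
#'   hypoechoic lesion with two brighter internal blobs crossing its
#'   boundary, a bladder-like distractor, drift and respiration-like
#'   oscillation over 60 frames. Used for end-to-end runs.
#' * `"internal-blob"`: the standard scene over 8 frames; the
#'   boundary-crossing blobs are the fine structure that short structuring
#'   segments follow and the long segment bridges.
#' * `"jump"`: a compact lesion (the 20 px jump at frame time 40 exceeds
#'   its directional extent, so an uncorrected contour cannot reacquire
#'   it), 120 frames, no distractors. Used for movement monitoring.
#' * `"truncated"`: a single frame whose lesion is cut by the bottom image
#'   border next to a black out-of-fan band; the incomplete lesion area
#'   drives contour overflow unless guarded.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [phantom_config()].
#' @export
phantom_preset <- function(name = c("standard", "internal-blob", "jump",
                                    "truncated"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "standard" = phantom_config(seed = seed),
    "internal-blob" = phantom_config(n_frames = 8L, seed = seed),
    "jump" = phantom_config(
      image_height = 128L, image_width = 128L, n_frames = 120L,
      lesion_center0 = c(64, 56), lesion_axes0 = c(12, 9),
      internal_blobs = list(), bladder = NULL, speckle_shape = 30,
      drift_px_per_frame = c(0.02, 0.03), oscillation = c(0.8, 25),
      jumps = list(list(frame = 40, displacement = c(12, 16))),
      deform_amplitude = 0.03, seed = seed),
    "truncated" = phantom_config(
      image_height = 160L, image_width = 160L, n_frames = 1L,
      lesion_center0 = c(150, 55), lesion_axes0 = c(45, 30),
      internal_blobs = list(), bladder = NULL, speckle_shape = 30,
      drift_px_per_frame = c(0, 0), oscillation = c(0, 25),
      jumps = list(), deform_amplitude = 0, allow_truncation = TRUE,
      dark_band = list(side = "left", width = 30, intensity = 0.02),
      seed = seed))
}

#' Analytic two-level validation images
#'
#' Noiseless two-level images (object 0.2 on background 0.8) with an exact
#' analytic truth mask and a ~60%-overlap initialization (the truth scaled
#' to 60% of its area about the centroid, then shifted a few pixels). The
#' shapes are several times larger than the longest structuring segment,
#' below which the smoothing operator cannot represent boundary features.
#'
#' @param shape `"disk"` (radius 60), `"ellipse"` (semi-axes 70 x 45) or
#'   `"square"` (side 160), all in a 220 x 220 image.
#' @return `list(image, truth, init)` where `truth` and `init` are 0/1
#'   matrices.
#' @export
analytic_shape_case <- function(shape = c("disk", "ellipse", "square")) {
  shape <- match.arg(shape)
  h <- 220L; w <- 220L
  truth <- switch(shape,
    disk = disk_mask(h, w, c(110, 110), 60),
    ellipse = ellipse_mask(h, w, c(110, 110), c(70, 45)),
    square = {
      m <- matrix(FALSE, h, w); m[31:190, 31:190] <- TRUE; m
    })
  img <- matrix(0.8, h, w)
  img[truth] <- 0.2
  init <- translate_mask(scale_mask(truth * 1, sqrt(0.6)), 5, 4)
  list(image = img, truth = truth * 1, init = init)
}

#' Scale a binary mask about its centroid
#'
#' Nearest-neighbour rescaling of the 1-region by a linear `factor` about
#' the mask centroid (area scales by `factor^2` up to pixelization).
#'
#' @param mask binary 0/1 matrix.
#' @param factor linear scale factor (> 0).
#' @return binary matrix of the same shape.
#' @export
scale_mask <- function(mask, factor) {
  stopifnot(factor > 0)
  if (sum(mask) == 0) return(mask * 0)
  ctr <- mask_centroid(mask)
  h <- nrow(mask); w <- ncol(mask)
  r_t <- matrix(seq_len(h), h, w)
  c_t <- matrix(seq_len(w), h, w, byrow = TRUE)
  r_s <- round(ctr[1] + (r_t - ctr[1]) / factor)
  c_s <- round(ctr[2] + (c_t - ctr[2]) / factor)
  ok <- r_s >= 1 & r_s <= h & c_s >= 1 & c_s <= w
  out <- matrix(0, h, w)
  out[ok] <- mask[cbind(r_s[ok], c_s[ok])]
  (out > 0) * 1
}

#' Translate a binary mask by an integer offset
#'
#' Pixels shifted beyond the grid are dropped; vacated pixels become 0.
#'
#' @param u binary 0/1 matrix.
#' @param dr,dc integer row/column offsets.
#' @return binary matrix of the same shape.
#' @export
translate_mask <- function(u, dr, dc) {
  shift_matrix(u, as.integer(dr), as.integer(dc), fill = 0)
}

#' Count 8-connected components of a binary mask
#'
#' @param u binary 0/1 matrix.
#' @return number of 8-connected components of the 1-region.
#' @export
count_components <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (s in which(u > 0)) {
    if (lab[s] != 0L) next
    k <- k + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- k
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + rr
          if (u[q] > 0 && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  k
}
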
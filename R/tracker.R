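#' MACWE tracking parameters
#'
#' Parameters of the morphological active-contour-without-edges update. The
#' region-competition model is run in its unit-parameter regime by default:
#' the smoothing count, balloon force and both region weights are all 1.
#'
#' @param mu smoothing repetitions per iteration (integer >= 0).
#' @param nu balloon force: +1 inflates (one dilation by a 3x3 cross per
#'   iteration), -1 deflates, 0 disables.
#' @param lambda1,lambda2 inside/outside region weights of the sign test.
#' @param iters_per_frame contour iterations per incoming frame.
#' @param operator_set structuring segments for the smoothing,
#'   e.g. [k3()] or [k15()].
#' @param overflow_tau fraction of outward-pointing contour forces above
#'   which the incomplete-area guard may activate ("most values positive").
#' @param overflow_scope `"border"` activates the guard only when the
#'   candidate contour touches the image border (lesion truncated by the
#'   field of view); `"global"` applies it everywhere.
#' @return a validated list of class `acwe_params`.
#' @export
acwe_params <- function(mu = 1L, nu = 1L, lambda1 = 1, lambda2 = 1,
                        iters_per_frame = 5L,
                        operator_set = k15(),
                        overflow_tau = 0.5,
                        overflow_scope = c("border", "global")) {
  overflow_scope <- match.arg(overflow_scope)
  stopifnot(mu >= 0L, abs(nu) <= 1L, iters_per_frame >= 1L,
            overflow_tau >= 0, overflow_tau <= 1)
  structure(list(mu = as.integer(mu), nu = as.integer(nu),
                 lambda1 = lambda1, lambda2 = lambda2,
                 iters_per_frame = as.integer(iters_per_frame),
                 operator_set = operator_set,
                 overflow_tau = overflow_tau,
                 overflow_scope = overflow_scope),
            class = "acwe_params")
}

#' Mean intensities inside and outside the contour
#'
#' @param image numeric matrix.
#' @param u binary 0/1 embedding of the same shape.
#' @return `list(c1, c2, degenerate)`: means inside (`u = 1`) and outside
#'   (`u = 0`); an empty region gets an epsilon-regularized denominator and
#'   sets `degenerate = TRUE`.
#' @export
region_means <- function(image, u) {
  if (!all(dim(image) == dim(u))) stop("image and embedding shapes differ")
  eps <- 1e-8
  n1 <- sum(u); n0 <- length(u) - n1
  c1 <- sum(image * u) / (n1 + eps)
  c2 <- sum(image * (1 - u)) / (n0 + eps)
  list(c1 = c1, c2 = c2, degenerate = (n1 == 0 || n0 == 0))
}

# central-difference gradient (one-sided at borders), nonzero indicator:
# marks the discrete contour pixels of a binary embedding
grad_nonzero <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  up <- u[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- u[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- u[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- u[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  (dn != up) | (rt != lf)
}

# Chan-Vese pixel force: negative favours "inside" (u = 1)
attachment_force <- function(image, params, stats) {
  params$lambda1 * (image - stats$c1)^2 -
    params$lambda2 * (image - stats$c2)^2
}

#' Balloon force step
#'
#' Uniform inflation (`nu = +1`, binary dilation with a 3x3 cross) or
#' deflation (`nu = -1`, erosion) of the embedding; `nu = 0` is a no-op.
#'
#' @param u binary 0/1 matrix.
#' @param nu integer in {-1, 0, 1}.
#' @return updated binary matrix.
#' @export
balloon_step <- function(u, nu) {
  stopifnot(abs(nu) <= 1)
  if (nu == 0) return(u)
  off <- cross_offsets()
  if (nu > 0) gray_dilate(u, off) else gray_erode(u, off)
}

#' Region-competition attachment step
#'
#' At every contour pixel the embedding is set by the sign of the
#' region-competition force `lambda1 (I - c1)^2 - lambda2 (I - c2)^2`:
#' negative switches the pixel inside, positive outside, an exact tie
#' leaves it unchanged. Pixels away from the contour are never touched.
#'
#' By default the contour pixels are those with nonzero discrete gradient
#' of `u` itself. Within a full MACWE iteration ([macwe_step()]) the
#' contour of the pre-balloon embedding is passed instead: the balloon
#' dilation would otherwise bury the original boundary one pixel inside
#' the updated mask, where the sign test could never reach it, and the
#' contour could inflate but never retreat.
#'
#' @param u binary 0/1 matrix.
#' @param image the (preprocessed) frame.
#' @param params an [acwe_params()].
#' @param stats region means from [region_means()] computed on `(image, u)`.
#' @param contour optional logical matrix marking the contour pixels to
#'   test; defaults to `grad_nonzero(u)`.
#' @return updated binary matrix.
#' @export
attachment_step <- function(u, image, params, stats, contour = NULL) {
  gz <- if (is.null(contour)) grad_nonzero(u) else contour
  force <- attachment_force(image, params, stats)
  u[gz & force < 0] <- 1
  u[gz & force > 0] <- 0
  u
}

contour_touches_border <- function(u) {
  any(u[1L, ] > 0) || any(u[nrow(u), ] > 0) ||
    any(u[, 1L] > 0) || any(u[, ncol(u)] > 0)
}

#' Incomplete-area overflow guard
#'
#' When the lesion is truncated by the field of view, region statistics
#' degrade and the inflating contour can overflow into the background. The
#' guard measures the fraction `f` of contour pixels of the previous
#' embedding whose region-competition force points outward (wants the pixel
#' inside); if `f > tau` ("most values positive") and the candidate contour
#' touches the image border, only non-growing changes are accepted: the
#' candidate is intersected with the previous embedding, suppressing this
#' iteration's balloon expansion.
#'
#' @param u_candidate candidate embedding after this iteration's update.
#' @param u_prev embedding at the start of the iteration.
#' @param image the (preprocessed) frame.
#' @param params an [acwe_params()].
#' @param stats region means used by this iteration.
#' @return the accepted embedding, with attribute `guard_active` (logical).
#' @export
overflow_guard <- function(u_candidate, u_prev, image, params, stats) {
  gz <- grad_nonzero(u_prev)
  active <- FALSE
  if (any(gz)) {
    force <- attachment_force(image, params, stats)
    f <- mean(force[gz] < 0)
    in_scope <- params$overflow_scope == "global" ||
      contour_touches_border(u_candidate)
    if (f > params$overflow_tau && in_scope) {
      u_candidate <- u_candidate * u_prev
      active <- TRUE
    }
  }
  attr(u_candidate, "guard_active") <- active
  u_candidate
}

#' One MACWE iteration
#'
#' One full update of the binary embedding: region means, balloon step,
#' region-competition attachment step, then sup-inf/inf-sup smoothing
#' repeated `mu` times. The overflow guard is applied on top of this by
#' [evolve_frame()].
#'
#' @inheritParams attachment_step
#' @return updated binary matrix.
#' @export
macwe_step <- function(u, image, params = acwe_params()) {
  stats <- region_means(image, u)
  contour <- grad_nonzero(u)
  u1 <- balloon_step(u, params$nu)
  u2 <- attachment_step(u1, image, params, stats, contour = contour)
  si_is_smooth(u2, params$operator_set, params$mu)
}

#' Evolve the contour on one frame
#'
#' Runs `iters_per_frame` MACWE iterations (each guarded against
#' incomplete-area overflow) of the embedding on a preprocessed frame.
#'
#' @param u_prev binary 0/1 embedding from the previous frame (nonempty).
#' @param frame_pre preprocessed frame.
#' @param params an [acwe_params()].
#' @return the evolved embedding with attributes `guard_activations`
#'   (integer count) and `degenerate` (TRUE if the 1-region vanished; the
#'   last non-empty embedding is returned in that case).
#' @export
evolve_frame <- function(u_prev, frame_pre, params = acwe_params()) {
  if (sum(u_prev) == 0) stop("initial embedding is empty")
  u <- u_prev
  guards <- 0L
  degenerate <- FALSE
  for (i in seq_len(params$iters_per_frame)) {
    u0 <- u
    stats <- region_means(frame_pre, u)
    contour <- grad_nonzero(u)
    u1 <- balloon_step(u, params$nu)
    u2 <- attachment_step(u1, frame_pre, params, stats, contour = contour)
    u3 <- si_is_smooth(u2, params$operator_set, params$mu)
    u <- overflow_guard(u3, u0, frame_pre, params, stats)
    if (isTRUE(attr(u, "guard_active"))) guards <- guards + 1L
    attr(u, "guard_active") <- NULL
    if (sum(u) == 0) {
      u <- u0
      degenerate <- TRUE
      break
    }
  }
  attr(u, "guard_activations") <- guards
  attr(u, "degenerate") <- degenerate
  u
}

#' Rigid 2D transform between image grids
#'
#' Relates a preoperative mask grid to the intraoperative frame grid:
#' rotation about the grid centre, scale (source-to-target mm-per-pixel
#' ratio), then translation in millimetres.
#'
#' @param rotation angle in radians (counter-clockwise in (row, col) space).
#' @param translation_mm `(dr_mm, dc_mm)` translation.
#' @param scale ratio of source pixel size to target pixel size (> 0).
#' @return a list of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation = 0, translation_mm = c(0, 0),
                              scale = 1) {
  stopifnot(scale > 0, length(translation_mm) == 2L)
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm),
                 scale = scale),
            class = "rigid_transform2d")
}

#' Initialize the contour from a preoperative mask
#'
#' Resamples a preoperative binary mask into the intraoperative frame grid
#' through a rigid transform (nearest-neighbour), producing the initial
#' contour for tracking.
#'
#' @param mask_preop nonempty binary matrix in the preoperative grid.
#' @param transform a [rigid_transform2d()].
#' @param target_shape `c(rows, cols)` of the intraoperative grid.
#' @param spacing_mm target pixel size in mm/pixel (converts the
#'   translation to pixels).
#' @return binary matrix of shape `target_shape`; error if the transform
#'   maps the mask fully outside the target grid.
#' @export
init_from_preop <- function(mask_preop, transform, target_shape,
                            spacing_mm = 1) {
  if (sum(mask_preop) == 0) stop("preoperative mask is empty")
  h_t <- target_shape[1]; w_t <- target_shape[2]
  h_s <- nrow(mask_preop); w_s <- ncol(mask_preop)
  ctr_s <- c((h_s + 1) / 2, (w_s + 1) / 2)
  ctr_t <- c((h_t + 1) / 2, (w_t + 1) / 2)
  t_px <- transform$translation_mm / spacing_mm
  co <- cos(transform$rotation); si <- sin(transform$rotation)
  # target pixel -> source pixel (inverse map)
  r_t <- matrix(seq_len(h_t), h_t, w_t)
  c_t <- matrix(seq_len(w_t), h_t, w_t, byrow = TRUE)
  dr <- r_t - ctr_t[1] - t_px[1]
  dc <- c_t - ctr_t[2] - t_px[2]
  r_s <- round(( co * dr + si * dc) / transform$scale + ctr_s[1])
  c_s <- round((-si * dr + co * dc) / transform$scale + ctr_s[2])
  ok <- r_s >= 1 & r_s <= h_s & c_s >= 1 & c_s <= w_s
  out <- matrix(0, h_t, w_t)
  out[ok] <- mask_preop[cbind(r_s[ok], c_s[ok])]
  out <- (out > 0.5) * 1
  if (sum(out) == 0)
    stop("transform maps the preoperative mask fully outside the target grid")
  out
}
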
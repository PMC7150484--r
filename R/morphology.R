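#' @title Shift-and-reduce morphology on image grids
#' @description Internal morphological primitives shared by the frame
#'   preprocessing and the contour evolution. All operators use the same
#'   border policy: a structuring element is clipped at the image border,
#'   i.e. offsets that fall outside the grid are ignored (no padding value
#'   is invented). For an erosion this is equivalent to padding with +Inf,
#'   for a dilation with -Inf.
#' @name morphology-internal
#' @keywords internal
NULL

# Shift a matrix by (dr, dc); vacated positions become `fill`.
shift_matrix <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- max(1L, 1L - dr):min(nr, nr - dr)
  c_src <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r_src) < 1L || length(c_src) < 1L || r_src[1] > r_src[length(r_src)])
    return(out)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# Pointwise min/max over all offsets of a structuring element, out-of-grid
# contributions ignored. `offsets` is an n x 2 integer matrix of (dr, dc).
reduce_offsets <- function(m, offsets, op = c("min", "max")) {
  op <- match.arg(op)
  fill <- if (op == "min") Inf else -Inf
  acc <- matrix(fill, nrow(m), ncol(m))
  f <- if (op == "min") pmin else pmax
  for (i in seq_len(nrow(offsets))) {
    # element offset (dr,dc) means pixel (r+dr, c+dc) participates at (r,c),
    # so the contribution is the matrix shifted by (-dr, -dc)
    acc <- f(acc, shift_matrix(m, -offsets[i, 1L], -offsets[i, 2L], fill = fill))
  }
  acc
}

gray_erode  <- function(m, offsets) reduce_offsets(m, offsets, "min")
gray_dilate <- function(m, offsets) reduce_offsets(m, offsets, "max")

# Disk structuring element offsets (Euclidean, radius in pixels).
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius^2
  as.matrix(g[keep, c("dr", "dc"), drop = FALSE])
}

# 3x3 cross (4-connected) element used by the balloon force.
cross_offsets <- function() {
  matrix(c(0L, 0L, -1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
         ncol = 2L, byrow = TRUE)
}

# Digital line segment of odd length centred on its midpoint. Angles are in
# degrees; the four canonical directions use unit pixel steps so a length-L
# segment covers L pixels along the digital line.
segment_offsets <- function(length, angle) {
  if (length %% 2L != 1L || length < 3L)
    stop("structuring segment length must be odd and >= 3")
  half <- (length - 1L) %/% 2L
  a <- angle %% 180
  step <- switch(as.character(a),
    "0"   = c(0L, 1L),
    "45"  = c(-1L, 1L),
    "90"  = c(1L, 0L),
    "135" = c(1L, 1L),
    {
      # general orientation: rounded sampling of the continuous line
      th <- a * pi / 180
      ks <- -half:half
      return(cbind(dr = as.integer(round(-ks * sin(th))),
                   dc = as.integer(round(ks * cos(th)))))
    })
  ks <- -half:half
  cbind(dr = step[1L] * ks, dc = step[2L] * ks)
}

#' Structuring-segment sets for contour smoothing
#'
#' The curvature-like smoothing of the contour embedding is a compound
#' sup-inf / inf-sup operation over a set of discrete line segments. The
#' classical set uses four short segments of three pixels
#' (0, 45, 90 and 135 degrees); the variant used for ultrasound lesions
#' replaces them with fifteen-pixel segments so that structures smaller
#' than the segment half-length cannot deflect the contour.
#'
#' @param lengths integer vector of segment lengths in pixels (odd, >= 3);
#'   recycled against `angles`.
#' @param angles orientations in degrees.
#' @return An object of class `operator_set`: a list of offset matrices,
#'   with attributes `lengths` and `angles`.
#' @examples
#' k3()   # four segments of length 3
#' k15()  # four segments of length 15
#' k15(single_orientation = 0)  # the literal single-segment reading
#' @export
operator_set <- function(lengths, angles) {
  n <- max(length(lengths), length(angles))
  lengths <- rep_len(as.integer(lengths), n)
  angles <- rep_len(angles, n)
  segs <- lapply(seq_len(n), function(i) segment_offsets(lengths[i], angles[i]))
  structure(segs, lengths = lengths, angles = angles, class = "operator_set")
}

#' @rdname operator_set
#' @export
k3 <- function() operator_set(3L, c(0, 45, 90, 135))

#' @rdname operator_set
#' @param single_orientation if non-`NULL`, build the set as one single
#'   length-15 segment at this orientation (degrees) instead of the default
#'   four orientations.
#' @export
k15 <- function(single_orientation = NULL) {
  if (is.null(single_orientation)) {
    operator_set(15L, c(0, 45, 90, 135))
  } else {
    operator_set(15L, single_orientation)
  }
}

#' @export
print.operator_set <- function(x, ...) {
  cat(sprintf("Structuring segment set: %d segment(s), lengths {%s}, angles {%s} deg\n",
              length(x), paste(unique(attr(x, "lengths")), collapse = ", "),
              paste(attr(x, "angles"), collapse = ", ")))
  invisible(x)
}

# sup of erosions / inf of dilations over the segment set
sup_inf <- function(u, operator_set) {
  acc <- matrix(-Inf, nrow(u), ncol(u))
  for (seg in operator_set) acc <- pmax(acc, gray_erode(u, seg))
  acc
}

inf_sup <- function(u, operator_set) {
  acc <- matrix(Inf, nrow(u), ncol(u))
  for (seg in operator_set) acc <- pmin(acc, gray_dilate(u, seg))
  acc
}

#' Sup-inf / inf-sup smoothing of a binary embedding
#'
#' One smoothing pass applies the inf-sup operator (infimum over segments of
#' the dilation along each segment) followed by the sup-inf operator
#' (supremum of the erosions). Repeated application approximates motion by
#' mean curvature of the contour at the scale set by the segment length.
#'
#' @param u binary 0/1 matrix (the contour is the boundary of the 1-region).
#' @param operator_set an [operator_set()], e.g. [k3()] or [k15()].
#' @param mu number of smoothing repetitions (non-negative integer).
#' @return smoothed binary matrix.
#' @export
si_is_smooth <- function(u, operator_set, mu = 1L) {
  if (!inherits(operator_set, "operator_set") || length(operator_set) == 0L)
    stop("`operator_set` must be a non-empty operator_set")
  stopifnot(mu >= 0L)
  for (i in seq_len(mu)) u <- sup_inf(inf_sup(u, operator_set), operator_set)
  u
}
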
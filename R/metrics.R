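#' Overlap and boundary-distance metrics
#'
#' Dice similarity coefficient, intersection-over-union and the symmetric
#' Hausdorff distance in millimetres, as used to score tracked lesion
#' contours against ground truth.
#'
#' @param a,b binary 0/1 matrices of the same shape.
#' @return a number: `dsc`/`iou` in [0, 1] (both defined as 1 when both
#'   masks are empty), `hausdorff_mm` in mm (error on an empty mask).
#' @name metrics
NULL

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have the same shape")
}

#' @rdname metrics
#' @export
dsc <- function(a, b) {
  check_same_shape(a, b)
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (na + nb)
}

#' @rdname metrics
#' @export
iou <- function(a, b) {
  check_same_shape(a, b)
  un <- sum(a > 0 | b > 0)
  if (un == 0) return(1)
  sum(a > 0 & b > 0) / un
}

# boundary pixels: mask minus its erosion by the 3x3 cross
boundary_pixels <- function(u) {
  er <- gray_erode((u > 0) * 1, cross_offsets())
  which((u > 0) & (er < 1), arr.ind = TRUE)
}

directed_hausdorff_px <- function(pts_a, pts_b) {
  # max over a of min over b of Euclidean distance; chunked O(n m)
  best <- 0
  step <- 512L
  for (s in seq(1L, nrow(pts_a), by = step)) {
    e <- min(s + step - 1L, nrow(pts_a))
    d2 <- outer(pts_a[s:e, 1], pts_b[, 1], "-")^2 +
      outer(pts_a[s:e, 2], pts_b[, 2], "-")^2
    best <- max(best, max(sqrt(apply(d2, 1, min))))
  }
  best
}

#' @rdname metrics
#' @param spacing_mm isotropic pixel size in mm/pixel.
#' @export
hausdorff_mm <- function(a, b, spacing_mm) {
  check_same_shape(a, b)
  if (length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a single positive isotropic pixel size")
  pa <- boundary_pixels(a); pb <- boundary_pixels(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("Hausdorff distance undefined for an empty mask")
  max(directed_hausdorff_px(pa, pb), directed_hausdorff_px(pb, pa)) *
    spacing_mm
}

#' Per-frame tracking report
#'
#' Scores a tracked mask sequence against ground truth with DSC, IoU and
#' the Hausdorff distance in mm, plus per-metric mean and SD.
#'
#' @param pred,truth lists of binary masks of equal length.
#' @param spacing_mm pixel size in mm/pixel.
#' @return list of class `tracking_report`: `per_frame` (data frame with
#'   `frame`, `dsc`, `iou`, `hd_mm`) and `summary` (data frame of mean/sd).
#' @export
tracking_report <- function(pred, truth, spacing_mm) {
  stopifnot(length(pred) == length(truth))
  n <- length(pred)
  df <- data.frame(frame = seq_len(n) - 1L,
                   dsc = NA_real_, iou = NA_real_, hd_mm = NA_real_)
  for (i in seq_len(n)) {
    df$dsc[i] <- dsc(pred[[i]], truth[[i]])
    df$iou[i] <- iou(pred[[i]], truth[[i]])
    df$hd_mm[i] <- tryCatch(hausdorff_mm(pred[[i]], truth[[i]], spacing_mm),
                            error = function(e) NA_real_)
  }
  summ <- data.frame(
    metric = c("dsc", "iou", "hd_mm"),
    mean = c(mean(df$dsc), mean(df$iou), mean(df$hd_mm, na.rm = TRUE)),
    sd = c(stats::sd(df$dsc), stats::sd(df$iou),
           stats::sd(df$hd_mm, na.rm = TRUE)))
  structure(list(per_frame = df, summary = summ),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("Tracking report over %d frames:\n", nrow(x$per_frame)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s mean %.4f  sd %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
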
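#' Central quarter-area treatment region
#'
#' The sonication treatment area is the central quarter of the tracked
#' lesion: the lesion shape scaled by 1/2 in each linear dimension about
#' its centroid (area ratio 1/4 up to pixelization), intersected with the
#' lesion mask itself.
#'
#' @param lesion_mask nonempty binary matrix.
#' @return binary matrix of the same shape; error if the input is empty or
#'   too small to contain a treatment region.
#' @export
treatment_region <- function(lesion_mask) {
  if (sum(lesion_mask) == 0) stop("lesion mask is empty")
  if (sum(lesion_mask > 0) < 16)
    stop("lesion too small for a treatment region")
  h <- nrow(lesion_mask); w <- ncol(lesion_mask)
  ctr <- mask_centroid(lesion_mask)
  r_t <- matrix(seq_len(h), h, w)
  c_t <- matrix(seq_len(w), h, w, byrow = TRUE)
  # target pixel is in the region iff its 2x magnification about the
  # centroid lands inside the lesion
  r_s <- round(ctr[1] + 2 * (r_t - ctr[1]))
  c_s <- round(ctr[2] + 2 * (c_t - ctr[2]))
  ok <- r_s >= 1 & r_s <= h & c_s >= 1 & c_s <= w
  out <- matrix(0, h, w)
  out[ok] <- lesion_mask[cbind(r_s[ok], c_s[ok])]
  out <- ((out > 0) & (lesion_mask > 0)) * 1
  if (sum(out) == 0)
    stop("lesion too small for a treatment region")
  out
}

#' Even focus grid over a treatment region
#'
#' Lays a square grid with pitch `spacing_mm` (default 5 mm, i.e. 0.5 cm)
#' anchored at the region centroid, and keeps the grid points falling
#' inside the region mask. Coordinates are millimetres with origin at the
#' centre of the top-left pixel; `x` runs along columns, `y` along rows.
#'
#' @param region binary treatment-region mask (possibly empty).
#' @param spacing_mm grid pitch in mm (> 0).
#' @param pixel_spacing_mm pixel size in mm/pixel (> 0).
#' @return data frame with columns `x_mm`, `y_mm`, sorted row-major
#'   (by `y_mm`, then `x_mm`); zero rows for an empty region.
#' @export
distribute_foci_2d <- function(region, spacing_mm = 5,
                               pixel_spacing_mm = 0.25) {
  stopifnot(spacing_mm > 0, pixel_spacing_mm > 0)
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0))
  if (sum(region) == 0) return(empty)
  ctr <- mask_centroid(region)           # (row, col), pixels
  ctr_mm <- (ctr - 1) * pixel_spacing_mm # (y, x)
  idx <- which(region > 0, arr.ind = TRUE)
  ry <- (range(idx[, 1]) - 1) * pixel_spacing_mm
  rx <- (range(idx[, 2]) - 1) * pixel_spacing_mm
  iy <- seq(floor((ry[1] - ctr_mm[1]) / spacing_mm),
            ceiling((ry[2] - ctr_mm[1]) / spacing_mm))
  ix <- seq(floor((rx[1] - ctr_mm[2]) / spacing_mm),
            ceiling((rx[2] - ctr_mm[2]) / spacing_mm))
  g <- expand.grid(x_mm = ctr_mm[2] + ix * spacing_mm,
                   y_mm = ctr_mm[1] + iy * spacing_mm)
  rr <- round(g$y_mm / pixel_spacing_mm) + 1
  cc <- round(g$x_mm / pixel_spacing_mm) + 1
  ok <- rr >= 1 & rr <= nrow(region) & cc >= 1 & cc <= ncol(region)
  ok[ok] <- region[cbind(rr[ok], cc[ok])] > 0
  out <- g[ok, c("x_mm", "y_mm"), drop = FALSE]
  out <- out[order(out$y_mm, out$x_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-slice focus plans into a 3D plan
#'
#' For each image slice, computes the central quarter treatment region of
#' the lesion mask and distributes foci on the even grid; the per-slice 2D
#' plans are stacked into a 3D distribution with `z = slice_index *
#' slice_spacing_mm`.
#'
#' @param per_slice list of `list(slice_index, lesion_mask)`; indices must
#'   be unique. A slice with an empty lesion mask yields a layer with zero
#'   foci.
#' @param slice_spacing_mm distance between slices in mm.
#' @param spacing_mm focus grid pitch in mm.
#' @param pixel_spacing_mm pixel size in mm/pixel.
#' @return object of class `focus_plan`: `slices` (list of
#'   `list(slice_index, z_mm, foci)`), `treatment_masks`, `spacing_mm`.
#' @export
assemble_3d <- function(per_slice, slice_spacing_mm, spacing_mm = 5,
                        pixel_spacing_mm = 0.25) {
  idxs <- vapply(per_slice, function(s) as.integer(s$slice_index), integer(1))
  if (anyDuplicated(idxs)) stop("duplicate slice index in plan input")
  ord <- order(idxs)
  slices <- vector("list", length(per_slice))
  tmasks <- vector("list", length(per_slice))
  for (i in seq_along(ord)) {
    s <- per_slice[[ord[i]]]
    if (sum(s$lesion_mask) == 0) {
      region <- s$lesion_mask * 0
      foci <- data.frame(x_mm = numeric(0), y_mm = numeric(0))
    } else {
      region <- tryCatch(treatment_region(s$lesion_mask),
                         error = function(e) s$lesion_mask * 0)
      foci <- distribute_foci_2d(region, spacing_mm, pixel_spacing_mm)
    }
    slices[[i]] <- list(slice_index = idxs[ord[i]],
                        z_mm = idxs[ord[i]] * slice_spacing_mm,
                        foci = foci)
    tmasks[[i]] <- region
  }
  structure(list(slices = slices, treatment_masks = tmasks,
                 spacing_mm = spacing_mm,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "focus_plan")
}

#' @export
print.focus_plan <- function(x, ...) {
  nf <- vapply(x$slices, function(s) nrow(s$foci), integer(1))
  cat(sprintf("HIFU focus plan: %d slice(s), %d foci total, grid pitch %.1f mm\n",
              length(x$slices), sum(nf), x$spacing_mm))
  for (s in x$slices)
    cat(sprintf("  slice %d (z = %.1f mm): %d foci\n",
                s$slice_index, s$z_mm, nrow(s$foci)))
  invisible(x)
}

#' Sonication permission gate
#'
#' A focus may only be fired while the movement monitor is not alarmed.
#'
#' @param monitor a [monitor_state()].
#' @return `"hold"` while alarmed, else `"fire"`.
#' @export
gate_by_alarm <- function(monitor) {
  if (isTRUE(monitor$alarm)) "hold" else "fire"
}

#' Export a focus plan as JSON
#'
#' @param plan a [assemble_3d()] plan.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(spacing_mm = plan$spacing_mm,
              slices = lapply(plan$slices, function(s) {
                list(slice_index = s$slice_index, z_mm = s$z_mm,
                     foci = unname(apply(as.matrix(s$foci), 1, function(r)
                       c(r[["x_mm"]], r[["y_mm"]]), simplify = FALSE)))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
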
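#' Histogram mutual information between two frames
#'
#' Mutual information from the joint intensity histogram with `bins`
#' equal-width bins over [0, 1]:
#' `sum p(x,y) log(p(x,y) / (p(x) p(y)))` in nats, with empty cells
#' contributing zero. Used to detect large unexpected patient movement: a
#' drop in MI against a stable reference frame signals a scene change.
#'
#' @param frame_a,frame_b numeric matrices of the same shape, values in
#'   [0, 1].
#' @param bins number of histogram bins per marginal (>= 2).
#' @return mutual information in nats (non-negative up to rounding).
#' @export
mutual_information <- function(frame_a, frame_b, bins = 32L) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have the same shape")
  stopifnot(bins >= 2L)
  ia <- pmin(pmax(floor(frame_a * bins), 0), bins - 1L)
  ib <- pmin(pmax(floor(frame_b * bins), 0), bins - 1L)
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  n <- sum(joint)
  p <- joint / n
  pj <- matrix(p, bins, bins, byrow = TRUE)  # rows: ia, cols: ib
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Create a movement-monitor state
#'
#' The monitor keeps a stable reference frame and a template patch cut at
#' the bounding box of the initial contour. Every `cadence` frames it
#' compares the current frame with the reference by mutual information;
#' when MI drops below `mi_threshold` times the baseline (established at
#' the first checkpoint) an alarm is raised, the sonication permission is
#' withdrawn, and normalized cross-correlation template matching computes a
#' moving force that translates the contour over the next `alpha` frames.
#' The reference then refreshes to the post-movement scene and the alarm
#' stands down after `stable_checkpoints_required` consecutive stable
#' checkpoints.
#'
#' @param reference_frame preprocessed frame at tracking start.
#' @param init_mask binary initial contour embedding.
#' @param cadence frames between MI checks (default 10).
#' @param mi_threshold fraction of the baseline MI below which the alarm is
#'   raised (0 < threshold <= 1).
#' @param bins histogram bins for the MI estimator.
#' @param search_range `c(a, b)`: admissible per-axis displacement
#'   magnitudes (pixels) for the template search.
#' @param alpha number of frames over which a moving force is spread.
#' @param stable_checkpoints_required consecutive stable checkpoints needed
#'   to clear an alarm.
#' @param template_pad pixels of context added around the initial-contour
#'   bounding box when cutting the template.
#' @param match_frame frame from which the NCC template is cut; defaults
#'   to `reference_frame`. The tracker passes the denoised but
#'   *unwindowed* first frame here: the contrast window saturates the
#'   background and whitens the lesion interior, which is fine for the
#'   MI check but destroys the intensity topography that correlation
#'   matching relies on.
#' @return a list of class `monitor_state`.
#' @export
monitor_state <- function(reference_frame, init_mask, cadence = 10L,
                          mi_threshold = 0.6, bins = 32L,
                          search_range = c(0L, 30L), alpha = 5L,
                          stable_checkpoints_required = 1L,
                          template_pad = 2L, match_frame = NULL) {
  stopifnot(cadence >= 1L, mi_threshold > 0, mi_threshold <= 1,
            search_range[1] <= search_range[2], alpha >= 1L,
            stable_checkpoints_required >= 1L)
  idx <- which(init_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("initial mask is empty")
  if (is.null(match_frame)) match_frame <- reference_frame
  r0 <- max(1L, min(idx[, 1]) - template_pad)
  r1 <- min(nrow(reference_frame), max(idx[, 1]) + template_pad)
  c0 <- max(1L, min(idx[, 2]) - template_pad)
  c1 <- min(ncol(reference_frame), max(idx[, 2]) + template_pad)
  template <- match_frame[r0:r1, c0:c1, drop = FALSE]
  tmpl_center <- c((r0 + r1) / 2, (c0 + c1) / 2)
  centroid <- mask_centroid(init_mask)
  structure(list(
    reference_frame = reference_frame,
    template = template,
    template_box = c(r0, r1, c0, c1),
    template_center = tmpl_center,
    centroid_offset = centroid - tmpl_center,
    cadence = as.integer(cadence),
    mi_threshold = mi_threshold,
    bins = as.integer(bins),
    search_range = as.integer(search_range),
    alpha = as.integer(alpha),
    stable_required = as.integer(stable_checkpoints_required),
    baseline_mi = NA_real_,
    alarm = FALSE,
    sonication_permitted = TRUE,
    stable_streak = 0L,
    pending_force = c(0, 0),
    force_step = 0L,
    force_total = c(0, 0),
    n_checks = 0L
  ), class = "monitor_state")
}

#' @export
print.monitor_state <- function(x, ...) {
  cat(sprintf("Movement monitor: cadence %d, MI threshold %.2f x baseline (%s), %s\n",
              x$cadence, x$mi_threshold,
              if (is.na(x$baseline_mi)) "baseline pending"
              else sprintf("baseline %.3f nats", x$baseline_mi),
              if (x$alarm) "ALARM" else "stable"))
  invisible(x)
}

#' Run one movement check
#'
#' At checkpoint frames (`frame_time` a positive multiple of the cadence)
#' the MI between the reference and the current frame is compared with the
#' baseline. The first checkpoint establishes the baseline and is stable by
#' definition. On alarm, the reference refreshes to the current frame so
#' that stability is judged against the post-movement scene.
#'
#' @param state a [monitor_state()].
#' @param frame current preprocessed frame.
#' @param frame_time 0-based frame time (frame 0 = tracking start).
#' @return `list(state, decision, mi)` with
#'   `decision` one of `"not_checked"`, `"stable"`, `"alarm"`.
#' @export
check_motion <- function(state, frame, frame_time) {
  if (frame_time %% state$cadence != 0L)
    return(list(state = state, decision = "not_checked", mi = NA_real_))
  mi <- mutual_information(state$reference_frame, frame, state$bins)
  state$n_checks <- state$n_checks + 1L
  if (state$n_checks == 1L) {
    # tracking-start checkpoint: reference and frame coincide, so this MI
    # is the self-information of the scene, not a valid baseline
    state$reference_frame <- frame
    return(list(state = state, decision = "stable", mi = mi))
  }
  if (is.na(state$baseline_mi)) {
    state$baseline_mi <- mi
    state$reference_frame <- frame
    return(list(state = state, decision = "stable", mi = mi))
  }
  if (mi < state$mi_threshold * state$baseline_mi) {
    state$alarm <- TRUE
    state$sonication_permitted <- FALSE
    state$stable_streak <- 0L
    # judge stability against the post-movement scene from now on
    state$reference_frame <- frame
    list(state = state, decision = "alarm", mi = mi)
  } else {
    if (state$alarm) {
      state$stable_streak <- state$stable_streak + 1L
      if (state$stable_streak >= state$stable_required) {
        state$alarm <- FALSE
        state$sonication_permitted <- TRUE
        state$stable_streak <- 0L
      }
    }
    state$reference_frame <- frame
    list(state = state, decision = if (state$alarm) "alarm" else "stable",
         mi = mi)
  }
}

#' Normalized cross-correlation template matching
#'
#' Searches for the template around its original location over integer
#' displacements whose per-axis magnitude lies within `search_range`
#' (Chebyshev annulus `a <= max(|dr|, |dc|) <= b`, displacement 0 included
#' when `a = 0`). The score is the Pearson correlation between template and
#' window; ties are broken by the smallest displacement, then row-major
#' order.
#'
#' @param image frame to search in.
#' @param template patch to match.
#' @param template_box `c(r0, r1, c0, c1)` original location of the patch.
#' @param search_range `c(a, b)` per-axis displacement bounds in pixels.
#' @return `list(position = c(row, col) of the matched patch centre,
#'   displacement = c(dr, dc), score)`.
#' @export
ncc_match <- function(image, template, template_box,
                      search_range = c(0L, 30L)) {
  tv <- as.vector(template)
  if (stats::sd(tv) == 0)
    stop("no-match: template has zero variance")
  a <- search_range[1]; b <- search_range[2]
  r0 <- template_box[1]; r1 <- template_box[2]
  c0 <- template_box[3]; c1 <- template_box[4]
  best <- NULL
  tv_c <- tv - mean(tv)
  tv_ss <- sqrt(sum(tv_c^2))
  for (dr in -b:b) for (dc in -b:b) {
    if (max(abs(dr), abs(dc)) < a) next
    rr0 <- r0 + dr; rr1 <- r1 + dr; cc0 <- c0 + dc; cc1 <- c1 + dc
    if (rr0 < 1 || cc0 < 1 || rr1 > nrow(image) || cc1 > ncol(image)) next
    wv <- as.vector(image[rr0:rr1, cc0:cc1])
    wv_c <- wv - mean(wv)
    denom <- tv_ss * sqrt(sum(wv_c^2))
    if (denom == 0) next
    score <- sum(tv_c * wv_c) / denom
    d2 <- dr * dr + dc * dc
    if (is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 && (d2 < best$d2 ||
          (d2 == best$d2 && (dr < best$displacement[1] ||
            (dr == best$displacement[1] && dc < best$displacement[2])))))) {
      best <- list(displacement = c(dr, dc), score = score, d2 = d2)
    }
  }
  if (is.null(best))
    stop("no-match: no admissible placement inside the image")
  list(position = c((r0 + r1) / 2 + best$displacement[1],
                    (c0 + c1) / 2 + best$displacement[2]),
       displacement = best$displacement,
       score = best$score)
}

# largest-remainder style integer split of a force over alpha frames:
# cumulative shift after j steps is sign(m) * ceiling(|m| j / alpha),
# so per-step shifts are integers summing exactly to m.
force_schedule_step <- function(m, alpha, j) {
  cum <- function(jj) sign(m) * ceiling(abs(m) * jj / alpha)
  cum(j) - cum(j - 1)
}

#' Register a moving force on the monitor
#'
#' Computes the moving force `m` as the vector from the current contour
#' centroid to the matched template position (plus the stored
#' template-to-centroid offset) and schedules it over the next `alpha`
#' frames.
#'
#' @param state a [monitor_state()].
#' @param matched_position matched template centre from [ncc_match()].
#' @param u current contour embedding.
#' @return updated state with `pending_force` set.
#' @export
set_moving_force <- function(state, matched_position, u) {
  target <- matched_position + state$centroid_offset
  m <- round(target - mask_centroid(u))
  state$force_total <- m
  state$pending_force <- m
  state$force_step <- 0L
  state
}

#' Apply one step of the moving force
#'
#' Translates the embedding by this frame's integer share of the pending
#' moving force. The per-frame shares are integers that sum exactly to the
#' registered force after `alpha` applications, distributed as evenly as
#' integer shifts allow.
#'
#' @param u binary embedding.
#' @param state a [monitor_state()] with a pending force.
#' @return `list(u, state, shift)`; error if the translation pushes the
#'   whole mask off-grid.
#' @export
apply_moving_force <- function(u, state) {
  if (all(state$pending_force == 0))
    return(list(u = u, state = state, shift = c(0L, 0L)))
  j <- state$force_step + 1L
  shift <- c(force_schedule_step(state$force_total[1], state$alpha, j),
             force_schedule_step(state$force_total[2], state$alpha, j))
  u_new <- translate_mask(u, shift[1], shift[2])
  if (sum(u_new) == 0)
    stop("tracking lost: moving force pushed the contour off the image")
  state$force_step <- j
  state$pending_force <- state$pending_force - shift
  if (j >= state$alpha) {
    state$pending_force <- c(0, 0)
    state$force_step <- 0L
    state$force_total <- c(0, 0)
  }
  list(u = u_new, state = state, shift = shift)
}
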
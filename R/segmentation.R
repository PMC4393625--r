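# The segmentation algorithm: head-point estimation (screw centre), tail
# estimation by iterative axis following, contact segmentation tip-to-head,
# and the SEEG-specific corrections (piecewise-linear axis for curved shafts,
# angle-constrained refinement for crossing shafts, hemisphere stop plane for
# bilaterally collinear shafts).

#' Segmentation configuration
#'
#' Collects the tunable parameters of the algorithm. Defaults follow the
#' method's canonical values: a 3 mm search cube grown in 1 mm steps to
#' 10 mm around the planned entry; a 3 mm centroid-refinement region; a 10
#' degree bend limit; and an axis-following step equal to the contact pitch.
#' During axis following the growing cube is capped at `follow_cap_factor`
#' times the pitch (1.5 d = 5.25 mm for the standard shaft) so that losing
#' the signal at the electrode tip cannot make the search leap onto a
#' neighbouring shaft.
#'
#' @param threshold Intensity threshold S, or `NULL` to auto-select with
#'   [auto_threshold()].
#' @param region_side Centroid-refinement region side (mm).
#' @param eps Centroid convergence tolerance (mm).
#' @param max_iter Centroid iteration cap.
#' @param search_init,search_max,search_step Growing-cube schedule (mm).
#' @param follow_cap_factor Cap of the growing cube during axis following,
#'   as a multiple of the contact pitch.
#' @param max_angle Maximum admissible bend between consecutive segments
#'   (degrees).
#' @param shrink_step Region shrink decrement of the crossing correction (mm).
#' @param hemisphere A [hemisphere_plane()] acting as the medial longitudinal
#'   fissure surrogate.
#' @param guard Whether the hemisphere stop rule is active.
#' @param max_steps Hard cap on axis-following iterations per electrode.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(threshold = NULL, region_side = 3, eps = 1e-3,
                       max_iter = 50L, search_init = 3, search_max = 10,
                       search_step = 1, follow_cap_factor = 1.5,
                       max_angle = 10, shrink_step = 0.5,
                       hemisphere = hemisphere_plane(), guard = TRUE,
                       max_steps = 100L) {
  structure(list(threshold = threshold, region_side = region_side, eps = eps,
                 max_iter = max_iter, search_init = search_init,
                 search_max = search_max, search_step = search_step,
                 follow_cap_factor = follow_cap_factor, max_angle = max_angle,
                 shrink_step = shrink_step, hemisphere = hemisphere,
                 guard = isTRUE(guard), max_steps = max_steps),
            class = "seg_config")
}

#' Hemisphere separation plane
#'
#' Plane standing in for the medial longitudinal fissure. The default is the
#' mid-sagittal plane of the RAS frame (through the origin with normal along
#' +x); override it when the scan's RAS origin is not inter-hemispheric.
#'
#' @param point A point on the plane (mm).
#' @param normal Plane normal (normalized internally).
#' @return An object of class `hemisphere_plane`.
#' @export
hemisphere_plane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  structure(list(point = .as_point3(point, "point"),
                 normal = .unit(.as_point3(normal, "normal"))),
            class = "hemisphere_plane")
}

#' Hemisphere stop rule
#'
#' An electrode implanted in one hemisphere never carries contacts in the
#' other, so the axis-following search must halt rather than run onto a
#' bilaterally collinear shaft approaching from the opposite side. The rule
#' stops the search as soon as a candidate point lies beyond the fissure
#' plane, i.e. when its signed distance to the plane has the opposite sign
#' to the head point's.
#'
#' @param plane A [hemisphere_plane()].
#' @param head Head point H (mm).
#' @param candidate Candidate axis/contact point (mm).
#' @return `TRUE` when the search must stop, `FALSE` to continue.
#' @export
hemisphere_guard <- function(plane, head, candidate) {
  stopifnot(inherits(plane, "hemisphere_plane"))
  sh <- sum((head - plane$point) * plane$normal)
  sc <- sum((candidate - plane$point) * plane$normal)
  (sh > 0 && sc < 0) || (sh < 0 && sc > 0)
}

.stop_not_found <- function(label, where) {
  cond <- structure(
    class = c("seegloc_electrode_not_found", "error", "condition"),
    list(message = sprintf("electrode%s not found %s",
                           if (nzchar(label)) paste0(" '", label, "'") else "",
                           where),
         call = NULL))
  stop(cond)
}

#' Estimate the head point (screw centre) of an electrode
#'
#' The most superficial electrode point is masked by the metal artifact of
#' the anchoring screw, but the screw centre approximates it well. Starting
#' from the planned entry point, a significant voxel is sought in a cube
#' grown from 3 to 10 mm in 1 mm steps; from that seed the centre of mass is
#' refined iteratively to convergence. No significant voxel within 10 mm
#' means the electrode is absent at its planned entry, which is an error for
#' this electrode only (class `seegloc_electrode_not_found`).
#'
#' @param vol Thresholded [voxel_volume()].
#' @param entry Planned entry point E (mm).
#' @param S Intensity threshold.
#' @param config A [seg_config()].
#' @param label Electrode label used in error messages.
#' @return The head point H (mm).
#' @export
estimate_head <- function(vol, entry, S, config = seg_config(), label = "") {
  entry <- .as_point3(entry, "entry")
  q0 <- find_significant_voxel(vol, entry, S, config$search_init,
                               config$search_max, config$search_step)
  if (is.null(q0))
    .stop_not_found(label, sprintf("at planned entry (no voxel above S within %g mm)",
                                   config$search_max))
  .refine_lenient(vol, q0, config$region_side, S, config$eps, config$max_iter)
}

# One axis-following step: from prev1 continue along direction prev2->prev1
# for step_dist, search a significant voxel near the extrapolated point in a
# cube grown up to l_cap, and refine it to a centroid (angle-constrained when
# `constrain`).  Returns NULL on signal loss.
.follow_step <- function(vol, prev1, prev2, step_dist, S, config, l_cap,
                         constrain) {
  s <- prev1 + .unit(prev1 - prev2) * step_dist
  q0 <- find_significant_voxel(vol, s, S, min(config$search_init, l_cap),
                               l_cap, config$search_step)
  if (is.null(q0)) return(NULL)
  cand <- if (constrain) {
    .refine_with_angle(vol, q0, prev1, prev2, S, config$region_side,
                       config$max_angle, config$shrink_step, config$eps,
                       config$max_iter)
  } else {
    c <- .refine_lenient(vol, q0, config$region_side, S, config$eps,
                         config$max_iter)
    attr(c, "merged") <- FALSE
    c
  }
  list(s = s, point = cand)
}

#' Estimate the tail (tip) point by following the electrode shaft
#'
#' From the head point H the algorithm walks toward the planned target,
#' producing axis points `A_k`: each step extrapolates one contact pitch `d`
#' along the line through the previous two axis points (the first step uses
#' the H-to-target line), finds a significant voxel near the extrapolated
#' point with a growing cube, and refines it to a mass centroid. Because
#' every accepted point re-anchors the local direction, the axis is
#' piecewise linear and tracks curved shafts. The walk stops when no
#' significant voxel remains near the extrapolation (the tip has been
#' passed), when a candidate fails to advance (the tip centroid was
#' re-found), or when the hemisphere rule fires. The deepest accepted
#' centroid is the tip D.
#'
#' The bend-angle constraint is active from the second step on; the first
#' step is deliberately unconstrained because its only reference axis is the
#' planned (possibly displaced) trajectory, and correcting toward a wrong
#' plan is exactly what must not happen.
#'
#' @param vol Thresholded [voxel_volume()].
#' @param head Head point H from [estimate_head()].
#' @param target Planned target point T (mm).
#' @param S Intensity threshold.
#' @param model [electrode_model()] supplying the step length d.
#' @param config A [seg_config()].
#' @param label Electrode label for error messages.
#' @return List with `tip` (point D) and `axis` (matrix of axis points, one
#'   row per point, first row = H).
#' @export
estimate_tail <- function(vol, head, target, S, model = electrode_model(),
                          config = seg_config(), label = "") {
  head <- .as_point3(head, "head"); target <- .as_point3(target, "target")
  d <- model$spacing
  l_cap <- min(config$search_max, config$follow_cap_factor * d)
  axis <- list(head)
  prev1 <- head
  prev2 <- head - .unit(target - head) * d   # virtual point behind H
  walked <- 0
  for (k in seq_len(config$max_steps)) {
    # planned geometry bounds the shaft: walking farther than the planned
    # head-target length (plus one pitch of slack) can only run onto another
    # shaft, so the tip must already have been passed
    if (walked + d > .dist3(head, target) + d) break
    st <- .follow_step(vol, prev1, prev2, d, S, config, l_cap,
                       constrain = k >= 2L)
    if (is.null(st)) break
    cand <- as.numeric(st$point)
    if (config$guard && hemisphere_guard(config$hemisphere, head, cand)) break
    if (.dist3(cand, prev1) < d / 2) break   # re-found the tip centroid
    walked <- walked + .dist3(cand, prev1)
    axis[[length(axis) + 1L]] <- cand
    prev2 <- prev1
    prev1 <- cand
  }
  if (length(axis) == 1L)
    .stop_not_found(label, "along planned axis (no significant voxel beyond head)")
  list(tip = axis[[length(axis)]],
       axis = do.call(rbind, axis))
}

#' Segment the contacts of one electrode
#'
#' Runs the same follow-and-refine loop as the tail estimation, but from the
#' tip D toward the head H with the contact pitch `d` as step. The first
#' search point lies at `d/2` from D; because D is itself the refined
#' centroid of the deepest contact, the first refined candidate either
#' re-finds that contact (it then becomes contact 1) or lands on the next
#' contact up the shaft (D is then recorded as contact 1 and the candidate
#' as contact 2). Contacts are numbered 1..N from the tip. The walk stops at
#' the model's contact count, on signal loss, when the head region is
#' reached, or when a step lands outside 75-125% of the pitch (the shaft
#' geometry admits no such spacing).
#'
#' @param vol Thresholded [voxel_volume()].
#' @param tip Tip point D from [estimate_tail()].
#' @param axis Axis matrix from [estimate_tail()] (recorded on the result).
#' @param head Head point H.
#' @param model [electrode_model()]; an `NA` contact count runs to signal
#'   loss (detections beyond a known count are flagged, not kept).
#' @param S Intensity threshold.
#' @param config A [seg_config()].
#' @param label Electrode label.
#' @return An object of class `seeg_electrode`: label, `contacts` (N x 3
#'   matrix, row 1 = tip contact), `head`, `tip`, `axis`, `model`,
#'   `merged` flags and `stop_reason`.
#' @export
segment_contacts <- function(vol, tip, axis, head, model = electrode_model(),
                             S, config = seg_config(), label = "") {
  tip <- .as_point3(tip, "tip"); head <- .as_point3(head, "head")
  d <- model$spacing
  l_cap <- min(config$search_max, config$follow_cap_factor * d)
  n_max <- if (is.na(model$n_contacts)) 30L else model$n_contacts
  contacts <- list()
  merged <- logical()
  stop_reason <- "head_region"
  prev1 <- tip
  prev2 <- tip - .unit(head - tip) * d   # virtual: first direction tip -> head
  first <- TRUE
  while (length(contacts) < n_max) {
    step_dist <- if (first) d / 2 else d
    s <- prev1 + .unit(prev1 - prev2) * step_dist
    if (.dist3(s, head) < d / 2) { stop_reason <- "head_region"; break }
    st <- .follow_step(vol, prev1, prev2, step_dist, S, config, l_cap,
                       constrain = TRUE)
    if (is.null(st)) { stop_reason <- "signal_loss"; break }
    cand <- as.numeric(st$point)
    if (config$guard && hemisphere_guard(config$hemisphere, head, cand)) {
      stop_reason <- "hemisphere"; break
    }
    adv <- .dist3(cand, prev1)
    if (first) {
      # D is the deepest contact's centroid: the first candidate either
      # re-refines it (contact 1) or has skipped to contact 2.
      if (adv <= d / 2) {
        contacts[[1L]] <- cand
        merged[1L] <- isTRUE(attr(st$point, "merged"))
      } else {
        contacts[[1L]] <- tip
        merged[1L] <- FALSE
        if (adv <= 1.25 * d) {
          contacts[[2L]] <- cand
          merged[2L] <- isTRUE(attr(st$point, "merged"))
        }
      }
      prev2 <- if (length(contacts) >= 2L) contacts[[1L]] else prev2
      prev1 <- contacts[[length(contacts)]]
      first <- FALSE
      next
    }
    if (adv < 0.75 * d || adv > 1.25 * d) { stop_reason <- "spacing"; break }
    contacts[[length(contacts) + 1L]] <- cand
    merged[length(contacts)] <- isTRUE(attr(st$point, "merged"))
    prev2 <- prev1
    prev1 <- cand
  }
  if (length(contacts) >= n_max) stop_reason <- "contact_count"
  if (length(contacts) == 0L)
    .stop_not_found(label, "during contact segmentation (zero contacts)")
  cm <- do.call(rbind, contacts)
  rownames(cm) <- paste0(label, seq_len(nrow(cm)))
  structure(list(label = label, contacts = cm, head = head, tip = tip,
                 axis = axis, model = model, merged = merged,
                 n_expected = model$n_contacts, stop_reason = stop_reason,
                 status = "ok"),
            class = "seeg_electrode")
}

#' @export
print.seeg_electrode <- function(x, ...) {
  cat(sprintf("<seeg_electrode> '%s': %d contact(s)%s, stop: %s\n",
              x$label, nrow(x$contacts),
              if (!is.na(x$n_expected)) sprintf(" of %d expected", x$n_expected)
              else "",
              x$stop_reason))
  invisible(x)
}

# full per-electrode pipeline; errors propagate to segment_implant
.segment_electrode <- function(vol, traj, model, S, config) {
  H <- estimate_head(vol, traj$entry, S, config, label = traj$label)
  tl <- estimate_tail(vol, H, traj$target, S, model, config,
                      label = traj$label)
  segment_contacts(vol, tl$tip, tl$axis, H, model, S, config,
                   label = traj$label)
}

#' Segment a whole implant
#'
#' Runs head estimation, tail estimation and contact segmentation for every
#' planned trajectory. Failures are isolated per electrode: an electrode
#' whose entry or shaft cannot be found is recorded in `failures` (a missed
#' electrode, i.e. false negatives) and the remaining electrodes proceed.
#' The algorithm contains no randomness, so identical inputs give identical
#' outputs.
#'
#' @param vol Thresholded post-implant CT [voxel_volume()] (apply
#'   [subtract_volumes()] and [apply_threshold()] upstream if needed).
#' @param trajectories List of [planned_trajectory()] objects.
#' @param models `NULL`, a single [electrode_model()] for all electrodes, or
#'   a named list keyed by electrode label (`"*"` = fallback).
#' @param config A [seg_config()]; a `NULL` threshold is auto-selected from
#'   the volume histogram.
#' @return An object of class `seeg_implant`: named list `electrodes`,
#'   `failures`, the threshold `S` used, and the `config`.
#' @export
segment_implant <- function(vol, trajectories, models = NULL,
                            config = seg_config()) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (length(trajectories) == 0L) {
    warning("no trajectories supplied; returning an empty implant",
            call. = FALSE)
    return(structure(list(electrodes = list(), failures = list(),
                          threshold = config$threshold, config = config),
                     class = "seeg_implant"))
  }
  labels <- vapply(trajectories, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate electrode labels in trajectory list", call. = FALSE)
  S <- if (is.null(config$threshold)) auto_threshold(vol) else config$threshold
  trajectories <- .trajectories_to_ct_space(trajectories, vol)
  electrodes <- list()
  failures <- list()
  for (tr in trajectories) {
    model <- .model_for_label(models, tr$label)
    res <- tryCatch(.segment_electrode(vol, tr, model, S, config),
                    error = function(e) e)
    if (inherits(res, "seeg_electrode")) {
      electrodes[[tr$label]] <- res
    } else {
      failures[[tr$label]] <- conditionMessage(res)
    }
  }
  structure(list(electrodes = electrodes, failures = failures,
                 threshold = S, config = config),
            class = "seeg_implant")
}

#' @export
print.seeg_implant <- function(x, ...) {
  n <- vapply(x$electrodes, function(e) nrow(e$contacts), 0L)
  cat(sprintf("<seeg_implant> %d electrode(s), %d contact(s), threshold S = %s\n",
              length(x$electrodes), sum(n),
              format(x$threshold, digits = 6)))
  if (length(x$failures))
    cat(sprintf("  failed: %s\n", paste(names(x$failures), collapse = ", ")))
  invisible(x)
}
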
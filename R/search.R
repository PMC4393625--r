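# The two primitive searches used everywhere: growing-cube significant-voxel
# search, and iterative centre-of-mass (centroid) refinement, plus the
# angle-constrained variant used by the crossing-electrode correction.

.sides_schedule <- function(l_init, l_max, l_step) {
  if (l_init > l_max)
    stop("'l_init' must not exceed 'l_max'", call. = FALSE)
  if (l_step <= 0) stop("'l_step' must be positive", call. = FALSE)
  s <- seq(l_init, l_max, by = l_step)
  if (s[length(s)] < l_max - 1e-9) s <- c(s, l_max)
  s
}

#' Search for a significant voxel in a growing cubic region
#'
#' Looks for a voxel with intensity strictly above `S` inside a cube centred
#' at `center`, starting at side `l_init` (3 mm by default) and enlarging in
#' `l_step` (1 mm) increments up to `l_max` (10 mm). The first region
#' containing significant voxels wins; within it, by default the voxel
#' nearest to the region centre is chosen (deterministic; ties fall back to
#' column-major voxel order). `order = "lexicographic"` instead takes the
#' first significant voxel in column-major voxel-index order.
#'
#' Absence is a value, not an error: `NULL` is returned when the schedule is
#' exhausted, and downstream this is what terminates the axis follow at the
#' electrode tip.
#'
#' @param vol A [voxel_volume()].
#' @param center Search centre (mm).
#' @param S Significance threshold: a voxel counts iff `I > S`.
#' @param l_init,l_max,l_step Region side schedule in mm.
#' @param order Voxel selection rule within the first non-empty region.
#' @return Voxel-centre coordinates (mm) of the found voxel, or `NULL`.
#' @export
find_significant_voxel <- function(vol, center, S,
                                   l_init = 3, l_max = 10, l_step = 1,
                                   order = c("nearest", "lexicographic")) {
  stopifnot(inherits(vol, "voxel_volume"))
  center <- .as_point3(center, "center")
  order <- match.arg(order)
  for (side in .sides_schedule(l_init, l_max, l_step)) {
    rv <- .region_voxels(vol, center, side)
    if (is.null(rv)) next
    sel <- which(rv$I > S)
    if (length(sel) == 0L) next
    if (order == "nearest") {
      d2 <- (rv$x[sel] - center[1])^2 + (rv$y[sel] - center[2])^2 +
            (rv$z[sel] - center[3])^2
      pick <- sel[which.min(d2)]
    } else {
      pick <- sel[1L]
    }
    return(c(rv$x[pick], rv$y[pick], rv$z[pick]))
  }
  NULL
}

.stop_no_convergence <- function(last, iter) {
  cond <- structure(
    class = c("seegloc_no_convergence", "error", "condition"),
    list(message = sprintf(
      "centroid refinement did not converge in %d iterations (last iterate %.4f, %.4f, %.4f)",
      iter, last[1], last[2], last[3]),
      call = NULL, last = last))
  stop(cond)
}

#' Iterative centroid refinement
#'
#' Iterates the centre-of-mass map: starting at `start`, repeatedly computes
#' the centre of mass of the cube of side `side` centred at the previous
#' iterate, until two consecutive iterates differ by less than `eps` mm.
#' Only voxels with `I > S` carry mass. Because the centre of mass of a
#' fixed voxel set is exact, the iteration typically reaches an exact fixed
#' point (the region's voxel set stops changing) within a few iterations on
#' an isolated blob.
#'
#' @param vol A [voxel_volume()].
#' @param start Starting point (mm); the region around it must contain
#'   above-threshold mass.
#' @param side Region side in mm. The 3 mm default exceeds the 2 mm contact
#'   length while staying below the 3.5 mm contact pitch, so neighbouring
#'   contacts never share a region on an undistorted shaft.
#' @param S Significance threshold.
#' @param eps Convergence tolerance in mm.
#' @param max_iter Iteration cap; exceeding it raises a
#'   `seegloc_no_convergence` error carrying the last iterate.
#' @return The converged centroid (mm).
#' @export
refine_centroid <- function(vol, start, side = 3, S = -Inf,
                            eps = 1e-3, max_iter = 50L) {
  stopifnot(inherits(vol, "voxel_volume"))
  q <- .as_point3(start, "start")
  for (i in seq_len(max_iter)) {
    qn <- .region_com(vol, q, side, S)
    if (is.null(qn)) .stop_empty_region(q, side)
    if (.dist3(qn, q) < eps) return(qn)
    q <- qn
  }
  .stop_no_convergence(q, max_iter)
}

# refine, but tolerate non-convergence by returning the last iterate
.refine_lenient <- function(vol, start, side, S, eps, max_iter) {
  tryCatch(refine_centroid(vol, start, side, S, eps, max_iter),
           seegloc_no_convergence = function(e) e$last)
}

# Shared shrink loop: refine from q0, and while the implied bend angle at
# prev1 exceeds max_angle, shrink the region and re-refine.  Returns the
# centroid with attributes "angle" and "merged".
.refine_with_angle <- function(vol, q0, prev1, prev2, S, side, max_angle,
                               shrink_step, eps, max_iter) {
  # a candidate coinciding with prev1 implies no bend at all
  bend <- function(cand)
    if (.dist3(cand, prev1) < 1e-6) 0 else segment_angle(prev2, prev1, cand)
  cand <- .refine_lenient(vol, q0, side, S, eps, max_iter)
  ang <- bend(cand)
  merged <- FALSE
  cur <- side
  while (ang > max_angle + 1e-9) {
    cur <- cur - shrink_step
    if (cur <= 1e-9) { merged <- TRUE; break }
    nxt <- tryCatch(.refine_lenient(vol, q0, cur, S, eps, max_iter),
                    seegloc_empty_region = function(e) NULL)
    if (is.null(nxt)) { merged <- TRUE; break }
    cand <- nxt
    ang <- bend(cand)
  }
  attr(cand, "angle") <- ang
  attr(cand, "merged") <- merged
  cand
}

#' Angle-constrained centroid refinement
#'
#' Refinement step with the crossing-electrode correction: when two shafts
#' cross, metal artifact merges their contacts into one voxel mass and the
#' plain centre of mass is dragged off-axis. Electrode geometry bounds the
#' bend between consecutive inter-contact segments at about 10 degrees, so
#' if the refined centroid implies a larger bend at `prev1` (relative to the
#' segment `prev2 -> prev1`), the region is shrunk in `shrink_step`
#' decrements and the refinement repeated until the angle is admissible or
#' the region vanishes. A vanished region returns the last centroid flagged
#' with attribute `merged = TRUE` (a merged-contact diagnostic).
#'
#' @param vol A [voxel_volume()].
#' @param s_k Search point; a significant voxel is first sought in the cube
#'   of side `side` centred here (empty cube raises `seegloc_empty_region`).
#' @param prev1,prev2 The two previous axis/contact points (`prev1` the most
#'   recent); the bend is measured at `prev1`.
#' @param S Significance threshold.
#' @param side Initial region side (mm).
#' @param max_angle Maximum admissible bend in degrees (default 10).
#' @param shrink_step Region shrink decrement in mm.
#' @param eps,max_iter Refinement controls, as in [refine_centroid()].
#' @return Centroid (mm) with attributes `angle` and `merged`.
#' @export
constrained_centroid <- function(vol, s_k, prev1, prev2, S, side = 3,
                                 max_angle = 10, shrink_step = 0.5,
                                 eps = 1e-3, max_iter = 50L) {
  s_k <- .as_point3(s_k, "s_k")
  prev1 <- .as_point3(prev1, "prev1"); prev2 <- .as_point3(prev2, "prev2")
  q0 <- find_significant_voxel(vol, s_k, S, l_init = side, l_max = side,
                               l_step = side)
  if (is.null(q0)) .stop_empty_region(s_k, side)
  .refine_with_angle(vol, q0, prev1, prev2, S, side, max_angle,
                     shrink_step, eps, max_iter)
}
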
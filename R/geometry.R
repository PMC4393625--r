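# Points, lines, cubic regions, image moments and centres of mass.
# All geometry is in physical millimetres; voxels enter only through the
# volume affine, which maps 0-based voxel indices to world (RAS) coordinates
# of voxel centres.

.as_point3 <- function(p, arg = "point") {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p)))
    stop(sprintf("'%s' must be a finite numeric vector of length 3", arg),
         call. = FALSE)
  as.double(p)
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12)
    stop("undefined axis: direction vector has zero length", call. = FALSE)
  v / n
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Point at a signed distance along the line through two points
#'
#' Returns the point `p1 + d * (p2 - p1)/||p2 - p1||`, i.e. the point on the
#' straight line through `p1` and `p2` lying at signed distance `d` from `p1`
#' in the direction of `p2`.
#'
#' @param p1,p2 Numeric length-3 points (mm). Must be distinct.
#' @param d Signed distance in mm; negative values step away from `p2`.
#' @return A numeric length-3 point.
#' @export
#' @examples
#' point_at_distance(c(0, 0, 0), c(0, 0, 2), 3.5)   # (0, 0, 3.5)
point_at_distance <- function(p1, p2, d) {
  p1 <- .as_point3(p1, "p1"); p2 <- .as_point3(p2, "p2")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d))
    stop("'d' must be a finite scalar distance in mm", call. = FALSE)
  p1 + .unit(p2 - p1) * d
}

#' Angle between two consecutive segments
#'
#' Angle, in degrees within \[0, 180\], between the directions `b - a` and
#' `c - b`. Collinear points give 0. This is the bend angle used by the
#' crossing-electrode correction, which accepts deviations of at most 10
#' degrees between consecutive inter-contact segments.
#'
#' @param a,b,c Numeric length-3 points; `a != b` and `b != c`.
#' @return Angle in degrees.
#' @export
segment_angle <- function(a, b, c) {
  a <- .as_point3(a, "a"); b <- .as_point3(b, "b"); c <- .as_point3(c, "c")
  u <- .unit(b - a)
  v <- .unit(c - b)
  cosang <- max(-1, min(1, sum(u * v)))
  acos(cosang) * 180 / pi
}

#' Axis-aligned cubic region
#'
#' A cube `R(c, l)` of side `l` mm centred at `c`; a voxel belongs to the
#' region iff each coordinate of its centre lies within `l/2` of the centre
#' (boundary inclusive).
#'
#' @param center Numeric length-3 centre (mm).
#' @param side Side length in mm, `> 0`.
#' @return An object of class `cubic_region`.
#' @export
cubic_region <- function(center, side) {
  center <- .as_point3(center, "center")
  if (!is.numeric(side) || length(side) != 1L || !is.finite(side) || side <= 0)
    stop("'side' must be a positive length in mm", call. = FALSE)
  structure(list(center = center, side = as.double(side)),
            class = "cubic_region")
}

# Voxel centres and intensities of a volume inside a cubic region.
# Returns NULL when the region does not intersect the volume.  The voxels
# come back in column-major order of their indices (first index fastest),
# which fixes a deterministic scan order.
.region_voxels <- function(vol, center, side, tol = 1e-9) {
  half <- side / 2
  inv <- vol$inv_affine
  vc <- inv[1:3, 1:3] %*% center + inv[1:3, 4]
  ext <- abs(inv[1:3, 1:3]) %*% rep(half, 3)
  dm <- dim(vol$data)
  lo <- pmax(floor(vc - ext - 1e-6), 0)
  hi <- pmin(ceiling(vc + ext + 1e-6), dm - 1)
  if (any(lo > hi)) return(NULL)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  A <- vol$affine
  X <- A[1, 4] + outer(outer(ii * A[1, 1], jj * A[1, 2], `+`), kk * A[1, 3], `+`)
  Y <- A[2, 4] + outer(outer(ii * A[2, 1], jj * A[2, 2], `+`), kk * A[2, 3], `+`)
  Z <- A[3, 4] + outer(outer(ii * A[3, 1], jj * A[3, 2], `+`), kk * A[3, 3], `+`)
  keep <- abs(X - center[1]) <= half + tol &
          abs(Y - center[2]) <= half + tol &
          abs(Z - center[3]) <= half + tol
  if (!any(keep)) return(NULL)
  sub <- vol$data[ii + 1L, jj + 1L, kk + 1L, drop = FALSE]
  list(x = X[keep], y = Y[keep], z = Z[keep], I = as.double(sub[keep]))
}

.stop_empty_region <- function(center, side) {
  cond <- structure(
    class = c("seegloc_empty_region", "error", "condition"),
    list(message = sprintf(
      "empty region: no mass in cube of side %.3g mm at (%.2f, %.2f, %.2f)",
      side, center[1], center[2], center[3]),
      call = NULL))
  stop(cond)
}

#' Image moment over a cubic region
#'
#' The raw moment of order `p + q + r`,
#' `M_pqr = sum x^p y^q z^r I(x, y, z)`, summed over the voxel centres
#' (physical mm coordinates) falling inside the region. `M_000` is the total
#' mass of the region. Regions are clipped at the volume boundary; a region
#' entirely outside the volume yields 0 with a warning.
#'
#' @param vol A [voxel_volume()].
#' @param region A [cubic_region()].
#' @param p,q,r Non-negative integer orders.
#' @return Scalar moment value.
#' @export
region_moment <- function(vol, region, p = 0, q = 0, r = 0) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(region, "cubic_region"))
  for (o in c(p, q, r))
    if (!is.numeric(o) || length(o) != 1L || o < 0 || o != round(o))
      stop("moment orders p, q, r must be non-negative integers", call. = FALSE)
  rv <- .region_voxels(vol, region$center, region$side)
  if (is.null(rv)) {
    warning("region lies entirely outside the volume; moment is 0",
            call. = FALSE)
    return(0)
  }
  sum(rv$x^p * rv$y^q * rv$z^r * rv$I)
}

#' Centre of mass of a cubic region
#'
#' `(M_100/M_000, M_010/M_000, M_001/M_000)` computed over the region.
#' A region with no mass (total `M_000 <= 0`) raises an error of class
#' `seegloc_empty_region`; downstream this condition drives the stop criteria
#' of the axis-following search.
#'
#' @inheritParams region_moment
#' @return Numeric length-3 point (mm).
#' @export
center_of_mass <- function(vol, region) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(region, "cubic_region"))
  com <- .region_com(vol, region$center, region$side)
  if (is.null(com)) .stop_empty_region(region$center, region$side)
  com
}

# Fast internal centre of mass: voxels with I > S contribute their intensity,
# others nothing.  Returns NULL for an empty/massless region.
.region_com <- function(vol, center, side, S = -Inf) {
  rv <- .region_voxels(vol, center, side)
  if (is.null(rv)) return(NULL)
  w <- ifelse(rv$I > S, rv$I, 0)
  m0 <- sum(w)
  if (m0 <= 0) return(NULL)
  c(sum(rv$x * w), sum(rv$y * w), sum(rv$z * w)) / m0
}
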
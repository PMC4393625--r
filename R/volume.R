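# Volume container, NIfTI IO, CT subtraction and thresholding.

#' 3D scalar volume with a voxel-to-world affine
#'
#' Wraps a 3D intensity array together with the 4x4 affine mapping 0-based
#' voxel indices to physical (RAS, mm) coordinates of voxel centres. All
#' algorithmic geometry in this package operates in physical mm through this
#' mapping, so anisotropic voxels (e.g. the 0.4 x 0.4 x 0.8 mm cone-beam CT
#' grid) are handled transparently.
#'
#' @param data Numeric 3D array of intensities.
#' @param affine 4x4 voxel-index to mm matrix; defaults to `diag(spacing)`
#'   with the first voxel centre at the origin.
#' @param spacing Per-axis voxel size in mm, used only when `affine` is NULL.
#' @return An object of class `voxel_volume` with fields `data`, `affine`,
#'   `inv_affine` and `spacing`.
#' @export
voxel_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("'data' must have positive extent on every axis", call. = FALSE)
  storage.mode(data) <- "double"
  attributes(data) <- list(dim = dim(data))
  if (is.null(affine)) {
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("'spacing' must be strictly positive", call. = FALSE)
    affine <- diag(c(spacing, 1))
  }
  if (length(affine) != 16L || !all(is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix", call. = FALSE)
  affine <- matrix(as.double(affine), 4L, 4L)
  inv <- tryCatch(solve(affine),
                  error = function(e) stop("'affine' is not invertible",
                                           call. = FALSE))
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("'affine' has a degenerate axis", call. = FALSE)
  structure(list(data = data, affine = affine, inv_affine = inv, spacing = sp),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm, intensity [%g, %g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(sprintf("%.3g", x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

# world coordinates (mm) of a 0-based voxel index triple (or matrix n x 3)
.voxel_to_world <- function(vol, v) {
  v <- rbind(matrix(v, ncol = 3L))
  t(vol$affine[1:3, 1:3] %*% t(v) + vol$affine[1:3, 4])
}

.world_to_voxel <- function(vol, w) {
  w <- rbind(matrix(w, ncol = 3L))
  t(vol$inv_affine[1:3, 1:3] %*% t(w) + vol$inv_affine[1:3, 4])
}

#' Load a NIfTI volume
#'
#' Reads a scalar 3D NIfTI file, keeping the data, affine (sform/qform) and
#' voxel spacing intact. Intensities are used as stored: cone-beam CT is not
#' calibrated to the Hounsfield scale, so no rescaling is attempted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_volume()].
#' @export
load_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dm <- dim(arr)
  # tolerate trailing singleton dimensions (e.g. 3D stored as X x Y x Z x 1)
  while (length(dm) > 3L && dm[length(dm)] == 1L) {
    dm <- dm[-length(dm)]
    dim(arr) <- dm
  }
  if (length(dm) != 3L)
    stop(sprintf("%s: expected a scalar 3D volume, got %d dimensions",
                 path, length(dim(img))), call. = FALSE)
  voxel_volume(arr, affine = RNifti::xform(img))
}

#' Write a volume to NIfTI
#'
#' @param vol A [voxel_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- structure(vol$affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Subtract the pre-implant from the post-implant CT
#'
#' Voxelwise `post - pre` with negative values clamped to 0. Bone has
#' intensities in the same range as electrode contacts, so removing it by
#' subtraction is what makes a single global threshold usable. Both volumes
#' must already live on the same grid (registration happens upstream); any
#' shape or affine mismatch is an error, never an implicit resampling.
#'
#' @param post,pre [voxel_volume()]s on an identical grid.
#' @return A [voxel_volume()] of the clamped difference.
#' @export
subtract_volumes <- function(post, pre) {
  stopifnot(inherits(post, "voxel_volume"), inherits(pre, "voxel_volume"))
  if (!identical(dim(post$data), dim(pre$data)))
    stop("grid mismatch: post and pre volumes differ in shape", call. = FALSE)
  if (max(abs(post$affine - pre$affine)) > 1e-6)
    stop("grid mismatch: post and pre volumes differ in affine", call. = FALSE)
  voxel_volume(pmax(post$data - pre$data, 0), affine = post$affine)
}

#' Apply an intensity threshold
#'
#' Voxels strictly above `S` keep their value; all others (including voxels
#' exactly at `S`) are set to 0, matching the strict `I(p) > S` significance
#' test used throughout the segmentation.
#'
#' @param vol A [voxel_volume()].
#' @param S Threshold intensity.
#' @return A thresholded [voxel_volume()].
#' @export
apply_threshold <- function(vol, S) {
  stopifnot(inherits(vol, "voxel_volume"),
            is.numeric(S), length(S) == 1L, is.finite(S))
  d <- vol$data
  d[d <= S] <- 0
  voxel_volume(d, affine = vol$affine)
}

#' Automatic threshold selection
#'
#' Picks the threshold as the first local minimum of the intensity histogram,
#' scanning upward from the lowest bin. The histogram uses 256 equal-width
#' bins over the range of the nonzero intensities and is smoothed with a
#' 3-bin moving average before minimum detection, which suppresses spurious
#' single-bin dips. On bone-subtracted CT the first valley separates residual
#' soft tissue from the metal mode; clinical practice on the scanner that
#' motivated this package uses a fixed cut-off of 1600 in scanner units.
#'
#' @param vol A [voxel_volume()] with at least two distinct intensities.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold intensity (scalar).
#' @export
auto_threshold <- function(vol, bins = 256L) {
  stopifnot(inherits(vol, "voxel_volume"))
  v <- vol$data[vol$data > 0]
  if (length(v) == 0L || length(unique(range(v))) < 2L ||
      diff(range(v)) == 0)
    stop(paste("cannot auto-select a threshold: volume has no nonzero",
               "intensity spread; supply S manually"), call. = FALSE)
  br <- seq(min(v), max(v), length.out = bins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  # a genuine inter-mode valley, not sampling jitter on a mode's flank:
  # the smoothed count must dip below half the tallest bin seen so far
  runmax <- cummax(sm)
  for (i in 2:(bins - 1L)) {
    if (sm[i] < sm[i - 1L] && sm[i] <= sm[i + 1L] &&
        sm[i] < 0.5 * runmax[i - 1L])
      return((br[i] + br[i + 1L]) / 2)
  }
  stop(paste("histogram has no interior local minimum;",
             "supply the threshold S manually"), call. = FALSE)
}
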
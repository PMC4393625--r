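# Planned entry/target fiducial files: plain text, `#` comments, one
# `label,x,y,z` record per point, two records (entry + target) per electrode.
# This is the dialect produced by exporting planned trajectories from
# 3DSlicer-style planning tools.

.new_trajectory <- function(label, entry, target, in_ct_space = TRUE) {
  entry <- .as_point3(entry, "entry"); target <- .as_point3(target, "target")
  if (!nzchar(label)) stop("trajectory label must be non-empty", call. = FALSE)
  if (.dist3(entry, target) < 1e-9)
    stop(sprintf("electrode '%s': entry and target coincide", label),
         call. = FALSE)
  structure(list(label = label, entry = entry, target = target,
                 in_ct_space = isTRUE(in_ct_space)),
            class = "seeg_trajectory")
}

#' Planned trajectory of one electrode
#'
#' @param label Unique electrode name (conventionally a capital letter).
#' @param entry Planned entry point E (mm), the superficial end at the skull
#'   screw.
#' @param target Planned target point T (mm), the deepest end.
#' @param in_ct_space Whether the coordinates already live in the CT world
#'   space (`FALSE` mirrors the CLI `-r/--noref` flag, meaning they must be
#'   mapped through the volume affine before use).
#' @return An object of class `seeg_trajectory`.
#' @export
planned_trajectory <- function(label, entry, target, in_ct_space = TRUE)
  .new_trajectory(label, entry, target, in_ct_space)

#' Parse a fiducial file of planned entry/target points
#'
#' Lines starting with `#` and blank lines are ignored; every other line must
#' be a `label,x,y,z` record. Each label must occur exactly twice — the pair
#' defines one electrode. By default the first record of a pair is taken as
#' the entry point and the second as the target; use
#' [orient_trajectories()] against a volume, or swap with
#' `order = "target_first"`, when the planning tool wrote them the other way
#' round.
#'
#' @param path Path to the text file.
#' @param in_ct_space Recorded on each trajectory; see [planned_trajectory()].
#' @param order `"entry_first"` (default) or `"target_first"`.
#' @return List of [planned_trajectory()] objects, in file order.
#' @export
parse_fiducials <- function(path, in_ct_space = TRUE,
                            order = c("entry_first", "target_first")) {
  order <- match.arg(order)
  if (!file.exists(path))
    stop(sprintf("fiducial file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      stop(sprintf("%s: malformed record on line %d: '%s'", path, ln, raw),
           call. = FALSE)
    label <- trimws(parts[1])
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (!nzchar(label) || any(!is.finite(xyz)))
      stop(sprintf("%s: malformed record on line %d: '%s'", path, ln, raw),
           call. = FALSE)
    recs[[length(recs) + 1L]] <- list(label = label, xyz = xyz, line = ln)
  }
  labels <- vapply(recs, `[[`, "", "label")
  out <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) != 2L)
      stop(sprintf(
        "%s: label '%s' has %d record(s) (line %s); exactly one entry and one target are required",
        path, lab, length(idx),
        paste(vapply(recs[idx], `[[`, 0, "line"), collapse = ", ")),
        call. = FALSE)
    a <- recs[[idx[1]]]$xyz; b <- recs[[idx[2]]]$xyz
    if (order == "target_first") { tmp <- a; a <- b; b <- tmp }
    out[[length(out) + 1L]] <- .new_trajectory(lab, a, b, in_ct_space)
  }
  out
}

#' Write trajectories to a fiducial file
#'
#' Inverse of [parse_fiducials()]: coordinates are written with six decimal
#' places, entry record first, so a parse/write/parse round trip is stable.
#' An empty trajectory list produces a file holding only the header comment.
#'
#' @param trajectories List of [planned_trajectory()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(trajectories, path) {
  lines <- c("# planned electrode fiducials",
             "# label,x,y,z  (entry record first, then target)")
  for (tr in trajectories) {
    stopifnot(inherits(tr, "seeg_trajectory"))
    lines <- c(lines,
               sprintf("%s,%.6f,%.6f,%.6f", tr$label,
                       tr$entry[1], tr$entry[2], tr$entry[3]),
               sprintf("%s,%.6f,%.6f,%.6f", tr$label,
                       tr$target[1], tr$target[2], tr$target[3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Orient entry/target pairs against a volume
#'
#' Fiducial files do not state which record of a pair is the entry: this
#' heuristic declares the deeper point — the one farther from the volume
#' boundary — the target, since planned targets sit in deep structures while
#' entries sit at the skull. Depth is the smallest distance from the point
#' to any face of the volume, measured in mm through the affine.
#'
#' @param trajectories List of [planned_trajectory()] objects.
#' @param vol The CT [voxel_volume()] the coordinates refer to.
#' @return The list with entry/target swapped where needed.
#' @export
orient_trajectories <- function(trajectories, vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  depth <- function(p) {
    v <- as.numeric(.world_to_voxel(vol, p))
    margins <- pmin(v, dim(vol$data) - 1 - v) * vol$spacing
    min(margins)
  }
  lapply(trajectories, function(tr) {
    if (depth(tr$entry) > depth(tr$target))
      .new_trajectory(tr$label, tr$target, tr$entry, tr$in_ct_space)
    else tr
  })
}

# map trajectory coordinates (voxel indices, 0-based) into CT world space
.trajectories_to_ct_space <- function(trajectories, vol) {
  lapply(trajectories, function(tr) {
    if (tr$in_ct_space) return(tr)
    .new_trajectory(tr$label,
                    as.numeric(.voxel_to_world(vol, tr$entry)),
                    as.numeric(.voxel_to_world(vol, tr$target)),
                    in_ct_space = TRUE)
  })
}
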
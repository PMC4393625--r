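# Synthetic post-implant CT phantoms with ground truth.  The generator
# emulates the imaging conditions of a cone-beam CT SEEG acquisition after
# bone subtraction: anisotropic 0.4 x 0.4 x 0.8 mm voxels, cylindrical
# contacts (2 mm x 0.8 mm, 1.5 mm gap), a bright screw blob at each entry,
# Gaussian metal-artifact blur that merges nearby contacts, and sub-threshold
# background noise standing in for residual soft tissue.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# Rodrigues rotation of v around unit axis k by ang degrees
.rotate_about <- function(v, k, ang) {
  th <- ang * pi / 180
  v * cos(th) + .cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# run fn with a temporarily seeded RNG, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specify a synthetic implant phantom
#'
#' Each electrode descriptor is a list with `label`, `entry` (planned entry
#' E, also the screw centre), `target` (planned target T, used to aim the
#' shaft), `n_contacts`, and optionally `bend_deg`/`bend_at_contact` for a
#' curved shaft (the segment carrying contacts with index below
#' `bend_at_contact`, counted from the tip, is rotated by `bend_deg` away
#' from the planned axis) and `model` for a non-catalogue geometry.
#'
#' The actual shaft is built from the entry side: the most superficial
#' contact centre sits `screw_gap` mm deep of the screw centre and contacts
#' follow at the model pitch, so for a straight electrode the deepest
#' contact lands short of or at the planned target depending on `||E - T||`.
#'
#' Intensities mimic bone-subtracted cone-beam CT in scanner units: metal
#' far above the 1600 threshold, background noise far below it.
#'
#' @param shape Grid extent in voxels (length 3).
#' @param spacing Voxel size in mm; default the 0.4 x 0.4 x 0.8 CT grid.
#' @param origin World coordinate of the first voxel centre; default centres
#'   the grid on the origin (so the default mid-sagittal plane x = 0 bisects
#'   the volume).
#' @param electrodes List of electrode descriptors (see above).
#' @param contact_intensity,screw_intensity Metal intensities.
#' @param screw_radius Radius of the spherical screw blob (mm).
#' @param screw_gap Distance from screw centre to the most superficial
#'   contact centre (mm).
#' @param blur_sigma Metal-artifact Gaussian blur, in mm.
#' @param noise_max Background noise amplitude (uniform on `[0, noise_max]`),
#'   kept well below the threshold.
#' @param threshold Reference threshold S; contact intensity must exceed it.
#' @param seed RNG seed recorded in the spec; phantoms are bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(0.4, 0.4, 0.8), origin = NULL,
                         electrodes = list(), contact_intensity = 8000,
                         screw_intensity = 10000, screw_radius = 1.2,
                         screw_gap = 5, blur_sigma = 0.4, noise_max = 300,
                         threshold = 1600, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing) == 3L,
            all(spacing > 0))
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  if (contact_intensity <= threshold)
    stop("contact_intensity must exceed the threshold", call. = FALSE)
  if (noise_max >= threshold)
    stop("noise_max must stay below the threshold", call. = FALSE)
  electrodes <- lapply(electrodes, function(e) {
    stopifnot(!is.null(e$label), !is.null(e$entry), !is.null(e$target))
    e$entry <- .as_point3(e$entry, "entry")
    e$target <- .as_point3(e$target, "target")
    if (is.null(e$model)) e$model <- default_model(e$n_contacts)
    e$n_contacts <- e$model$n_contacts
    if (is.null(e$bend_deg)) e$bend_deg <- 0
    e
  })
  structure(list(shape = as.integer(shape), spacing = as.double(spacing),
                 origin = as.double(origin), electrodes = electrodes,
                 contact_intensity = contact_intensity,
                 screw_intensity = screw_intensity,
                 screw_radius = screw_radius, screw_gap = screw_gap,
                 blur_sigma = blur_sigma, noise_max = noise_max,
                 threshold = threshold, seed = seed),
            class = "phantom_spec")
}

# true contact-centre chain of one electrode (matrix, row 1 = tip contact),
# plus the per-contact local axis direction (entry -> tip) used to orient
# the rasterized cylinders
.electrode_chain <- function(e, screw_gap) {
  model <- e$model
  n <- model$n_contacts
  d <- model$spacing
  u0 <- .unit(e$target - e$entry)
  centers <- matrix(NA_real_, n, 3)
  dirs <- matrix(NA_real_, n, 3)
  centers[n, ] <- e$entry + screw_gap * u0
  dirs[n, ] <- u0
  u <- u0
  if (n > 1) for (k in (n - 1):1) {
    # a physical shaft bends gradually: the total bend is split over the two
    # joints flanking the bend contact, keeping each adjacent-segment
    # deviation within the method's geometric assumption
    if (e$bend_deg != 0 && !is.null(e$bend_at_contact) &&
        (k + 1 == e$bend_at_contact || k + 2 == e$bend_at_contact)) {
      ref <- if (abs(sum(u0 * c(0, 0, 1))) > 0.9) c(0, 1, 0) else c(0, 0, 1)
      ax <- .unit(.cross3(u0, ref))
      u <- .unit(.rotate_about(u, ax, e$bend_deg / 2))
    }
    centers[k, ] <- centers[k + 1, ] + d * u
    dirs[k, ] <- u
  }
  list(centers = centers, dirs = dirs)
}

# paint a solid into `arr` by voxel-coverage supersampling (4 x 4 x 2
# sub-points per anisotropic voxel); overlapping metal takes the maximum.
.paint_solid <- function(arr, origin, spacing, lo_w, hi_w, inside_fn,
                         intensity, subs = c(4L, 4L, 2L)) {
  dm <- dim(arr)
  lo <- pmax(floor((lo_w - origin) / spacing), 0)
  hi <- pmin(ceiling((hi_w - origin) / spacing), dm - 1)
  if (any(lo > hi))
    stop("phantom solid lies outside the grid", call. = FALSE)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- origin[1] + ii * spacing[1]
  ys <- origin[2] + jj * spacing[2]
  zs <- origin[3] + kk * spacing[3]
  frac <- array(0, c(length(ii), length(jj), length(kk)))
  offs <- expand.grid(
    x = ((seq_len(subs[1]) - 0.5) / subs[1] - 0.5) * spacing[1],
    y = ((seq_len(subs[2]) - 0.5) / subs[2] - 0.5) * spacing[2],
    z = ((seq_len(subs[3]) - 0.5) / subs[3] - 0.5) * spacing[3])
  for (o in seq_len(nrow(offs))) {
    X <- outer(outer(xs + offs$x[o], ys * 0, `+`), zs * 0, `+`)
    Y <- outer(outer(xs * 0, ys + offs$y[o], `+`), zs * 0, `+`)
    Z <- outer(outer(xs * 0, ys * 0, `+`), zs + offs$z[o], `+`)
    frac <- frac + inside_fn(X, Y, Z)
  }
  frac <- frac / nrow(offs)
  blk <- arr[ii + 1L, jj + 1L, kk + 1L, drop = FALSE]
  arr[ii + 1L, jj + 1L, kk + 1L] <- pmax(blk, intensity * frac)
  arr
}

.cylinder_inside <- function(center, u, half_len, radius) {
  function(X, Y, Z) {
    px <- X - center[1]; py <- Y - center[2]; pz <- Z - center[3]
    a <- px * u[1] + py * u[2] + pz * u[3]
    (abs(a) <= half_len) & (px^2 + py^2 + pz^2 - a^2 <= radius^2)
  }
}

.sphere_inside <- function(center, radius) {
  function(X, Y, Z) {
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
  }
}

# separable Gaussian blur in mm units (zero-padded edges)
.gaussian_blur3d <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dm <- dim(a)
    m <- matrix(a, nrow = dm[1])
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    f <- stats::filter(padded, k, sides = 2)
    m <- f[(r + 1):(r + dm[1]), , drop = FALSE]
    a <- array(m, dm)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a synthetic post-implant CT phantom with ground truth
#'
#' Rasterizes every contact cylinder (anti-aliased by voxel-coverage
#' fraction) and screw blob, applies the metal-artifact blur and background
#' noise, and computes ground-truth contact centroids from the blurred,
#' thresholded image mass — not the ideal cylinder centres — because image
#' mass is all any segmentation can recover; the difference isolates
#' rasterization error from algorithm error. Each truth centroid averages
#' the above-threshold voxels lying within half a pitch of the ideal contact
#' centre and closer to it than to any other metal object.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [voxel_volume()]), `truth` (per-electrode
#'   truth: `contacts` matrix with row 1 = tip, `axis` polyline, counts and
#'   planned points) and the `spec`; class `seeg_phantom`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  arr <- array(0, spec$shape)
  origin <- spec$origin; spacing <- spec$spacing
  upper <- origin + (spec$shape - 1) * spacing
  chains <- list()
  for (e in spec$electrodes) {
    ch <- .electrode_chain(e, spec$screw_gap)
    hl <- e$model$contact_length / 2
    rad <- e$model$contact_diameter / 2
    pad <- hl + rad
    ext <- rbind(ch$centers, e$entry)
    if (any(apply(ext, 2, min) - pad < origin) ||
        any(apply(ext, 2, max) + pad > upper))
      stop(sprintf("electrode '%s' exits the phantom grid", e$label),
           call. = FALSE)
    for (k in seq_len(nrow(ch$centers))) {
      cc <- ch$centers[k, ]; u <- .unit(ch$dirs[k, ])
      arr <- .paint_solid(arr, origin, spacing, cc - pad, cc + pad,
                          .cylinder_inside(cc, u, hl, rad),
                          spec$contact_intensity)
    }
    arr <- .paint_solid(arr, origin, spacing,
                        e$entry - spec$screw_radius,
                        e$entry + spec$screw_radius,
                        .sphere_inside(e$entry, spec$screw_radius),
                        spec$screw_intensity)
    chains[[e$label]] <- ch
  }
  arr <- .gaussian_blur3d(arr, spec$blur_sigma, spacing)
  arr <- .with_seed(spec$seed,
                    function() arr + array(stats::runif(length(arr), 0,
                                                        spec$noise_max),
                                           dim(arr)))
  affine <- diag(c(spacing, 1))
  affine[1:3, 4] <- origin
  vol <- voxel_volume(arr, affine = affine)

  # ground truth from the blurred, thresholded mass
  all_centers <- do.call(rbind, c(lapply(chains, `[[`, "centers"),
                                  lapply(spec$electrodes, `[[`, "entry")))
  truth_el <- list()
  for (e in spec$electrodes) {
    ch <- chains[[e$label]]
    n <- nrow(ch$centers)
    tc <- matrix(NA_real_, n, 3)
    half_pitch <- e$model$spacing / 2
    for (k in seq_len(n)) {
      cc <- ch$centers[k, ]
      rv <- .region_voxels(vol, cc, 2 * half_pitch)
      keep <- rv$I > spec$threshold
      dx <- rv$x - cc[1]; dy <- rv$y - cc[2]; dz <- rv$z - cc[3]
      d2own <- dx^2 + dy^2 + dz^2
      keep <- keep & (d2own <= half_pitch^2)
      if (any(keep)) {
        pts <- cbind(rv$x, rv$y, rv$z)[keep, , drop = FALSE]
        w <- rv$I[keep]
        # drop voxels closer to any other metal object
        d2all <- apply(all_centers, 1, function(ctr)
          (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
          (pts[, 3] - ctr[3])^2)
        d2all <- matrix(d2all, nrow = nrow(pts))
        own <- d2own[keep] <= apply(d2all, 1, min) + 1e-9
        if (any(own))
          tc[k, ] <- colSums(pts[own, , drop = FALSE] * w[own]) / sum(w[own])
      }
    }
    truth_el[[e$label]] <- list(
      label = e$label, contacts = tc, ideal_centers = ch$centers,
      axis = ch$centers[rev(seq_len(n)), , drop = FALSE],
      n_contacts = n, entry = e$entry, target = e$target, model = e$model)
  }
  truth <- structure(list(electrodes = truth_el, threshold = spec$threshold,
                          spacing = spacing, seed = spec$seed),
                     class = "phantom_truth")
  structure(list(volume = vol, truth = truth, spec = spec),
            class = "seeg_phantom")
}

#' Planned trajectories of a phantom
#'
#' @param phantom A `seeg_phantom` (or a [phantom_spec()]).
#' @return List of [planned_trajectory()] objects matching the phantom's
#'   planned entry/target points.
#' @export
phantom_trajectories <- function(phantom) {
  spec <- if (inherits(phantom, "seeg_phantom")) phantom$spec else phantom
  stopifnot(inherits(spec, "phantom_spec"))
  lapply(spec$electrodes, function(e)
    planned_trajectory(e$label, e$entry, e$target))
}

#' Electrode models of a phantom implant
#'
#' @param phantom A `seeg_phantom` (or [phantom_spec()]).
#' @return Named list of [electrode_model()]s keyed by label, as known from
#'   the implant plan.
#' @export
phantom_models <- function(phantom) {
  spec <- if (inherits(phantom, "seeg_phantom")) phantom$spec else phantom
  ms <- lapply(spec$electrodes, `[[`, "model")
  names(ms) <- vapply(spec$electrodes, `[[`, "", "label")
  ms
}

#' Write phantom ground truth to text files
#'
#' Truth contact centroids go to a fiducial-dialect text file (one
#' `labelK,x,y,z` record per contact, tip first) and per-electrode metadata
#' (counts, planned points, seed) to a JSON sidecar.
#'
#' @param truth A `phantom_truth`.
#' @param path Output path for the text file; the sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  lines <- "# phantom ground-truth contact centroids (tip = contact 1)"
  meta <- list()
  for (el in truth$electrodes) {
    for (k in seq_len(el$n_contacts))
      lines <- c(lines, sprintf("%s%d,%.6f,%.6f,%.6f", el$label, k,
                                el$contacts[k, 1], el$contacts[k, 2],
                                el$contacts[k, 3]))
    meta[[el$label]] <- list(n_contacts = el$n_contacts,
                             entry = el$entry, target = el$target)
  }
  writeLines(lines, path)
  jsonlite::write_json(list(seed = truth$seed, threshold = truth$threshold,
                            electrodes = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Standard phantom implant used by the robustness experiments
#'
#' A seeded implant of `n_electrodes` straight multi-contact shafts (8-18
#' contacts each) on the anisotropic CT grid: entries on the lateral (+x)
#' face in a 5 x 2 grid, trajectories running medially with small random
#' angulations, screw at each entry. The layout keeps shafts at least ~7 mm
#' apart so phantoms isolate algorithmic behaviour from implant-design
#' pathologies (which get dedicated phantoms in the tests).
#'
#' @param seed Seed controlling contact counts and angulations.
#' @param n_electrodes Number of electrodes (max 10 in the fixed layout).
#' @return A [phantom_spec()].
#' @export
cohort_phantom_spec <- function(seed = 1L, n_electrodes = 10L) {
  stopifnot(n_electrodes >= 1L, n_electrodes <= 10L)
  shape <- c(190L, 170L, 40L)
  spacing <- c(0.4, 0.4, 0.8)
  origin <- c(2, 0, 0)
  rows <- 10 + 12 * (0:4)        # y positions
  cols <- c(10, 22)              # z positions
  .with_seed(seed, function() {
    ns <- sample(8:18, n_electrodes, replace = TRUE)
    electrodes <- vector("list", n_electrodes)
    for (i in seq_len(n_electrodes)) {
      y <- rows[((i - 1) %% 5) + 1]
      z <- cols[((i - 1) %/% 5) + 1]
      entry <- c(74, y, z)
      u <- .unit(c(-1, stats::runif(1, -0.04, 0.04),
                   stats::runif(1, -0.04, 0.04)))
      len <- 5 + (ns[i] - 1) * 3.5
      electrodes[[i]] <- list(label = LETTERS[i], entry = entry,
                              target = entry + len * u, n_contacts = ns[i])
    }
    phantom_spec(shape = shape, spacing = spacing, origin = origin,
                 electrodes = electrodes, seed = seed)
  })
}
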
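# Shared phantom builders and independent oracles.  Heavier fixtures are
# built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# one straight 8-contact electrode on the anisotropic CT grid
mini_phantom_spec <- function(seed = 7, n_contacts = 8, bend_deg = 0,
                              bend_at_contact = NULL) {
  u <- c(-1, 0.02, 0.01); u <- u / sqrt(sum(u * u))
  len <- 5 + (n_contacts - 1) * 3.5
  e <- c(74, 12, 14)
  phantom_spec(shape = c(190, 60, 40), origin = c(2, 0, 0),
               electrodes = list(list(label = "A", entry = e,
                                      target = e + len * u,
                                      n_contacts = n_contacts,
                                      bend_deg = bend_deg,
                                      bend_at_contact = bend_at_contact)),
               seed = seed)
}

mini_phantom <- function() memo("mini", function() make_phantom(mini_phantom_spec()))

curved_phantom <- function() memo("curved", function() {
  u <- c(-1, 0.02, 0.01); u <- u / sqrt(sum(u * u))
  e <- c(52, 20, 14.2)
  make_phantom(phantom_spec(
    shape = c(150, 80, 40), origin = c(2, 0, 0),
    electrodes = list(list(label = "C", entry = e, target = e + 43.5 * u,
                           n_contacts = 12, bend_deg = 10,
                           bend_at_contact = 6)),
    seed = 11))
})

# electrode B crosses A at 45 degrees, one of its contacts 1.8 mm off A's
# contact 6 and slice-centred (brighter) while A sits between slices:
# the blurred masses merge and drag the plain centre of mass off-axis
crossing_phantom <- function() memo("crossing", function() {
  eA <- c(50, 20, 14.0)
  cross_pt <- c(38, 21.8, 14.4)
  dirB <- c(-cos(pi / 4), -sin(pi / 4), 0)
  eB <- cross_pt - 22.5 * dirB
  make_phantom(phantom_spec(
    shape = c(150, 120, 40), origin = c(2, 0, 0),
    electrodes = list(
      list(label = "A", entry = eA, target = eA + 29.5 * c(-1, 0, 0),
           n_contacts = 8),
      list(label = "B", entry = eB, target = eB + 33 * dirB,
           n_contacts = 9)),
    seed = 5))
})

# two collinear 9-contact shafts implanted from opposite hemispheres,
# tips 4 mm apart across the x = 0 midplane
bilateral_phantom <- function() memo("bilateral", function() {
  make_phantom(phantom_spec(
    shape = c(200, 60, 40),
    electrodes = list(
      list(label = "R", entry = c(35, 0, 0), target = c(2, 0, 0),
           n_contacts = 9),
      list(label = "L", entry = c(-35, 0, 0), target = c(-2, 0, 0),
           n_contacts = 9)),
    seed = 13))
})

# the seeded five-implant cohort used by the robustness experiments
cohort_phantoms <- function() memo("cohort", function()
  lapply(1:5, function(i) make_phantom(cohort_phantom_spec(seed = 100 + i))))

segment_phantom <- function(ph, guard = TRUE) {
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  segment_implant(vol, phantom_trajectories(ph), phantom_models(ph),
                  seg_config(threshold = ph$spec$threshold, guard = guard))
}

# ---- independent oracles -------------------------------------------------

# literal triple-loop region moment (independent of .region_voxels)
brute_moment <- function(vol, center, side, p, q, r) {
  dm <- dim(vol$data)
  acc <- 0
  for (i in 0:(dm[1] - 1)) for (j in 0:(dm[2] - 1)) for (k in 0:(dm[3] - 1)) {
    w <- as.numeric(vol$affine %*% c(i, j, k, 1))[1:3]
    if (all(abs(w - center) <= side / 2 + 1e-9))
      acc <- acc + w[1]^p * w[2]^q * w[3]^r * vol$data[i + 1, j + 1, k + 1]
  }
  acc
}

brute_com <- function(vol, center, side) {
  m0 <- brute_moment(vol, center, side, 0, 0, 0)
  c(brute_moment(vol, center, side, 1, 0, 0),
    brute_moment(vol, center, side, 0, 1, 0),
    brute_moment(vol, center, side, 0, 0, 1)) / m0
}

# distance from a point to a piecewise-linear polyline (rows = vertices)
dist_to_polyline <- function(p, poly) {
  dmin <- Inf
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab * ab)))
    dmin <- min(dmin, sqrt(sum((a + t * ab - p)^2)))
  }
  dmin
}

# intensity-weighted centroid of above-threshold voxels assigned to an ideal
# contact centre, recomputed by direct array scanning
oracle_contact_centroid <- function(vol, center, all_centers, S,
                                    radius = 1.75) {
  dm <- dim(vol$data)
  org <- vol$affine[1:3, 4]
  sp <- diag(vol$affine)[1:3]
  lo <- pmax(floor((center - radius - org) / sp), 0)
  hi <- pmin(ceiling((center + radius - org) / sp), dm - 1)
  num <- c(0, 0, 0); den <- 0
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    v <- vol$data[i + 1, j + 1, k + 1]
    if (v <= S) next
    w <- org + c(i, j, k) * sp
    d2 <- sum((w - center)^2)
    if (d2 > radius^2) next
    others <- apply(all_centers, 1, function(ctr) sum((w - ctr)^2))
    if (d2 <= min(others) + 1e-9) {
      num <- num + w * v
      den <- den + v
    }
  }
  if (den == 0) return(rep(NA_real_, 3))
  num / den
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
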
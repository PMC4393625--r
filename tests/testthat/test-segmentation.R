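# Head/tail estimation, contact segmentation and the SEEG corrections.

test_that("head estimation recovers the screw blob centroid", {
  # isolated synthetic blob: ball of bright voxels on the anisotropic grid
  d <- array(0, c(40, 40, 20))
  ctr <- c(8, 8, 8)
  for (i in 0:39) for (j in 0:39) for (k in 0:19) {
    w <- c(i * 0.4, j * 0.4, k * 0.8)
    if (sum((w - ctr)^2) <= 1.2^2) d[i + 1, j + 1, k + 1] <- 3000
  }
  vol <- voxel_volume(d, spacing = c(0.4, 0.4, 0.8))
  idx <- which(d > 1600, arr.ind = TRUE) - 1
  oracle <- unname(colMeans(sweep(idx, 2, c(0.4, 0.4, 0.8), `*`)))

  # planned entry displaced 2 mm from the blob centre
  H <- estimate_head(vol, ctr + c(2, 0, 0), 1600)
  expect_equal(H, oracle, tolerance = 1e-3)
  # entry exactly at the centroid is a fixed point
  expect_equal(estimate_head(vol, oracle, 1600), oracle, tolerance = 1e-9)
  # nothing within 10 mm
  expect_error(estimate_head(vol, c(14, 2, 2), 1600),
               class = "seegloc_electrode_not_found")
})

test_that("tail following reaches the deepest contact of a straight shaft", {
  ph <- mini_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  tr <- phantom_trajectories(ph)[[1]]
  truth <- ph$truth$electrodes$A
  H <- estimate_head(vol, tr$entry, ph$spec$threshold)
  tl <- estimate_tail(vol, H, tr$target, ph$spec$threshold, default_model(8))
  expect_lt(sqrt(sum((tl$tip - truth$contacts[1, ])^2)), 0.4)
  # axis rows: head plus one point per contact
  expect_equal(nrow(tl$axis), 9)
})

test_that("a displaced target leaves the reconstruction unchanged", {
  ph <- mini_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  tr <- phantom_trajectories(ph)[[1]]
  S <- ph$spec$threshold
  H <- estimate_head(vol, tr$entry, S)
  ref <- estimate_tail(vol, H, tr$target, S, default_model(8))
  set.seed(8)
  for (i in 1:3) {
    td <- displace_target(tr$entry, tr$target, 12)
    got <- estimate_tail(vol, H, td, S, default_model(8))
    expect_lt(sqrt(sum((got$tip - ref$tip)^2)), 1e-3)
  }
})

test_that("contact segmentation recovers every contact at the right pitch", {
  for (n in c(8L, 18L)) {
    ph <- if (n == 8L) mini_phantom() else
      make_phantom(mini_phantom_spec(seed = 21, n_contacts = 18))
    vol <- apply_threshold(ph$volume, ph$spec$threshold)
    imp <- segment_implant(vol, phantom_trajectories(ph),
                           list(A = default_model(n)),
                           seg_config(threshold = ph$spec$threshold))
    el <- imp$electrodes$A
    expect_equal(nrow(el$contacts), n)
    # mean error vs rasterization ground truth below the in-plane pitch
    err <- sqrt(rowSums((el$contacts - ph$truth$electrodes$A$contacts)^2))
    expect_lt(mean(err), 0.4)
    # monotone depth ordering: distance from the head grows tip-ward
    depth <- sqrt(rowSums(sweep(el$contacts, 2, el$head)^2))
    expect_true(all(diff(depth) < 0))
    # spacing conservation within 0.2 mm of the 3.5 mm pitch
    gaps <- sqrt(rowSums(diff(el$contacts)^2))
    expect_true(all(abs(gaps - 3.5) <= 0.2))
  }
})

test_that("curved shafts are tracked within half a voxel of the centerline", {
  ph <- curved_phantom()
  imp <- segment_phantom(ph)
  el <- imp$electrodes$C
  truth <- ph$truth$electrodes$C
  expect_equal(nrow(el$contacts), 12)
  err <- sqrt(rowSums((el$contacts - truth$contacts)^2))
  expect_lt(max(err), 0.5)
  for (i in 2:nrow(el$axis))
    expect_lt(dist_to_polyline(el$axis[i, ], truth$axis), 0.5)
  # piecewise axis: accepted bends stay within the configured limit
  if (nrow(el$axis) >= 3)
    for (i in 3:nrow(el$axis))
      expect_lt(segment_angle(el$axis[i - 2, ], el$axis[i - 1, ],
                              el$axis[i, ]), 10 + 1e-6)
})

test_that("crossing shafts are corrected by shrinking the region", {
  ph <- crossing_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  tA <- ph$truth$electrodes$A
  S <- ph$spec$threshold
  s <- tA$contacts[5, ] +
    3.5 * (tA$contacts[5, ] - tA$contacts[4, ]) /
      sqrt(sum((tA$contacts[5, ] - tA$contacts[4, ])^2))
  un <- refine_centroid(vol, find_significant_voxel(vol, s, S, 3, 5.25),
                        side = 3, S = S)
  co <- constrained_centroid(vol, s, prev1 = tA$contacts[5, ],
                             prev2 = tA$contacts[4, ], S = S)
  dev_un <- sqrt(sum((un - tA$contacts[6, ])^2))
  dev_co <- sqrt(sum((as.numeric(co) - tA$contacts[6, ])^2))
  expect_gt(dev_un, 1)
  expect_lt(dev_co, 0.5)
  # and the full implant still reconstructs
  ev <- evaluate(segment_phantom(ph), ph$truth)
  expect_equal(ev$fn, 0L)
  expect_equal(ev$fp, 0L)
})

test_that("the hemisphere rule stops searches at the fissure plane", {
  pl <- hemisphere_plane(c(0, 0, 0), c(1, 0, 0))
  H <- c(30, 0, 0)
  expect_false(hemisphere_guard(pl, H, c(5, 0, 0)))    # short of the plane
  expect_true(hemisphere_guard(pl, H, c(-2, 0, 0)))    # crossed it
  expect_false(hemisphere_guard(pl, H, c(30, 50, 0)))  # parallel, same side

  ph <- bilateral_phantom()
  imp <- segment_phantom(ph)
  expect_equal(nrow(imp$electrodes$R$contacts), 9)
  expect_equal(nrow(imp$electrodes$L$contacts), 9)
  expect_true(all(imp$electrodes$R$contacts[, 1] > 0))
  expect_true(all(imp$electrodes$L$contacts[, 1] < 0))
  # without the guard the right reconstruction overflows the midline
  imp2 <- segment_phantom(ph, guard = FALSE)
  expect_true(any(imp2$electrodes$R$contacts[, 1] < 0))
})

test_that("implant runs are deterministic and isolate per-electrode failures", {
  ph <- mini_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  trajs <- phantom_trajectories(ph)
  cfg <- seg_config(threshold = ph$spec$threshold)
  a <- segment_implant(vol, trajs, phantom_models(ph), cfg)
  b <- segment_implant(vol, trajs, phantom_models(ph), cfg)
  expect_identical(a$electrodes$A$contacts, b$electrodes$A$contacts)

  # a trajectory into empty air fails alone; the real electrode survives
  ghost <- planned_trajectory("Z", c(52, 20, 28), c(20, 20, 28))
  mix <- segment_implant(vol, c(trajs, list(ghost)), phantom_models(ph), cfg)
  expect_named(mix$failures, "Z")
  expect_equal(nrow(mix$electrodes$A$contacts), 8)

  expect_warning(empty <- segment_implant(vol, list(), config = cfg),
                 "no trajectories")
  expect_length(empty$electrodes, 0)
})
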
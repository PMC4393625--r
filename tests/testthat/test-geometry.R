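# Moments, centres of mass, points and angles.

test_that("point_at_distance walks the line through two points", {
  expect_equal(point_at_distance(c(0, 0, 0), c(0, 0, 2), 3.5), c(0, 0, 3.5))
  expect_equal(point_at_distance(c(1, 1, 1), c(4, 5, 1), 0), c(1, 1, 1))
  # 3-4-5 triangle: unit direction (3,4,0)/5
  expect_equal(point_at_distance(c(1, 1, 1), c(4, 5, 1), 5), c(4, 5, 1))
  expect_error(point_at_distance(c(1, 2, 3), c(1, 2, 3), 1), "undefined axis")
})

test_that("region moments match hand counts on uniform and single voxels", {
  vol <- voxel_volume(array(1, c(3, 3, 3)))
  expect_equal(region_moment(vol, cubic_region(c(1, 1, 1), 3), 0, 0, 0), 27)

  d <- array(0, c(5, 5, 5))
  d[3, 4, 5] <- 5                       # voxel centre (2, 3, 4), I = 5
  vol2 <- voxel_volume(d)
  expect_equal(region_moment(vol2, cubic_region(c(2, 3, 4), 1), 1, 0, 0), 10)
})

test_that("moments and centres of mass equal a brute-force triple loop", {
  set.seed(421)
  for (case in 1:25) {
    dm <- sample(4:10, 3, replace = TRUE)
    sp <- stats::runif(3, 0.3, 1.2)
    org <- stats::runif(3, -3, 3)
    aff <- diag(c(sp, 1)); aff[1:3, 4] <- org
    vol <- voxel_volume(array(stats::runif(prod(dm)), dm), affine = aff)
    center <- org + stats::runif(3, 0, (dm - 1) * sp)
    side <- stats::runif(1, 1, 4)
    for (ord in list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      expect_equal(
        region_moment(vol, cubic_region(center, side), ord[1], ord[2], ord[3]),
        brute_moment(vol, center, side, ord[1], ord[2], ord[3]),
        tolerance = 1e-12)
    }
    expect_equal(center_of_mass(vol, cubic_region(center, side)),
                 brute_com(vol, center, side), tolerance = 1e-12)
  }
})

test_that("centre of mass respects symmetry and midpoints", {
  vol <- voxel_volume(array(1, c(5, 5, 5)))
  expect_equal(center_of_mass(vol, cubic_region(c(2, 2, 2), 5)), c(2, 2, 2))

  d <- array(0, c(3, 3, 5))
  d[2, 2, 1] <- 4; d[2, 2, 3] <- 4      # centres (1,1,0) and (1,1,2)
  vol2 <- voxel_volume(d)
  expect_equal(center_of_mass(vol2, cubic_region(c(1, 1, 1), 4)), c(1, 1, 1))
})

test_that("empty and out-of-volume regions signal as specified", {
  d <- array(0, c(4, 4, 4)); d[1, 1, 1] <- 1
  vol <- voxel_volume(d)
  expect_error(center_of_mass(vol, cubic_region(c(3, 3, 3), 1)),
               class = "seegloc_empty_region")
  expect_warning(m <- region_moment(vol, cubic_region(c(50, 50, 50), 2)),
                 "outside")
  expect_equal(m, 0)
})

test_that("centre of mass is translation-equivariant on the voxel lattice", {
  set.seed(99)
  d <- array(stats::runif(6^3), c(6, 6, 6))
  vol <- voxel_volume(d, spacing = c(0.4, 0.4, 0.8))
  big <- array(0, c(10, 10, 10))
  big[3:8, 4:9, 2:7] <- d               # shift by (2, 3, 1) voxels
  shift <- c(2, 3, 1) * c(0.4, 0.4, 0.8)
  vol2 <- voxel_volume(big, spacing = c(0.4, 0.4, 0.8))
  r <- cubic_region(c(1, 1.2, 2), 2.5)
  expect_equal(center_of_mass(vol2, cubic_region(r$center + shift, r$side)),
               center_of_mass(vol, r) + shift, tolerance = 1e-12)
})

test_that("centre of mass stays inside the bounding box of region mass", {
  set.seed(5)
  for (i in 1:10) {
    d <- array(stats::runif(5^3) * (stats::runif(5^3) > 0.6), c(5, 5, 5))
    vol <- voxel_volume(d, spacing = c(0.5, 0.7, 0.9))
    center <- stats::runif(3, 0.5, 2.5)
    rv <- seegloc:::.region_voxels(vol, center, 2)
    keep <- rv$I > 0
    if (!any(keep)) next
    com <- center_of_mass(vol, cubic_region(center, 2))
    expect_true(com[1] >= min(rv$x[keep]) - 1e-12 &&
                com[1] <= max(rv$x[keep]) + 1e-12)
    expect_true(com[2] >= min(rv$y[keep]) - 1e-12 &&
                com[2] <= max(rv$y[keep]) + 1e-12)
    expect_true(com[3] >= min(rv$z[keep]) - 1e-12 &&
                com[3] <= max(rv$z[keep]) + 1e-12)
  }
})

test_that("segment angle handles collinear, perpendicular and rotations", {
  expect_equal(segment_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), 0)
  expect_equal(segment_angle(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)), 90)
  expect_error(segment_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "undefined axis")
  set.seed(17)
  a <- c(0.3, -1, 2); b <- c(1.4, 0.2, 0.5); c_ <- c(2, 2, 1)
  ref <- segment_angle(a, b, c_)
  for (i in 1:10) {
    R <- random_rotation()
    expect_equal(segment_angle(R %*% a, R %*% b, R %*% c_), ref,
                 tolerance = 1e-6)
  }
})
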
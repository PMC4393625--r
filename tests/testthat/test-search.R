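# Growing-cube significant-voxel search and centroid refinement.

test_that("significant voxels are found, enlarged to, or reported absent", {
  d <- array(0, c(41, 21, 11))
  vol <- voxel_volume(d, spacing = c(0.4, 0.4, 0.8))
  center <- c(4, 4, 4)

  # voxel ~1 mm from the centre: inside the initial 3 mm region
  d1 <- d; d1[11 + 2, 11, 6] <- 3000        # 0-based (12,10,5) -> (4.8,4,4)
  v1 <- voxel_volume(d1, spacing = c(0.4, 0.4, 0.8))
  expect_equal(find_significant_voxel(v1, center, 1600), c(4.8, 4, 4))

  # nearest significant voxel 4.8 mm along x: needs side >= 9.6
  d2 <- d; d2[11 + 12, 11, 6] <- 3000       # centre (8.8, 4, 4)
  v2 <- voxel_volume(d2, spacing = c(0.4, 0.4, 0.8))
  expect_equal(find_significant_voxel(v2, center, 1600), c(8.8, 4, 4))
  expect_null(find_significant_voxel(v2, center, 1600, l_max = 9.5))

  # empty neighbourhood out to 10 mm
  expect_null(find_significant_voxel(vol, center, 1600))
})

test_that("found voxels always exceed S and lie inside the largest cube", {
  set.seed(61)
  for (i in 1:20) {
    d <- array(stats::runif(16^3, 0, 2000), c(16, 16, 16))
    vol <- voxel_volume(d, spacing = c(0.4, 0.5, 0.8))
    center <- stats::runif(3, 1, 5)
    S <- stats::runif(1, 1200, 1999)
    p <- find_significant_voxel(vol, center, S, l_init = 1, l_max = 4)
    if (is.null(p)) {
      rv <- seegloc:::.region_voxels(vol, center, 4)
      expect_true(is.null(rv) || all(rv$I <= S))
    } else {
      expect_true(all(abs(p - center) <= 2 + 1e-9))
      v <- seegloc:::.world_to_voxel(vol, p)
      expect_gt(d[round(v[1]) + 1, round(v[2]) + 1, round(v[3]) + 1], S)
    }
  }
})

test_that("centroid refinement reaches the rasterized contact centroid", {
  ph <- mini_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  truth <- ph$truth$electrodes$A
  target <- truth$contacts[3, ]

  all_centers <- rbind(truth$ideal_centers, truth$entry)
  oracle <- oracle_contact_centroid(vol, truth$ideal_centers[3, ],
                                    all_centers, ph$spec$threshold)
  # offset starts within the contact's basin converge to the same point
  offs <- list(c(0, 0, 0), c(1, 0, 0), c(-0.7, 0.5, 0.3), c(0, -0.6, 0.7))
  for (o in offs) {
    got <- refine_centroid(vol, target + o, side = 3, S = ph$spec$threshold)
    expect_equal(got, oracle, tolerance = 1e-3)
  }
  # exact centroid start is a fixed point
  expect_equal(refine_centroid(vol, oracle, side = 3, S = ph$spec$threshold),
               oracle, tolerance = 1e-9)
})

test_that("refinement in empty space raises the empty-region condition", {
  vol <- voxel_volume(array(0, c(20, 20, 10)), spacing = c(0.4, 0.4, 0.8))
  expect_error(refine_centroid(vol, c(3, 3, 3), S = 1600),
               class = "seegloc_empty_region")
})

test_that("constrained refinement equals plain refinement off any crossing", {
  ph <- mini_phantom()
  vol <- apply_threshold(ph$volume, ph$spec$threshold)
  tc <- ph$truth$electrodes$A$contacts
  s <- tc[4, ] + c(0.3, 0.2, -0.2)
  plain <- refine_centroid(vol, find_significant_voxel(vol, s,
                                                       ph$spec$threshold),
                           side = 3, S = ph$spec$threshold)
  con <- constrained_centroid(vol, s, prev1 = tc[3, ], prev2 = tc[2, ],
                              S = ph$spec$threshold)
  expect_equal(as.numeric(con), plain, tolerance = 1e-9)
  expect_false(attr(con, "merged"))
  expect_error(constrained_centroid(vol, c(70, 22, 28), prev1 = tc[3, ],
                                    prev2 = tc[2, ], S = ph$spec$threshold),
               class = "seegloc_empty_region")
})
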
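# Phantom generator, ground truth, displacement draws and FP/FN accounting.

test_that("rasterized metal mass matches the analytic solid volumes", {
  sp <- mini_phantom_spec(seed = 3)
  sp$noise_max <- 0
  ph <- make_phantom(sp)
  voxvol <- prod(sp$spacing)
  total_mass <- sum(ph$volume$data) * voxvol
  # 8 cylinders plus one screw sphere (blur conserves mass away from edges)
  expected <- 8 * pi * 0.4^2 * 2 * sp$contact_intensity +
    4 / 3 * pi * sp$screw_radius^3 * sp$screw_intensity
  expect_equal(total_mass, expected, tolerance = 0.05)
})

test_that("above-threshold footprint of a slice-centred shaft is plausible", {
  # shaft in a single 0.8 mm slice: the analytic voxel count applies
  u <- c(-1, 0.001, 0); u <- u / sqrt(sum(u^2))
  e <- c(52, 12, 14.4)
  sp <- phantom_spec(shape = c(150, 60, 40), origin = c(2, 0, 0),
                     electrodes = list(list(label = "A", entry = e,
                                            target = e + 29.5 * u,
                                            n_contacts = 8)),
                     noise_max = 0, seed = 3)
  ph <- make_phantom(sp)
  # exclude the screw neighbourhood
  xs <- 2 + 0.4 * (seq_len(150) - 1)
  shaft <- ph$volume$data[xs < 44, , ]
  count <- sum(shaft > sp$threshold)
  analytic <- 8 * pi * 0.4^2 * 2 / prod(sp$spacing)
  expect_gt(count, 0.5 * analytic)
  expect_lt(count, 2 * analytic)
})

test_that("phantoms are bit-reproducible under a fixed seed", {
  a <- make_phantom(mini_phantom_spec(seed = 42))
  b <- make_phantom(mini_phantom_spec(seed = 42))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$electrodes$A$contacts, b$truth$electrodes$A$contacts)
  c_ <- make_phantom(mini_phantom_spec(seed = 43))
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("truth centroids equal an independent voxel-mass oracle", {
  ph <- mini_phantom()
  truth <- ph$truth$electrodes$A
  all_centers <- rbind(truth$ideal_centers, truth$entry)
  for (k in c(1, 4, 8)) {
    oracle <- oracle_contact_centroid(ph$volume, truth$ideal_centers[k, ],
                                      all_centers, ph$spec$threshold)
    expect_equal(truth$contacts[k, ], oracle, tolerance = 1e-9)
  }
})

test_that("electrodes leaving the grid are rejected", {
  sp <- mini_phantom_spec()
  sp$electrodes[[1]]$target <- c(300, 12, 14)
  expect_error(make_phantom(sp), "exits the phantom grid")
})

test_that("displaced targets sit on the perpendicular circle", {
  E <- c(0, 0, 0); T_ <- c(30, 5, -2)
  expect_equal(displace_target(E, T_, 0), T_)
  set.seed(12)
  for (r in c(1, 7.5, 15)) {
    Td <- displace_target(E, T_, r)
    expect_lt(abs(sqrt(sum((Td - T_)^2)) - r), 1e-9)
    expect_lt(abs(sum((Td - T_) * (T_ - E))), 1e-9)
  }
  expect_error(displace_target(E, E, 5), "undefined axis")
})

test_that("FP/FN accounting follows the channel-count normalization", {
  ph <- make_phantom(mini_phantom_spec(seed = 9, n_contacts = 10))
  imp <- segment_phantom(ph)
  ev <- evaluate(imp, ph$truth)
  expect_equal(ev$fn, 0L); expect_equal(ev$fp, 0L)
  expect_equal(ev$n_matched, 10L)

  # drop one predicted contact -> one FN out of 10
  drop1 <- imp
  drop1$electrodes$A$contacts <- drop1$electrodes$A$contacts[-3, ]
  ev1 <- evaluate(drop1, ph$truth)
  expect_equal(ev1$fn_rate, 0.1)
  expect_equal(ev1$fp_rate, 0)

  # add a spurious detection far from any contact -> one FP out of 10
  add1 <- imp
  add1$electrodes$A$contacts <- rbind(add1$electrodes$A$contacts,
                                      c(45, 25, 28))
  ev2 <- evaluate(add1, ph$truth)
  expect_equal(ev2$fp_rate, 0.1)
  expect_equal(ev2$fn_rate, 0)
})

test_that("the robustness experiment reports one summary row per radius", {
  ph <- mini_phantom()
  rb <- robustness_experiment(ph, radii = seq(1, 15, by = 2), n_samples = 5,
                              seed = 4)
  expect_equal(nrow(rb$summary), 8)
  expect_equal(rb$summary$radius, seq(1, 15, by = 2))
  expect_equal(nrow(rb$samples), 40)
  # seeded: repeatable
  rb2 <- robustness_experiment(ph, radii = seq(1, 15, by = 2), n_samples = 5,
                               seed = 4)
  expect_identical(rb$samples, rb2$samples)

  # zero displacement reproduces the reference exactly
  rb0 <- robustness_experiment(ph, radii = 0, n_samples = 2, seed = 4)
  expect_true(all(rb0$samples$mean_paired == 0))
})
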
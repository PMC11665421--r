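# Polar boundary profiles, protrusion detection and phase classification.

test_that("a perfect disk gives a flat polar profile", {
  seg <- segment_spheroid(make_disk_frame(80))
  prof <- polar_profile(seg, 360)
  expect_true(all(abs(prof$r - 80) < 1))
  expect_equal(prof$r_mean, 80, tolerance = 0.01)
  expect_equal(prof$r_mean, mean(prof$r))
  expect_equal(nrow(detect_protrusions(prof)), 0)
})

test_that("a rectangular 40 um bump yields the closed-form length", {
  # base 80 um, bump 40 um over 20 degrees of a 360-bin profile:
  # r_mean = 80 + 40 * 20/360; length = 120 - r_mean ~ 37.78
  r <- rep(80, 360)
  r[101:120] <- 120
  prof <- make_profile(r)
  det <- detect_protrusions(prof)
  expect_equal(nrow(det), 1)
  expect_equal(det$length, 40 * (1 - 20 / 360), tolerance = 1e-12)
  expect_equal(det$length, 37.78, tolerance = 1e-3)
  # oracle agreement
  expect_equal(det$length, max(oracle_runs(r)), tolerance = 1e-12)
})

test_that("three equal bumps give three equal protrusions", {
  r <- rep(80, 360)
  for (s in c(0, 120, 240)) r[s + (11:30)] <- 115
  det <- detect_protrusions(make_profile(r))
  expect_equal(nrow(det), 3)
  expect_lt(diff(range(det$length)) / mean(det$length), 0.05)
})

test_that("runs wrapping through theta = 0 are detected once", {
  r <- rep(80, 360)
  r[c(351:360, 1:10)] <- 110
  det <- detect_protrusions(make_profile(r))
  expect_equal(nrow(det), 1)
  expect_equal(det$length, 30 * (1 - 20 / 360), tolerance = 1e-12)
})

test_that("detection agrees with the brute-force oracle on random profiles", {
  set.seed(13)
  for (i in 1:25) {
    r <- 80 + pmax(0, rnorm(120, 0, 8))
    det <- detect_protrusions(make_profile(r),
                              classification_params(min_prominence = 0, theta_bins = 120))
    want <- oracle_runs(r)
    expect_equal(sort(det$length), sort(want), tolerance = 1e-12)
  }
})

test_that("an ellipse profile spans its semi-axes with two maxima", {
  seg <- segment_spheroid(make_ellipse_frame(100, 80))
  prof <- polar_profile(seg, 360)
  expect_equal(min(prof$r), 80, tolerance = 2)
  expect_equal(max(prof$r), 100, tolerance = 2)
  # the two long-axis maxima sit 180 degrees apart: the global maximum and
  # the maximum over the opposite half of the profile
  i1 <- which.max(prof$r)
  far <- which(pmin(abs(prof$theta - prof$theta[i1]),
                    2 * pi - abs(prof$theta - prof$theta[i1])) > pi / 2)
  i2 <- far[which.max(prof$r[far])]
  sep <- abs(prof$theta[i1] - prof$theta[i2])
  expect_equal(min(sep, 2 * pi - sep), pi, tolerance = 0.1)
  # central symmetry of the profile
  expect_equal(prof$r, prof$r[((seq_len(360) + 179) %% 360) + 1],
               tolerance = 0.05)
})

test_that("a mildly eccentric convex shape yields no long protrusions", {
  seg <- segment_spheroid(make_ellipse_frame(84, 80))
  prof <- polar_profile(seg, 360)
  det <- detect_protrusions(prof)
  expect_true(nrow(det) == 0 || all(det$length < 0.1 * prof$r_mean))
})

test_that("protrusion detection is rotation-equivariant", {
  sim <- simulate_spheroid_timelapse(spheroid_sim_params(
    r0 = 70, t_ons_true = 5, alpha_true = 0.25, duration = 18,
    n_protrusions = 2, protrusion_growth = 3, noise_sd = 0.01, seed = 12))
  fr <- sim$movie$frames[[length(sim$movie$frames)]]
  rot <- bf_frame(t(fr$pixels)[, nrow(fr$pixels):1], fr$pixel_size, fr$time)
  p0 <- polar_profile(segment_spheroid(fr), 360)
  p1 <- polar_profile(segment_spheroid(rot), 360)
  d0 <- detect_protrusions(p0)
  d1 <- detect_protrusions(p1)
  expect_equal(nrow(d0), nrow(d1))
  expect_equal(sort(d0$length), sort(d1$length), tolerance = 0.02)
  shifted <- sort((d0$peak_theta + pi / 2) %% (2 * pi))
  ang_diff <- abs(shifted - sort(d1$peak_theta))
  ang_diff <- pmin(ang_diff, 2 * pi - ang_diff)
  expect_true(all(ang_diff < 5 * pi / 180))
})

test_that("net dissociated count subtracts and floors", {
  expect_equal(net_dissociated_count(15, 2), 13L)
  expect_equal(net_dissociated_count(3, 5), 0L)
  expect_equal(net_dissociated_count(0, 0), 0L)
})

test_that("phase classification truth table incl. strict boundaries", {
  expect_equal(classify_phase(30, 2)$label, "liquid")
  expect_equal(classify_phase(10, 0)$label, "solid")
  g <- classify_phase(40, 15)
  expect_equal(g$label, "gas")
  expect_true(g$coexistence)
  # strict inequalities: boundary values fall to the lower phase
  expect_equal(classify_phase(25, 0)$label, "solid")
  expect_equal(classify_phase(0, 10)$label, "solid")
  expect_equal(classify_phase(25.001, 10)$label, "liquid")
  gg <- classify_phase(0, 11)
  expect_equal(gg$label, "gas")
  expect_false(gg$coexistence)
  # total function over a grid
  for (ml in c(0, 10, 25, 30)) for (nc in c(0, 5, 10, 11, 20)) {
    lab <- classify_phase(ml, nc)$label
    expect_true(lab %in% c("solid", "liquid", "gas"))
  }
})

test_that("phase_from_track classifies synthetic scenes end to end", {
  # liquid-like: long protrusions, no dissociated cells
  sim <- simulate_spheroid_timelapse(spheroid_sim_params(
    r0 = 70, t_ons_true = 4, alpha_true = 0.2, duration = 16,
    n_protrusions = 3, protrusion_growth = 4, noise_sd = 0.01, seed = 5))
  tr <- track_timelapse(sim$movie)
  res <- phase_from_track(tr)
  expect_equal(res$phase$label, "liquid")
  expect_gt(res$phase$mean_protrusion_length, 25)
  # solid-like: nothing happens
  sim2 <- simulate_spheroid_timelapse(spheroid_sim_params(
    r0 = 70, alpha_true = 0, duration = 6, noise_sd = 0.01, seed = 6))
  res2 <- phase_from_track(track_timelapse(sim2$movie))
  expect_equal(res2$phase$label, "solid")
})
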
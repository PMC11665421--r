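# Hydrogel characterization: bubble pore sizes, void fraction, Darcy
# permeability and the elasticity conversion.

two_fiber_slice <- function(sep = 40, nr = 101, nc = 120, noise_sd = 0.02,
                            seed = 1) {
  set.seed(seed)
  r1 <- (nr - sep) %/% 2; r2 <- r1 + sep
  img <- matrix(0, nr, nc)
  img[c(r1, r2), ] <- 1
  img + rnorm(length(img), 0, noise_sd)
}

test_that("two parallel fibers give a pore diameter equal to the separation", {
  sl <- two_fiber_slice(sep = 40)
  stack <- confocal_stack(sl, pixel_size_xy = 0.2)
  res <- bubble_pore_sizes(stack)
  # dominant pore: 40 px * 0.2 um = 8 um, within 1 px (0.2 um)
  expect_lt(abs(mean(res$pore_diameters) - 8), 0.2 + 1e-9)
  expect_equal(res$mean, mean(res$pore_diameters))
  expect_equal(res$n_maxima, length(res$pore_diameters))
  # oracle: brute-force nearest-fiber distance at the channel midline
  fiber <- sl > 0.5
  edm <- oracle_edt(fiber)
  mid <- (which(rowSums(fiber) > ncol(fiber) / 2)[1] +
            which(rowSums(fiber) > ncol(fiber) / 2)[2]) / 2
  expect_equal(unname(edm[mid, 10]), 20, tolerance = 1e-9)
})

test_that("an all-bright slice has no void phase", {
  stack <- confocal_stack(matrix(1, 64, 64), 0.2)
  expect_error(bubble_pore_sizes(stack), class = "EmptyVoidPhase")
})

test_that("pore size distribution is invariant to intensity rescaling", {
  sim <- simulate_fiber_stack(fiber_sim_params(volume_shape = c(2, 96, 96),
                                               fiber_count = 25, seed = 8))
  r1 <- bubble_pore_sizes(sim$stack)
  scaled <- confocal_stack(sim$stack$voxels * 2.5, sim$stack$pixel_size_xy,
                           sim$stack$z_step)
  r2 <- bubble_pore_sizes(scaled)
  expect_equal(r1$n_maxima, r2$n_maxima)
  expect_equal(r1$pore_diameters, r2$pore_diameters, tolerance = 1e-8)
})

test_that("mean pore size decreases with fiber density (10/10 paired seeds)", {
  wins <- vapply(1:10, function(s) {
    lo <- simulate_fiber_stack(fiber_sim_params(volume_shape = c(1, 96, 96),
                                                fiber_count = 12, seed = s))
    hi <- simulate_fiber_stack(fiber_sim_params(volume_shape = c(1, 96, 96),
                                                fiber_count = 36, seed = s))
    mean_lo <- bubble_pore_sizes(lo$stack)$mean
    mean_hi <- bubble_pore_sizes(hi$stack)$mean
    mean_hi < mean_lo
  }, logical(1))
  expect_true(all(wins))
})

test_that("void fraction reports the black/white ratio and fraction", {
  # exactly half black
  proj <- matrix(0, 64, 64); proj[, 33:64] <- 1
  vf <- void_fraction(proj)
  expect_equal(vf$ratio_black_white, 1)
  expect_equal(vf$fraction_void, 0.5)
  # uniform projection: AllVoid error carrying fraction 1
  err <- tryCatch(void_fraction(matrix(0, 64, 64)), AllVoid = function(e) e)
  expect_s3_class(err, "AllVoid")
  expect_equal(err$data$fraction_void, 1)
  # generator ground truth: coverage c -> ratio ~ (1-c)/c
  sim <- simulate_fiber_stack(fiber_sim_params(volume_shape = c(3, 96, 96),
                                               fiber_count = 30,
                                               intensity_noise_sd = 0.03,
                                               seed = 2))
  vf2 <- void_fraction(sim$stack)
  want <- (1 - sim$coverage) / sim$coverage
  expect_lt(abs(vf2$ratio_black_white - want) / want, 0.15)
})

test_that("dye-front tracking recovers the generator velocity", {
  # 10 px/frame at 0.62 um px and 30 s interval -> 2.067e-7 m/s
  v_true <- 10 * 0.62e-6 / 30
  sim <- simulate_dye_front(front_sim_params(velocity_true = v_true,
                                             n_frames = 8, shape = c(240, 48),
                                             noise_sd = 0.01, seed = 3))
  tr <- track_dye_front(sim$series)
  expect_lt(abs(tr$velocity - v_true) / v_true, 0.02)
  expect_true(all(diff(tr$front_positions) > 0))
  # static front, noiseless -> exactly zero velocity
  sim0 <- simulate_dye_front(front_sim_params(velocity_true = 0, noise_sd = 0,
                                              n_frames = 5, seed = 1))
  expect_equal(track_dye_front(sim0$series)$velocity, 0)
  # saturated frames -> NoFront
  sat <- front_series(replicate(3, matrix(1, 100, 20), simplify = FALSE),
                      0.62, 30, 2000, 1e-3)
  expect_error(track_dye_front(sat), class = "NoFront")
})

test_that("sub-pixel per-frame displacement is recovered within 10%", {
  v_true <- 0.4 * 0.62e-6 / 30  # 0.4 px per frame
  sim <- simulate_dye_front(front_sim_params(velocity_true = v_true,
                                             n_frames = 13, noise_sd = 0.005,
                                             shape = c(160, 64), seed = 4))
  tr <- track_dye_front(sim$series)
  expect_lt(abs(tr$velocity - v_true) / v_true, 0.10)
})

test_that("Darcy inversion round-trips and scales linearly", {
  set.seed(17)
  for (i in 1:100) {
    K <- 10^runif(1, -18, -12)
    dP <- 10^runif(1, 2, 5); L <- 10^runif(1, -4, -2); mu <- 10^runif(1, -3.5, -2)
    v <- dP * K / (L * mu)                 # forward Darcy
    expect_equal(permeability_from_velocity(v, dP, L, mu), K,
                 tolerance = 1e-12)
  }
  expect_equal(permeability_from_velocity(0, 2000, 1e-3, 1e-3), 0)
  K1 <- permeability_from_velocity(1e-7, 1000, 1e-3, 1e-3)
  expect_equal(permeability_from_velocity(1e-7, 2000, 1e-3, 1e-3), K1 / 2)
  expect_error(permeability_from_velocity(1e-7, -5, 1e-3, 1e-3),
               class = "InvalidPhysical")
})

test_that("pore size from permeability is sqrt(K) with unit attributes", {
  p <- pore_size_from_permeability(2.36e-16)
  expect_equal(as.numeric(p), 1.536e-8, tolerance = 1e-3)
  expect_equal(round(attr(p, "per_1e8_m"), 2), 1.54)
  p2 <- pore_size_from_permeability(1.29e-16)
  expect_equal(round(attr(p2, "per_1e8_m"), 2), 1.14)
  expect_equal(as.numeric(pore_size_from_permeability(0)), 0)
  # monotone in K
  ks <- sort(10^runif(20, -18, -12))
  expect_true(all(diff(vapply(ks, function(k)
    as.numeric(pore_size_from_permeability(k)), numeric(1))) > 0))
  expect_error(pore_size_from_permeability(-1), class = "NegativePermeability")
})

test_that("end-to-end permeability recovers the generating K within 5%", {
  K_true <- 2.36e-16
  v <- K_true * 2000 / (1e-3 * 1e-3)
  sim <- simulate_dye_front(front_sim_params(velocity_true = v, n_frames = 10,
                                             shape = c(260, 48), seed = 5))
  res <- darcy_permeability(sim$series)
  expect_lt(abs(res$K - K_true) / K_true, 0.05)
  expect_equal(res$pore_size, sqrt(res$K), tolerance = 1e-12)
})

test_that("Young's modulus conversion", {
  expect_equal(youngs_modulus(200, 0.5), 600)
  expect_equal(youngs_modulus(123, 0), 246)
  expect_equal(youngs_modulus(0, 0.5), 0)
  expect_error(youngs_modulus(100, 0.7), class = "InvalidPoisson")
})

test_that("TV denoising reduces noise while keeping edges", {
  set.seed(2)
  clean <- matrix(0, 64, 64); clean[, 33:64] <- 1
  noisy <- clean + rnorm(64 * 64, 0, 0.2)
  den <- tv_denoise(noisy, weight = 0.2)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2) / 2)
  # edge preserved: the two plateaus stay well separated
  expect_gt(mean(den[, 40:60]) - mean(den[, 5:25]), 0.8)
})
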
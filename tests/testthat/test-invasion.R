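# Trajectory normalization, onset, saturation and power-law fitting.

test_that("normalization divides by the initial radius", {
  tr <- normalize_radius(c(0, 1, 2), c(100, 110, 130))
  expect_equal(tr$r_norm, c(1, 1.1, 1.3))
  expect_identical(tr$r_norm[1], 1)
  expect_equal(normalize_radius(0:3, rep(80, 4))$r_norm, rep(1, 4))
  expect_error(normalize_radius(c(0, 1), c(0, 10)), class = "ZeroInitialRadius")
})

test_that("onset time interpolates the threshold crossing", {
  tr <- normalize_radius(c(0, 1, 2), c(1, 1.05, 1.15) * 100)
  expect_equal(onset_time(tr), 1.5)
  # never reached -> undefined
  flat <- normalize_radius(0:5, 100 * c(1, 1.02, 1.04, 1.06, 1.07, 1.08))
  expect_true(is.na(onset_time(flat)))
  # threshold met exactly at a sample ("reaches" is inclusive)
  exact <- normalize_radius(c(0, 1), c(100, 110))
  expect_equal(onset_time(exact), 1)
})

test_that("onset is monotone in the threshold", {
  set.seed(21)
  for (i in 1:20) {
    t <- 0:24
    r <- 100 * cummax(1 + cumsum(abs(rnorm(25, 0.01, 0.02))) - abs(rnorm(1, 0.01)))
    r[1] <- 100
    tr <- normalize_radius(t, r)
    ons <- vapply(c(1.05, 1.1, 1.2, 1.3),
                  function(th) onset_time(tr, metrics_params(onset_threshold = th)),
                  numeric(1))
    ons <- ons[!is.na(ons)]
    expect_true(all(diff(ons) >= 0))
  }
})

test_that("saturation time finds plateaus and survives short upticks", {
  # rising then exactly constant after t = 20
  t <- 0:30
  r <- c(seq(100, 140, length.out = 21), rep(140, 10))
  tr <- normalize_radius(t, r)
  expect_equal(saturation_time(tr), 20)
  # strict power law over an onset-to-20h window never saturates at 1%/hr
  t2 <- 1:20
  tr2 <- normalize_radius(t2, 100 * (t2 / t2[1])^0.3)
  expect_equal(saturation_time(tr2), 20)
  rate <- diff(tr2$r_norm) / (head(tr2$r_norm, -1))
  expect_true(all(rate >= 0.01))  # analytic check: alpha/t >= 0.3/20 > 1%/hr
  # plateau interrupted by one noisy 1-hr uptick shorter than the 3-hr run
  r3 <- c(seq(100, 130, length.out = 11), rep(130, 20))
  r3[16] <- 135; r3[17] <- 130
  tr3 <- normalize_radius(0:30, r3)
  expect_equal(saturation_time(tr3), 10)
  expect_equal(saturation_time(tr3),
               oracle_saturation(tr3$times, tr3$r_norm, 0.01, 3))
})

test_that("saturation rule agrees with the run-length oracle on random walks", {
  set.seed(31)
  for (i in 1:15) {
    t <- 0:40
    r <- 100 * (1 + cumsum(c(0, abs(rnorm(40, 0.01, 0.015)) *
                               (runif(40) < 0.7))))
    tr <- normalize_radius(t, r)
    expect_equal(saturation_time(tr),
                 oracle_saturation(t, tr$r_norm, 0.01, 3))
  }
})

test_that("power-law fit recovers noiseless exponents to 1e-10", {
  t <- 5:20
  for (a in c(0, 0.1, 0.15, 0.29, 0.44, 0.7, 1)) {
    tr <- normalize_radius(t, 100 * (t / 5)^a)
    fit <- fit_expansion_rate(tr, c(5, 20))
    expect_lt(abs(fit$alpha - a), 1e-10)
    expect_true(fit$alpha_interval[1] <= fit$alpha &&
                  fit$alpha <= fit$alpha_interval[2])
  }
  # A549-style window
  t2 <- 15:72
  fit2 <- fit_expansion_rate(normalize_radius(t2, 90 * (t2 / 15)^0.15), c(15, 72))
  expect_lt(abs(fit2$alpha - 0.15), 1e-10)
})

test_that("degenerate and invalid fits are handled", {
  t <- 1:10
  flat <- fit_expansion_rate(normalize_radius(t, rep(100, 10)), c(1, 10))
  expect_equal(flat$alpha, 0)
  expect_equal(diff(flat$alpha_interval), 0)
  tr <- normalize_radius(t, 100 * t)
  expect_error(fit_expansion_rate(tr, c(9.5, 10.5)), class = "InsufficientData")
  bad <- normalize_radius(t, c(100, 90, -5, rep(80, 7)))
  expect_error(fit_expansion_rate(bad, c(1, 10)), class = "NonPositiveValues")
})

test_that("metrics are scale- and time-unit-consistent", {
  t <- 0:24
  r <- 100 * ifelse(t <= 6, 1, (t / 6)^0.25)
  tr1 <- normalize_radius(t, r)
  tr2 <- normalize_radius(t, 7.3 * r)
  expect_equal(tr1$r_norm, tr2$r_norm)
  expect_equal(onset_time(tr1), onset_time(tr2))
  f1 <- fit_expansion_rate(tr1, c(7, 24))
  f2 <- fit_expansion_rate(tr2, c(7, 24))
  expect_equal(f1$alpha, f2$alpha)
  # minutes instead of hours: same slope, different intercept
  trm <- normalize_radius(t * 60, r)
  fm <- fit_expansion_rate(trm, c(7 * 60, 24 * 60))
  expect_equal(fm$alpha, f1$alpha, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fm$intercept, f1$intercept)))
})

test_that("mean fitted exponent over 100 noisy replicates is unbiased", {
  set.seed(1)
  t <- 5:20
  alphas <- replicate(100, {
    sim <- simulate_radius_trajectory(t, 5, 0.29, noise_sd = 0.02)
    fit_expansion_rate(normalize_radius(t, sim$r_eff), c(5, 20))$alpha
  })
  se <- sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.29), se)
})

test_that("replicate aggregation averages pointwise", {
  t <- 0:10
  a <- normalize_radius(t, 100 * pmax(1, (t / 3))^0.2)
  b <- normalize_radius(t, 100 * pmax(1, (t / 3))^0.4)
  agg <- aggregate_replicates(list(a, a))
  expect_equal(agg$mean, a$r_norm)
  expect_equal(agg$sd, rep(0, length(t)))
  agg2 <- aggregate_replicates(list(a, b))
  expect_true(all(agg2$mean >= pmin(a$r_norm, b$r_norm) - 1e-12 &
                    agg2$mean <= pmax(a$r_norm, b$r_norm) + 1e-12))
  expect_error(aggregate_replicates(list()), class = "EmptyInput")
  # 10 noisy replicates of t^0.29: mean-curve fit within 0.02
  set.seed(9)
  t3 <- 5:20
  reps <- lapply(1:10, function(i) {
    sim <- simulate_radius_trajectory(t3, 5, 0.29, noise_sd = 0.02)
    normalize_radius(t3, sim$r_eff)
  })
  m <- aggregate_replicates(reps)
  fit <- fit_expansion_rate(m$as_trajectory, c(5, 20))
  expect_lt(abs(fit$alpha - 0.29), 0.02)
})

test_that("summarize_invasion combines onset, saturation and fit", {
  t <- 0:24
  law <- unjamr:::spheroid_radius_law(t, 8, 0.3)
  tr <- normalize_radius(t, 100 * law)
  s <- summarize_invasion(tr)
  expect_equal(s$t_ons, 8, tolerance = 0.05)
  expect_equal(s$alpha, 0.3, tolerance = 0.02)
  expect_equal(s$r_norm_final, law[25])
  flat <- normalize_radius(t, rep(100, 25))
  sf <- summarize_invasion(flat)
  expect_true(is.na(sf$t_ons) && is.na(sf$alpha))
})
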
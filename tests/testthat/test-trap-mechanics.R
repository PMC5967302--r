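# Trap mechanics: thermal energy arithmetic, equipartition calibration on
# exact Gaussian samples and simulated tracks, force-extension construction
# and first-linear-region fitting.

test_that("thermal energy is k_B T in pN um", {
  expect_identical(thermal_energy(0), 0)
  expect_equal(thermal_energy(298.15), 4.1164e-3, tolerance = 1e-4)
  expect_equal(thermal_energy(296.15), 4.0888e-3, tolerance = 1e-4)
  expect_error(thermal_energy(-1), "temperature")
})

test_that("equipartition calibration inverts a known variance", {
  # exact Gaussian sample rescaled to sample variance 1.0e-2 um^2
  x <- withr::with_seed(8, rnorm(20000))
  x <- (x - mean(x)) / sd(x) * 0.1
  trk <- data.frame(t_s = seq_along(x) * 1e-3, x_um = x)

  cal_d <- stiffness_equipartition(trk, 298.15, "direct_variance")
  expect_equal(cal_d$k_x, 4.1164e-3 / 1e-2, tolerance = 1e-4)

  cal_g <- stiffness_equipartition(trk, 298.15, "gaussian_fit")
  expect_equal(cal_g$k_x, cal_d$k_x, tolerance = 0.02)
  expect_identical(cal_g$method, "gaussian_fit")

  # constant track is degenerate
  flat <- data.frame(t_s = 1:200, x_um = rep(1.5, 200))
  expect_error(stiffness_equipartition(flat), "degenerate")
  expect_error(stiffness_equipartition(trk[1:50, ]), "at least 100")
})

test_that("calibration recovers the generating stiffness of a bead track", {
  trk <- simulate_trapped_bead(stiffness = 7.29, temperature = 296.15,
                               n_frames = 10000, seed = 17)
  cal <- stiffness_equipartition(trk, 296.15)
  expect_lt(abs(cal$k_x - 7.29), 0.5)

  # a two-axis track calibrates each axis independently
  trk$y_um <- simulate_trapped_bead(stiffness = 5, temperature = 296.15,
                                    n_frames = 10000, seed = 18)$x_um
  cal2 <- stiffness_equipartition(trk, 296.15, "direct_variance")
  expect_lt(abs(cal2$k_y - 5), 0.4)
})

test_that("calibration is unbiased across seeds for both variance methods", {
  ks <- t(vapply(1:50, function(i) {
    trk <- simulate_trapped_bead(stiffness = 7.29, temperature = 296.15,
                                 n_frames = 4000, seed = 300 + i)
    c(g = suppressWarnings(stiffness_equipartition(trk, 296.15)$k_x),
      d = stiffness_equipartition(trk, 296.15, "direct_variance")$k_x)
  }, numeric(2)))
  # MC error of the mean over 50 runs is ~0.05 pN/um; allow 3x
  expect_equal(mean(ks[, "d"]), 7.29, tolerance = 0.025)
  expect_equal(mean(ks[, "g"]), 7.29, tolerance = 0.025)
})

test_that("stiffness scales inversely with squared position units", {
  trk <- simulate_trapped_bead(stiffness = 7.29, n_frames = 5000, seed = 4)
  k1 <- stiffness_equipartition(trk, 296.15, "direct_variance")$k_x
  trk2 <- transform(trk, x_um = x_um * 3)
  k2 <- stiffness_equipartition(trk2, 296.15, "direct_variance")$k_x
  expect_equal(k2, k1 / 9, tolerance = 1e-10)
})

test_that("force is linear in displacement", {
  expect_identical(force_from_displacement(7.29, 0), 0)
  expect_equal(force_from_displacement(7.29, 0.5), 3.645)
  expect_equal(force_from_displacement(7.29, -0.5), -3.645)
  expect_equal(force_from_displacement(2, c(1, 2)), c(2, 4))
  expect_error(force_from_displacement(0, 1), "k")
})

test_that("force-extension curve applies baseline zeroing and F = k dx", {
  tp <- simulate_tether_pull(trap_stiffness = 10, tether_stiffness = 10,
                             noise_sd = 0, dwell = 0.5)
  cv <- force_extension_curve(tp$bead, tp$stage, list(k_x = 10))
  fit <- linear_region_fit(cv)
  expect_equal(fit$slope, 5, tolerance = 5e-7)        # 6 significant digits
  expect_equal(fit$bounds[2], nrow(cv))

  # tether-extension axis recovers the tether stiffness itself
  cvt <- force_extension_curve(tp$bead, tp$stage, list(k_x = 10),
                               axis = "tether")
  expect_equal(linear_region_fit(cvt)$slope, 10, tolerance = 5e-7)

  # zero bead deviation -> zero force
  tp0 <- simulate_tether_pull(tether_stiffness = 0, noise_sd = 0)
  cv0 <- force_extension_curve(tp0$bead, tp0$stage, list(k_x = 10))
  expect_true(all(cv0$force_pN == 0))

  # constant 0.1-um deviation from the pre-pull position at k = 5 -> 0.5 pN
  tt <- seq(0, 5, 0.01)
  bead <- data.frame(t_s = tt, x_um = ifelse(tt > 1, 0.1, 0))
  stage <- data.frame(t_s = tt, stage_um = pmax(tt - 1, 0))
  cvc <- force_extension_curve(bead, stage, list(k_x = 5))
  expect_true(all(abs(cvc$force_pN[cvc$t_s >= 1] - 0.5) < 1e-12))

  # disjoint time supports are an error
  expect_error(force_extension_curve(
    data.frame(t_s = 0:10, x_um = 0),
    data.frame(t_s = 20:30, stage_um = 0), list(k_x = 1)), "overlap")
})

test_that("slope is equivariant under a shift of the time origin", {
  tp <- simulate_tether_pull(trap_stiffness = 8, tether_stiffness = 4,
                             noise_sd = 0)
  cv <- force_extension_curve(tp$bead, tp$stage, list(k_x = 8))
  bead2 <- transform(tp$bead, t_s = t_s + 3)
  stage2 <- transform(tp$stage, t_s = t_s + 3)
  cv2 <- force_extension_curve(bead2, stage2, list(k_x = 8))
  expect_equal(linear_region_fit(cv2)$slope, linear_region_fit(cv)$slope)
})

test_that("linear-region fit finds the first linear part", {
  # exact line: full curve, slope recovered to rounding
  x <- seq(0, 2, by = 0.05)
  cv <- data.frame(extension_um = x, force_pN = 2 * x)
  fit <- linear_region_fit(cv)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_identical(fit$bounds, c(1L, length(x)))

  # noiseless changepoint (slope 3 then 0): strict R2 localizes the end of
  # the linear region to within one sample
  xc <- seq(0, 2, by = 0.05)
  yc <- ifelse(xc < 1, 3 * xc, 3)
  cvc <- data.frame(extension_um = xc, force_pN = yc)
  fitc <- linear_region_fit(cvc, r2_min = 0.999)
  cp <- max(which(xc <= 1))
  expect_lte(abs(fitc$bounds[2] - cp), 1)
  expect_equal(fitc$slope, 3, tolerance = 0.02)

  # noisy line: slope within its own 95% confidence interval of the truth
  xn <- seq(0, 2, by = 0.01)
  yn <- 2 * xn + withr::with_seed(31, rnorm(length(xn), 0, 0.02))
  fitn <- linear_region_fit(data.frame(extension_um = xn, force_pN = yn),
                            r2_min = 0.98)
  ols <- summary(lm(yn[1:fitn$n] ~ xn[1:fitn$n]))
  se <- ols$coefficients[2, 2]
  expect_lt(abs(fitn$slope - 2), qt(0.975, fitn$n - 2) * se)

  # no window can satisfy the criterion on pure noise
  pure <- withr::with_seed(5, data.frame(extension_um = runif(40),
                                         force_pN = rnorm(40)))
  expect_error(linear_region_fit(pure, r2_min = 0.999), "no linear region")
  expect_error(linear_region_fit(cv[1:5, ]), "at least")
})
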
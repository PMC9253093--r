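# kinematic extraction: velocities, acceleration fits, rocking, yaw

test_that("velocity series honors the 3-4-5 and 5-12-13 worked examples", {
  mid <- rbind(c(0, 0, 0), c(0.03, 0.04, 0))
  tr <- synthetic_path_trial(mid, c(0, 1), offset = c(0, 0, 0))
  expect_equal(velocity_series(tr, "3d")$v, 0.05)
  expect_equal(velocity_series(tr, "2d")$v, 0.05)

  mid2 <- rbind(c(0, 0, 0), c(0.03, 0.04, 0.12))
  tr2 <- synthetic_path_trial(mid2, c(0, 1), offset = c(0, 0, 0))
  expect_equal(velocity_series(tr2, "3d")$v, 0.13)
  expect_equal(velocity_series(tr2, "2d")$v, 0.05)

  # purely vertical motion has zero horizontal speed
  mid3 <- cbind(0, 0, seq(0, 1, length.out = 10))
  tr3 <- synthetic_path_trial(mid3, seq(0, 1, length.out = 10),
                              offset = c(0, 0, 0))
  expect_equal(velocity_series(tr3, "2d")$v, rep(0, 9))
  expect_true(all(velocity_series(tr3, "3d")$v > 0))
})

test_that("v2d never exceeds v3d, equality iff no vertical displacement", {
  b <- morphotype_params()$center
  tr <- simulate_linear_trial(b, jet_profile(), noise_sd = 0.001, seed = 7,
                              duration = 5)
  v2 <- velocity_series(tr, "2d")$v
  v3 <- velocity_series(tr, "3d")$v
  expect_true(all(v2 <= v3 + 1e-12))
})

test_that("non-monotone timestamps are rejected", {
  tr <- synthetic_path_trial(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                             c(0, 2, 1))
  expect_error(velocity_series(tr), "increasing")
})

test_that("acceleration fit recovers exact synthetic slopes", {
  # v = 0.15 t exactly: quadratic midpoint path x = 0.075 t^2
  t <- seq(0, 2, by = 1 / 23.975)
  mid <- cbind(0.075 * t^2, 0, 0)
  tr <- synthetic_path_trial(mid, t, motor_on = as.integer(t <= 1))
  f <- fit_acceleration(tr, windows = cbind(0, 1))
  # frame differencing evaluates v at interval midpoints; the linear trend
  # is recovered exactly
  expect_equal(f$slope, 0.15, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$slope_cm_s2, 15, tolerance = 1e-6)

  # constant speed: slope 0
  mid2 <- cbind(0.2 * t, 0, 0)
  tr2 <- synthetic_path_trial(mid2, t, motor_on = as.integer(t <= 1))
  f2 <- fit_acceleration(tr2)
  expect_equal(f2$slope, 0, tolerance = 1e-9)

  expect_error(fit_acceleration(tr, windows = cbind(0, 0.05)), "fewer than 3")
})

test_that("low-drag morphs out-accelerate high-drag morphs at equal thrust", {
  p <- morphotype_params()
  acc <- function(b) fit_acceleration(
    simulate_linear_trial(b, jet_profile(), noise_sd = 0, seed = 1,
                          duration = 2.5))$slope_cm_s2
  a_compressed <- acc(p$oxycone)
  a_inflated <- acc(p$sphaerocone)
  expect_gt(a_compressed, a_inflated)
})

test_that("on noise-free trials the fitted acceleration approaches T/(m+ma) at t->0", {
  b <- body_params(mass = 1000, added_mass_coefficient = 0.25,
                   drag_coefficient = 0.3, frontal_area = 100,
                   rocking_amplitude_deg = 0, buoyancy_imbalance = 0)
  jet <- jet_profile(pulse_duration = 0.25, refill_duration = 1,
                     thrust_mean = 0.3, tau = 0)
  tr <- simulate_linear_trial(b, jet, noise_sd = 0, seed = 1, duration = 0.6,
                              lateral_drift = 0)
  f <- fit_acceleration(tr, windows = cbind(0, 0.25))
  expect_lt(abs(f$slope - 0.3 / 1.25) / (0.3 / 1.25), 0.02)
})

test_that("rocking angle zero cases and envelope recovery", {
  # posterior point directly above anterior, theta_tp = 0 -> 0 deg
  t <- seq(0, 1, length.out = 5)
  tr <- synthetic_path_trial(cbind(t, 0, 0), t, offset = c(0, 0, -0.05))
  # offset negative: p2 above p1
  expect_equal(rocking_angle(tr, theta_tp = 0)$theta_dv, rep(0, 5))

  # posterior horizontal from anterior, theta_tp = 90 -> 0 deg
  tr2 <- synthetic_path_trial(cbind(t, 0, 0), t, offset = c(-0.05, 0, 0))
  expect_equal(rocking_angle(tr2, theta_tp = 90)$theta_dv, rep(0, 5))

  tr3 <- synthetic_path_trial(cbind(t, 0, 0), t, offset = c(0, 0, 0))
  expect_error(rocking_angle(tr3), "coincident")

  # simulator rocking amplitude is recovered from the series
  b <- morphotype_params()$center
  b$rocking_amplitude_deg <- 5
  tr4 <- simulate_linear_trial(b, jet_profile(), noise_sd = 0, seed = 3,
                               duration = 6)
  theta_tp <- 45 # static angle of the default tracking offsets
  dv <- rocking_angle(tr4, theta_tp)$theta_dv
  expect_lt(abs(max(abs(dv)) - 5) / 5, 0.05)
  # period recovery: dominant spacing between sign changes ~ half period
  zc <- diff(which(diff(sign(dv)) != 0)) / 23.975
  expect_lt(abs(median(zc) - 0.5 / b$rocking_frequency_hz),
            0.1 / b$rocking_frequency_hz)
})

test_that("yaw series: quarter turn, statics, reversal antisymmetry, 3.25 revolutions", {
  tr <- synthetic_rotation_trial(90, n_frames = 120)
  y <- yaw_series(tr)
  expect_equal(y$net_angle[length(y$net_angle)], 90, tolerance = 1e-6)

  # static body
  t <- seq(0, 2, length.out = 20)
  trs <- synthetic_path_trial(cbind(0, 0, 0)[rep(1, 20), ], t,
                              offset = c(0.05, 0, 0))
  ys <- yaw_series(trs)
  expect_equal(ys$net_angle, rep(0, 20))
  expect_equal(ys$omega, rep(0, 19))

  # reversing frame order negates the net angle exactly
  tr_rev <- tr[rev(seq_len(nrow(tr))), ]
  tr_rev$t_s <- tr$t_s
  class(tr_rev) <- class(tr)
  y_rev <- yaw_series(tr_rev)
  expect_equal(y_rev$net_angle[length(y_rev$net_angle)],
               -y$net_angle[length(y$net_angle)], tolerance = 1e-9)

  # 3.25 revolutions unwrap to 1170 degrees without +-180 jumps
  tr2 <- synthetic_rotation_trial(1170, n_frames = 400, noise_sd = 1e-4,
                                  seed = 2)
  y2 <- yaw_series(tr2)
  expect_equal(y2$net_angle[length(y2$net_angle)], 1170, tolerance = 2)
  expect_equal(y2$revolutions, 3.25, tolerance = 0.01)
  expect_lt(max(abs(diff(y2$net_angle))), 90) # continuity

  # vertically stacked points have no bearing
  trv <- synthetic_path_trial(cbind(0, 0, 0)[rep(1, 5), ],
                              seq(0, 1, length.out = 5),
                              offset = c(0, 0, 0.05))
  expect_error(yaw_series(trv), "bearing undefined")
})

test_that("trial summary: constant-velocity peak, zero-motion coasting", {
  t <- seq(0, 4, by = 1 / 23.975)
  tr <- synthetic_path_trial(cbind(0.2 * t, 0, 0), t,
                             motor_on = as.integer(t <= 1))
  s <- trial_summary(tr)
  expect_equal(s$peak_velocity, 0.2, tolerance = 1e-9)

  tr0 <- synthetic_path_trial(cbind(0, 0, 0)[rep(1, length(t)), ], t,
                              motor_on = as.integer(t <= 1))
  s0 <- trial_summary(tr0)
  expect_equal(s0$coasting_distance, 0)

  expect_error(trial_group_summary(list()), "empty")
})

test_that("compressed parameter sets coast farther than inflated at equal thrust", {
  p <- morphotype_params()
  coast <- function(b, seed) trial_summary(
    simulate_linear_trial(b, jet_profile(), noise_sd = 0.001, seed = seed,
                          duration = 10))$coasting_distance
  d_compressed <- vapply(1:5, function(s) coast(p$oxycone, s), numeric(1))
  d_inflated <- vapply(1:5, function(s) coast(p$sphaerocone, s), numeric(1))
  expect_true(all(d_compressed > d_inflated))
})
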
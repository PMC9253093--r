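# theoretical conch generation, partition conservation and morphospace

test_that("whorl sections have the requested proportions", {
  spec <- conch_spec(inflation = 1.0, section_exponent = 2,
                     umbilical_exposure = 0.5, n_section = 64)
  sec <- generate_whorl_section(spec, 180)
  h <- diff(range(sec[, 1]))
  b <- diff(range(sec[, 2]))
  expect_equal(b / h, 1.0, tolerance = 1e-6)

  spec2 <- conch_spec(inflation = 2.0, umbilical_exposure = 0.5)
  sec2 <- generate_whorl_section(spec2, 180)
  expect_equal(diff(range(sec2[, 2])) / diff(range(sec2[, 1])), 2.0,
               tolerance = 1e-6)

  # exponent-2 superellipse of inflation 1 is a circle
  fr_r <- sec[, 1] - mean(range(sec[, 1]))
  expect_equal(sqrt(fr_r^2 + sec[, 2]^2), rep(h / 2, nrow(sec)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("imported section polylines normalize area-preservingly and reject self-intersection", {
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  ellipse <- cbind(3 + 2 * cos(t), 1.5 * sin(t))
  spec <- conch_spec(whorl_section = ellipse)
  norm <- spec$whorl_section
  expect_equal(diff(range(norm[, 1])), 1, tolerance = 1e-9)
  # area scales with the square of the height normalization
  a0 <- abs(sum(ellipse[, 1] * c(ellipse[-1, 2], ellipse[1, 2]) -
                  c(ellipse[-1, 1], ellipse[1, 1]) * ellipse[, 2]) / 2)
  a1 <- abs(sum(norm[, 1] * c(norm[-1, 2], norm[1, 2]) -
                  c(norm[-1, 1], norm[1, 1]) * norm[, 2]) / 2)
  expect_equal(a1 * 4^2, a0, tolerance = 1e-6)

  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(conch_spec(whorl_section = bowtie), "self-intersecting")
})

test_that("venter radius follows the logarithmic spiral", {
  spec <- conch_spec(expansion_per_rev = 2, total_revolutions = 3)
  expect_equal(venter_radius(spec, 720) / venter_radius(spec, 360), 2,
               tolerance = 1e-9)
  expect_equal(venter_radius(spec, 1080), 8, tolerance = 1e-9)
  # piecewise ontogeny integrates exactly
  spec2 <- conch_spec(expansion_per_rev = 2, ontogeny_segments = list(
    list(start_deg = 360, end_deg = 720, expansion_per_rev = 3)))
  expect_equal(venter_radius(spec2, 1080), 2 * 3 * 2, tolerance = 1e-9)
})

test_that("every generated component is watertight and the partition conserves volume", {
  for (nm in c("serpenticone", "oxycone", "sphaerocone", "center")) {
    m <- cached_demo_model(nm)
    expect_true(validate_watertight(m$water_displaced)$passes, label = nm)
    expect_true(validate_watertight(m$shell)$passes, label = nm)
    expect_true(validate_watertight(m$soft_body)$passes, label = nm)
    expect_true(validate_watertight(m$cameral_volumes)$passes, label = nm)
    v_wd <- signed_volume(m$water_displaced)
    v_parts <- signed_volume(m$shell) + signed_volume(m$cameral_volumes) +
      signed_volume(m$soft_body)
    expect_lt(abs(v_wd - v_parts) / v_wd, 0.01)
  }
})

test_that("shell volume agrees with an independent ray-casting oracle", {
  m <- cached_demo_model("center")
  v_direct <- signed_volume(m$water_displaced)
  v_ray <- raycast_volume(m$water_displaced, n = 128L)
  expect_lt(abs(v_direct - v_ray) / v_direct, 0.015)
  # the hollow wall solid (outer surface + inverted inner surface) encloses
  # outer-minus-inner; parity ray casting sees the same wall intervals
  v_shell <- signed_volume(m$shell_wall)
  v_shell_ray <- raycast_volume(m$shell_wall, n = 128L)
  expect_lt(abs(v_shell - v_shell_ray) / v_shell, 0.05)
})

test_that("chamber count follows the septal spacing", {
  # 230 degrees of phragmocone at 23-degree spacing -> 10 chambers
  spec <- conch_spec(total_revolutions = 2,
                     body_chamber_angle = 720 - 230,
                     step_deg = 4, n_section = 24)
  sep <- insert_septa(generate_conch(spec))
  expect_length(sep$chambers, 10L)
  expect_length(sep$septum_angles_deg, 10L)
})

test_that("septal volume scales with the thickness ratio", {
  base <- demo_conch_specs(step_deg = 4, n_section = 24)$center
  thick <- base
  thick$septal_thickness_ratio <- 2 * base$septal_thickness_ratio
  v1 <- sum(vapply(insert_septa(generate_conch(base))$septa,
                   signed_volume, numeric(1)))
  v2 <- sum(vapply(insert_septa(generate_conch(thick))$septa,
                   signed_volume, numeric(1)))
  expect_equal(v2 / v1, 2, tolerance = 0.02)
})

test_that("soft body volume is zero at angle 0 and strictly increasing", {
  spec <- demo_conch_specs(step_deg = 4, n_section = 24)$center
  conch <- generate_conch(spec)
  expect_null(partition_soft_body(conch, 0))
  angles <- c(60, 120, 180, 240)
  vols <- vapply(angles, function(a)
    signed_volume(partition_soft_body(conch, a)), numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_error(partition_soft_body(conch, 2000), "exceeds")
})

test_that("soft body and cameral volumes partition the tube interior disjointly", {
  m <- cached_demo_model("center")
  # the final septum separates them along the spiral; their volumes must
  # fill the shell interior without overlap
  v_in <- signed_volume(m$water_displaced) - signed_volume(m$shell)
  expect_equal(signed_volume(m$cameral_volumes) + signed_volume(m$soft_body),
               v_in, tolerance = 1e-3)
})

test_that("conch regeneration is bit-identical", {
  spec <- demo_conch_specs(step_deg = 6, n_section = 20)$center
  a <- generate_conch(spec)
  b <- generate_conch(spec)
  expect_identical(a$outer$vertices, b$outer$vertices)
  expect_identical(a$inner$faces, b$inner$faces)
})

test_that("mesh diameter matches the analytic spiral prediction", {
  for (nm in c("center", "oxycone")) {
    m <- cached_demo_model(nm)
    spec <- m$spec
    r_pred <- venter_radius(spec, spec$total_revolutions * 360)
    r_mesh <- max(sqrt(m$water_displaced$vertices[, 1]^2 +
                         m$water_displaced$vertices[, 3]^2))
    expect_lt(abs(r_mesh - r_pred) / r_pred, 0.01)
  }
})

test_that("overly involute specs error with guidance", {
  spec <- conch_spec(expansion_per_rev = 1.05, umbilical_exposure = 0,
                     total_revolutions = 2, step_deg = 6, n_section = 16)
  expect_error(generate_conch(spec), "umbilical_exposure")
})

test_that("westermann coordinates: center point, scale invariance, corners", {
  # equal normalized components land on the morphospace center
  ms <- conch_measurements(demo_conch_specs()$center)
  w <- westermann_coordinates(ms$D, ms$U, ms$ah, ms$ab, W = ms$W)
  expect_equal(as.numeric(w), rep(1 / 3, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # dimensionless: scaling all measurements leaves the point unchanged
  w2 <- westermann_coordinates(ms$D * 7, ms$U * 7, ms$ah * 7, ms$ab * 7,
                               W = ms$W)
  expect_equal(as.numeric(w2), as.numeric(w), tolerance = 1e-12)

  # each demo morphotype lands in its corner third
  specs <- demo_conch_specs()
  pt <- function(nm) {
    m <- conch_measurements(specs[[nm]])
    westermann_coordinates(m$D, m$U, m$ah, m$ab, W = m$W)
  }
  expect_gt(pt("serpenticone")[["u_exp"]], 1 / 2)
  expect_gt(pt("oxycone")[["w_exp"]], 1 / 2)
  expect_gt(pt("sphaerocone")[["th_infl"]], 1 / 2)

  # grid search: the inflation component is maximized toward full breadth
  # and closed umbilicus (the sphere-like conch)
  grid <- expand.grid(U = c(0, 0.2, 0.4), ab = c(0.3, 0.6, 1.0),
                      ah = c(0.3, 0.45))
  th <- mapply(function(U, ab, ah)
    westermann_coordinates(1, U, ah, ab)[["th_infl"]],
    grid$U, grid$ab, grid$ah)
  sphere_like <- which(grid$U == 0 & grid$ab == 1.0 & grid$ah == 0.45)
  expect_equal(th[sphere_like], max(th), tolerance = 1e-12)
  expect_true(all(grid$U[th == max(th)] == 0))

  expect_error(westermann_coordinates(1, 1.2, 0.4, 0.4), "smaller")
  expect_error(westermann_coordinates(-1, 0.2, 0.4, 0.4), "positive")
})
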
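#' Time-averaged jet thrust from a peak measurement
#'
#' Jet pulses deliver a time-averaged thrust that is a fixed fraction of the
#' peak: for a 1 kg extant Nautilus the peak is about 2 N and the
#' time-average about 23% of it, 0.46 N.
#'
#' @param peak_N peak thrust, N.
#' @param fraction time-averaged fraction of the peak.
#' @return Time-averaged thrust in N.
#' @export
time_averaged_thrust <- function(peak_N = 2, fraction = 0.23) {
  if (peak_N < 0 || fraction < 0) stop("thrust quantities must be >= 0")
  peak_N * fraction
}

#' Jet pulse profile
#'
#' Trapezoidal thrust with exponential rise and decay (time constant `tau`):
#' the motor quickly reaches full thrust once initiated and quickly declines
#' after shutting off. The plateau is scaled so the time-average over each
#' pulse window equals `thrust_mean`.
#'
#' @param pulse_duration pulse length, s.
#' @param refill_duration coasting ("refill") period between pulses, s.
#' @param n_pulses number of pulses (0 for pure coasting).
#' @param thrust_mean time-averaged thrust per pulse, N.
#' @param tau rise/decay time constant, s; `0` gives an ideal square pulse.
#' @return A `jet_profile`.
#' @export
jet_profile <- function(pulse_duration = 1, refill_duration = 1,
                        n_pulses = 1, thrust_mean = 0.3, tau = 0.05) {
  if (pulse_duration <= 0 || refill_duration <= 0)
    stop("durations must be > 0")
  if (thrust_mean < 0) stop("thrust must be >= 0")
  P <- pulse_duration
  plateau <- if (n_pulses > 0 && thrust_mean > 0) {
    if (tau <= 0) thrust_mean else
      thrust_mean * P / (P - tau * (1 - exp(-P / tau)))
  } else 0
  structure(list(pulse_duration = P, refill_duration = refill_duration,
                 n_pulses = n_pulses, thrust_mean = thrust_mean,
                 tau = tau, plateau = plateau),
            class = "jet_profile")
}

#' Thrust at time t
#'
#' @param jet a [jet_profile()].
#' @param t time(s) since the first motor-on frame, s.
#' @return Thrust in N (vectorized over `t`).
#' @export
thrust_at <- function(jet, t) {
  if (jet$n_pulses == 0 || jet$plateau == 0) return(rep(0, length(t)))
  out <- numeric(length(t))
  period <- jet$pulse_duration + jet$refill_duration
  for (k in seq_len(jet$n_pulses)) {
    t0 <- (k - 1) * period
    tl <- t - t0
    on <- tl >= 0 & tl < jet$pulse_duration
    if (jet$tau <= 0) { # ideal square pulse
      out[on] <- out[on] + jet$plateau
      next
    }
    out[on] <- out[on] + jet$plateau * (1 - exp(-tl[on] / jet$tau))
    after <- tl >= jet$pulse_duration
    lvl <- jet$plateau * (1 - exp(-jet$pulse_duration / jet$tau))
    out[after] <- out[after] +
      lvl * exp(-(tl[after] - jet$pulse_duration) / jet$tau)
  }
  out
}

motor_on_at <- function(jet, t) {
  if (jet$n_pulses == 0) return(rep(0L, length(t)))
  period <- jet$pulse_duration + jet$refill_duration
  on <- rep(FALSE, length(t))
  for (k in seq_len(jet$n_pulses)) {
    t0 <- (k - 1) * period
    on <- on | (t >= t0 & t < t0 + jet$pulse_duration)
  }
  as.integer(on)
}

#' Rigid-body parameters of a jet-propelled robot
#'
#' Masses in g, lengths in cm, positions of tracking points in m. The added
#' mass (water accelerated with the body) is `added_mass_coefficient` times
#' the body mass (the bodies are neutrally buoyant, so body mass equals
#' displaced mass). Rotational drag is quadratic in the yaw rate with
#' coefficient `rotational_drag` (g cm^2 per (rad/s)^2).
#'
#' @param mass body mass, g (near neutral buoyancy this equals the displaced
#'   mass; the four robots are about 982 g).
#' @param added_mass_coefficient fraction of displaced mass entrained.
#' @param frontal_area motion-normal projected area, cm^2.
#' @param drag_coefficient dimensionless quadratic drag coefficient.
#' @param fluid_density g/cm^3.
#' @param izz vertical-axis moment of inertia, g cm^2.
#' @param rotational_drag quadratic yaw-drag coefficient, g cm^2.
#' @param lever_arm hyponome lever arm about the vertical axis, cm.
#' @param tracking_offsets list of two length-3 offsets (m) of the anterior
#'   and posterior tracking points from the body center, in the body frame
#'   (x forward, z up).
#' @param buoyancy_imbalance signed residual weight, g (positive sinks).
#' @param rocking_amplitude_deg,rocking_frequency_hz pitch rocking imposed
#'   on the tracking points.
#' @param name label.
#' @return A `body_params`.
#' @export
body_params <- function(mass = 982, added_mass_coefficient = 0.5,
                        frontal_area = pi * 7.5^2, drag_coefficient = 0.61,
                        fluid_density = 1.025, izz = 22000,
                        rotational_drag = 1000, lever_arm = 7.5,
                        tracking_offsets = list(c(0.03, 0, 0.12),
                                                c(-0.03, 0, 0.18)),
                        buoyancy_imbalance = 0.5,
                        rocking_amplitude_deg = 4,
                        rocking_frequency_hz = 0.8,
                        name = "body") {
  p <- list(mass = mass, added_mass_coefficient = added_mass_coefficient,
            frontal_area = frontal_area,
            drag_coefficient = drag_coefficient,
            fluid_density = fluid_density, izz = izz,
            rotational_drag = rotational_drag, lever_arm = lever_arm,
            tracking_offsets = tracking_offsets,
            buoyancy_imbalance = buoyancy_imbalance,
            rocking_amplitude_deg = rocking_amplitude_deg,
            rocking_frequency_hz = rocking_frequency_hz,
            name = name)
  if (with(p, mass <= 0 || frontal_area <= 0 || izz <= 0))
    stop("mass, frontal_area and izz must be > 0")
  if (p$drag_coefficient < 0 || p$rotational_drag < 0)
    stop("drag coefficients must be >= 0")
  if (!all(vapply(p[c("mass", "added_mass_coefficient", "frontal_area",
                      "drag_coefficient", "fluid_density", "izz",
                      "rotational_drag", "lever_arm")],
                  function(x) is.finite(x), logical(1))))
    stop("non-finite body parameter")
  class(p) <- "body_params"
  p
}

#' Morphotype parameter sets for the trial simulator
#'
#' Forward-model parameters emulating the four robot morphotypes at the
#' ~1 kg, 15 cm scale: compressed morphotypes (serpenticone, oxycone) have
#' low translational drag coefficients and small frontal areas but broad
#' flanks that resist yaw (large rotational drag); the inflated sphaerocone
#' has the highest translational drag and spins almost freely; the
#' morphospace center is intermediate. Translational drag coefficients are
#' the reported robot values (~0.5, ~0.14, ~0.61, ~0.5); rotational
#' parameters are the package's own calibration of the quadratic yaw-drag
#' stand-in (see the methods vignette).
#'
#' @return Named list of [body_params()].
#' @export
morphotype_params <- function() {
  sphere_A <- pi * 7.5^2
  list(
    serpenticone = body_params(drag_coefficient = 0.5,
                               frontal_area = 0.35 * sphere_A,
                               added_mass_coefficient = 0.2,
                               izz = 40000, rotational_drag = 3.5e5,
                               lever_arm = 9, name = "serpenticone"),
    oxycone = body_params(drag_coefficient = 0.14,
                          frontal_area = 0.3 * sphere_A,
                          added_mass_coefficient = 0.2,
                          izz = 45000, rotational_drag = 3e5,
                          lever_arm = 9.5, name = "oxycone"),
    sphaerocone = body_params(drag_coefficient = 0.61,
                              frontal_area = sphere_A,
                              added_mass_coefficient = 0.5,
                              izz = 22000, rotational_drag = 1000,
                              lever_arm = 7.5, name = "sphaerocone"),
    center = body_params(drag_coefficient = 0.5,
                         frontal_area = 0.62 * sphere_A,
                         added_mass_coefficient = 0.35,
                         izz = 30000, rotational_drag = 2e4,
                         lever_arm = 8, name = "center"))
}

# RK4 over a fixed grid; f(t, state) -> d state/dt
rk4_integrate <- function(f, state0, t_end, dt) {
  n <- ceiling(t_end / dt - 1e-9)
  states <- matrix(0, n + 1L, length(state0))
  states[1L, ] <- state0
  tt <- numeric(n + 1L)
  s <- state0
  t <- 0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- f(t, s)
    k2 <- f(t + h / 2, s + h / 2 * k1)
    k3 <- f(t + h / 2, s + h / 2 * k2)
    k4 <- f(t + h, s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    states[i + 1L, ] <- s
    tt[i + 1L] <- t
  }
  list(t = tt, states = states)
}

tracked_trial <- function(t, p1, p2, motor_on, fps, kind,
                          ground_truth = NULL) {
  df <- data.frame(frame = seq_along(t) - 1L, t_s = t,
                   p1x = p1[, 1], p1y = p1[, 2], p1z = p1[, 3],
                   p2x = p2[, 1], p2y = p2[, 2], p2z = p2[, 3],
                   motor_on = motor_on)
  attr(df, "fps") <- fps
  attr(df, "kind") <- kind
  attr(df, "ground_truth") <- ground_truth
  class(df) <- c("tracked_trial", "data.frame")
  df
}

#' Simulate a linear jetting/coasting trial
#'
#' Integrates `(m + m_added) dv/dt = T(t) - 0.5 rho Cd A v^2` along the jet
#' axis with an explicit RK4 at a 1 ms internal step, then samples two
#' rigid-body tracking points at the video frame rate, superimposing pitch
#' rocking, buoyancy-driven vertical drift, lateral drift and Gaussian
#' position noise. Deterministic given the seed.
#'
#' @param body a [body_params()].
#' @param jet a [jet_profile()]; `n_pulses = 0` gives pure coasting.
#' @param noise_sd Gaussian position noise per coordinate, m.
#' @param seed RNG seed.
#' @param duration trial length, s.
#' @param v0 initial speed, m/s.
#' @param fps video frame rate (frames/s).
#' @param dt internal integrator step, s.
#' @param lateral_drift ambient lateral drift speed, m/s (signed direction
#'   drawn from the seed).
#' @return A `tracked_trial` data.frame (`frame`, `t_s`, `p1x..p2z` in m,
#'   `motor_on`), with the ground truth attached as an attribute.
#' @export
simulate_linear_trial <- function(body, jet = jet_profile(),
                                  noise_sd = 0.002, seed = 1,
                                  duration = 12, v0 = 0, fps = 23.975,
                                  dt = 1e-3, lateral_drift = 0.004) {
  m_eff_kg <- body$mass * (1 + body$added_mass_coefficient) / 1000
  k_drag <- 0.5 * (body$fluid_density * 1000) * body$drag_coefficient *
    (body$frontal_area * 1e-4) # N per (m/s)^2
  f <- function(t, s) c(s[2], (thrust_at(jet, t) - k_drag * s[2]^2) /
                          m_eff_kg)
  sol <- rk4_integrate(f, c(0, v0), duration, dt)
  tf <- seq(0, duration, by = 1 / fps)
  xf <- stats::approx(sol$t, sol$states[, 1], xout = tf)$y
  vf <- stats::approx(sol$t, sol$states[, 2], xout = tf)$y
  set.seed(seed)
  lat <- sample(c(-1, 1), 1) * lateral_drift
  # residual weight sinks the body at its quadratic-drag terminal speed
  w_dyn <- abs(body$buoyancy_imbalance) * 980.665
  w_term <- if (w_dyn > 0)
    -sign(body$buoyancy_imbalance) *
      sqrt(2 * w_dyn / (body$fluid_density * body$drag_coefficient *
                          body$frontal_area)) / 100 else 0
  phase <- stats::runif(1, 0, 2 * pi)
  pitch <- body$rocking_amplitude_deg * pi / 180 *
    sin(2 * pi * body$rocking_frequency_hz * tf + phase)
  ctr <- cbind(xf, lat * tf, w_term * tf)
  o1 <- body$tracking_offsets[[1]]
  o2 <- body$tracking_offsets[[2]]
  rot_pitch <- function(o, ph) # rotation about the lateral (y) axis
    cbind(o[1] * cos(ph) + o[3] * sin(ph), rep(o[2], length(ph)),
          -o[1] * sin(ph) + o[3] * cos(ph))
  p1 <- ctr + rot_pitch(o1, pitch)
  p2 <- ctr + rot_pitch(o2, pitch)
  gt <- list(body = body, jet = jet, seed = seed, v = vf, x = xf,
             center = ctr, noise_sd = noise_sd)
  if (noise_sd > 0) {
    p1 <- p1 + matrix(stats::rnorm(length(p1), 0, noise_sd), ncol = 3)
    p2 <- p2 + matrix(stats::rnorm(length(p2), 0, noise_sd), ncol = 3)
  }
  tracked_trial(tf, p1, p2, motor_on_at(jet, tf), fps, "linear", gt)
}

#' Simulate a yaw maneuverability trial
#'
#' With a 90-degree elbow on the hyponome the jet torque spins the body
#' about the vertical axis: `Izz domega/dt = T(t) L - c_rot omega |omega|`.
#' Tracking points rotate rigidly about the axis; rotation is
#' counter-clockwise viewed from above (positive angles).
#'
#' @inheritParams simulate_linear_trial
#' @param keep_states also return the dense internal states (for
#'   convergence/closed-form checks) as attribute `states`.
#' @return A `tracked_trial` with top-down rigid rotation.
#' @export
simulate_yaw_trial <- function(body, jet = jet_profile(),
                               noise_sd = 0.002, seed = 1,
                               duration = 12, fps = 23.975, dt = 1e-3,
                               keep_states = FALSE) {
  torque_at <- function(t) thrust_at(jet, t) * 1e5 * body$lever_arm # dyn cm
  f <- function(t, s) c(s[2], (torque_at(t) -
                                 body$rotational_drag * s[2] * abs(s[2])) /
                          body$izz)
  sol <- rk4_integrate(f, c(0, 0), duration, dt)
  tf <- seq(0, duration, by = 1 / fps)
  psi <- stats::approx(sol$t, sol$states[, 1], xout = tf)$y
  omega <- stats::approx(sol$t, sol$states[, 2], xout = tf)$y
  set.seed(seed)
  o1 <- body$tracking_offsets[[1]]
  o2 <- body$tracking_offsets[[2]]
  rot_z <- function(o, ps)
    cbind(o[1] * cos(ps) - o[2] * sin(ps),
          o[1] * sin(ps) + o[2] * cos(ps), rep(o[3], length(ps)))
  p1 <- rot_z(o1, psi)
  p2 <- rot_z(o2, psi)
  gt <- list(body = body, jet = jet, seed = seed, psi = psi, omega = omega,
             noise_sd = noise_sd)
  if (noise_sd > 0) {
    p1 <- p1 + matrix(stats::rnorm(length(p1), 0, noise_sd), ncol = 3)
    p2 <- p2 + matrix(stats::rnorm(length(p2), 0, noise_sd), ncol = 3)
  }
  tr <- tracked_trial(tf, p1, p2, motor_on_at(jet, tf), fps, "yaw", gt)
  if (keep_states) attr(tr, "states") <- sol
  tr
}

#' Trial CSV input/output
#'
#' Trials are stored as plain CSV with columns `frame`, `t_s`, `p1x..p2z`
#' (meters) and `motor_on` (0/1).
#'
#' @param trial a `tracked_trial`.
#' @param path file path.
#' @return `read_trial()` returns a `tracked_trial`; `write_trial()` the
#'   path, invisibly.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial)[, c(
    "frame", "t_s", "p1x", "p1y", "p1z", "p2x", "p2y", "p2z", "motor_on")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "t_s", "p1x", "p1y", "p1z", "p2x", "p2y", "p2z",
            "motor_on")
  if (!all(need %in% names(df))) stop("not a trial CSV: missing columns")
  dtv <- diff(df$t_s)
  if (any(dtv <= 0)) stop("timestamps must be strictly increasing")
  attr(df, "fps") <- 1 / stats::median(dtv)
  class(df) <- c("tracked_trial", "data.frame")
  df
}

#' Generate a fixture suite of simulated trials and reference inputs
#'
#' Emits, under `dir`: linear and yaw trial CSVs for each morphotype
#' parameter set (9 linear and 15 yaw per set by default, the trial counts
#' of the pool experiments), analytic reference meshes, the demonstration
#' conch specs and mass budget as JSON, ground-truth JSON per trial, and a
#' manifest with per-file MD5 digests. Regeneration with the same seed is
#' bit-identical.
#'
#' @param dir output directory (created).
#' @param seed master seed; per-trial seeds derive from it.
#' @param n_linear,n_yaw trials per morphotype parameter set.
#' @param morphotypes subset of names from [morphotype_params()].
#' @param duration trial length, s.
#' @return The manifest, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_linear = 9, n_yaw = 15,
                               morphotypes = names(morphotype_params()),
                               duration = 12) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- morphotype_params()[morphotypes]
  files <- character(0)
  emit <- function(rel) {
    files <<- c(files, rel)
    file.path(dir, rel)
  }
  trial_seed <- function(i) (seed * 1000L + i) %% .Machine$integer.max
  i <- 0L
  counts <- list()
  for (nm in names(params)) {
    for (k in seq_len(n_linear)) {
      i <- i + 1L
      tr <- simulate_linear_trial(params[[nm]], jet_profile(),
                                  seed = trial_seed(i),
                                  duration = duration)
      write_trial(tr, emit(sprintf("%s_linear_%02d.csv", nm, k)))
    }
    for (k in seq_len(n_yaw)) {
      i <- i + 1L
      tr <- simulate_yaw_trial(params[[nm]], jet_profile(),
                               seed = trial_seed(i), duration = duration)
      write_trial(tr, emit(sprintf("%s_yaw_%02d.csv", nm, k)))
    }
    counts[[nm]] <- list(linear = n_linear, yaw = n_yaw)
    jsonlite::write_json(
      params[[nm]][setdiff(names(params[[nm]]), "tracking_offsets")],
      emit(sprintf("%s_params.json", nm)), auto_unbox = TRUE, digits = NA)
  }
  write_mesh(mesh_cube(10), emit("reference_cube.obj"))
  write_mesh(mesh_icosphere(7.5, 3), emit("reference_sphere.obj"))
  specs <- demo_conch_specs()
  jsonlite::write_json(
    lapply(specs, function(s) s[setdiff(names(s), "whorl_section")]),
    emit("demo_conch_specs.json"), auto_unbox = TRUE, digits = NA)
  bud <- demo_mass_budget()
  jsonlite::write_json(
    list(displaced_mass = bud$displaced_mass, target_M = bud$target_M,
         components = lapply(bud$components, unclass)),
    emit("demo_mass_budget.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed, counts = counts, duration = duration,
                   files = as.list(stats::setNames(
                     as.character(tools::md5sum(file.path(dir, files))),
                     files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
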
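#' Coasting velocity under pure quadratic drag
#'
#' Closed-form solution of `(m + m_a) dv/dt = -0.5 rho Cd A v^2`:
#' `v(t) = v0 / (1 + k v0 t)` with `k = rho Cd A / (2 (m + m_a))`.
#'
#' @param v0 speed at motor-off (m/s).
#' @param k decay rate (1/m).
#' @param t time since motor-off (s), vectorized.
#' @return Speed in m/s.
#' @export
coasting_velocity_model <- function(v0, k, t) {
  if (v0 <= 0) stop("v0 must be > 0")
  if (k < 0) stop("k must be >= 0")
  v0 / (1 + k * v0 * t)
}

#' Fit a drag coefficient to the coasting phase of a trial
#'
#' Nonlinear least squares of the quadratic-drag coasting model against the
#' horizontal speed series over the coasting window (motor-off to rest or
#' track end). The drag coefficient is recovered from the fitted decay rate
#' as `Cd = 2 k m_eff / (rho A)`. Frames after the body has yawed away from
#' its course by more than `max_bearing_change` are refused, since rotation
#' away from the movement direction corrupts the late deceleration record.
#'
#' @param trial a `tracked_trial` of a single-pulse (or coasting) run.
#' @param frontal_area reference area, cm^2 (motion-normal projected area of
#'   the displaced-water body; see [frontal_area()]).
#' @param effective_mass body mass plus added mass, g.
#' @param fluid_density g/cm^3.
#' @param max_bearing_change bearing change (deg) beyond which frames are
#'   dropped.
#' @param min_frames minimum coasting frames required.
#' @return A `drag_fit`: `Cd`, `k` (1/m), `v0` (m/s), `r_squared`, `window`
#'   (frame indices used), `convention` notes, and the inputs echoed.
#' @export
fit_drag_coefficient <- function(trial, frontal_area, effective_mass,
                                 fluid_density = 1.025,
                                 max_bearing_change = 60,
                                 min_frames = 10L) {
  vs <- velocity_series(trial, "2d")
  mw <- motor_windows(trial)
  t_off <- if (is.null(mw)) trial$t_s[1] else max(mw[, 2])
  sel <- vs$t_s > t_off
  # refuse frames after the course has rotated away (yaw during coasting)
  mid <- cbind((trial$p1x + trial$p2x) / 2, (trial$p1y + trial$p2y) / 2)
  hdg <- atan2(diff(mid[, 2]), diff(mid[, 1]))
  if (any(sel)) {
    first <- which(sel)[1]
    dh <- abs((hdg - hdg[first] + pi) %% (2 * pi) - pi) * 180 / pi
    bad <- sel & dh > max_bearing_change
    if (any(bad)) sel[seq(which(bad)[1], length(sel))] <- FALSE
  }
  if (sum(sel) < min_frames)
    stop(sprintf("coasting window too short: %d frame(s) < %d",
                 sum(sel), min_frames))
  dat <- data.frame(t = vs$t_s[sel] - vs$t_s[which(sel)[1]], v = vs$v[sel])
  v0_start <- max(dat$v[1], 1e-4)
  k_start <- {
    # crude slope-based start: dv/dt ~ -k v^2
    dv <- (dat$v[1] - dat$v[min(nrow(dat), 10)]) /
      (dat$t[min(nrow(dat), 10)] - dat$t[1] + 1e-12)
    max(dv / v0_start^2, 1e-3)
  }
  fit <- minpack.lm::nlsLM(v ~ v0 / (1 + k * v0 * t), data = dat,
                           start = list(v0 = v0_start, k = k_start),
                           lower = c(1e-6, -10),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  k <- unname(co["k"])
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((dat$v - mean(dat$v))^2)
  # k [1/m] = rho Cd A / (2 m_eff) in SI: rho*1000 kg/m^3, A*1e-4 m^2, m/1000 kg
  Cd <- 2 * k * (effective_mass / 1000) /
    ((fluid_density * 1000) * (frontal_area * 1e-4))
  out <- list(Cd = Cd, k = k, v0 = unname(co["v0"]), r_squared = r2,
              window = which(sel), n = sum(sel),
              frontal_area = frontal_area, effective_mass = effective_mass,
              fluid_density = fluid_density,
              non_physical = k < 0,
              convention = paste(
                "reference area = motion-normal projected area;",
                "effective mass = body + constant added mass;",
                "least squares on v (not log v)"))
  class(out) <- "drag_fit"
  out
}

#' @export
print.drag_fit <- function(x, ...) {
  cat(sprintf(
    "drag fit: Cd = %.4g (k = %.4g 1/m, v0 = %.4g m/s, R^2 = %.3f, n = %d)%s\n",
    x$Cd, x$k, x$v0, x$r_squared, x$n,
    if (x$non_physical) "  [non-physical: negative k]" else ""))
  invisible(x)
}

#' Projected (silhouette) frontal area of a mesh
#'
#' Area of the silhouette of a watertight mesh projected along a direction.
#' Method `"raster"` rasterizes the projected triangles onto a grid of
#' `resolution^2` cells (general). Method `"convex"` uses the exact
#' half-sum identity `A = 0.5 * sum |n_f . d| A_f`, valid for convex bodies
#' only.
#'
#' @param mesh a closed [tri_mesh()].
#' @param direction length-3 viewing direction (need not be unit).
#' @param resolution raster grid size per axis.
#' @param method `"raster"` or `"convex"`.
#' @return Area in cm^2.
#' @export
frontal_area <- function(mesh, direction = c(1, 0, 0), resolution = 1024L,
                         method = c("raster", "convex")) {
  method <- match.arg(method)
  n <- sqrt(sum(direction^2))
  if (n < 1e-15) stop("zero-length direction")
  d <- direction / n
  fc <- face_corners(mesh)
  if (method == "convex") {
    nrm <- cross3(fc$b - fc$a, fc$c - fc$a) / 2 # area-weighted normals
    return(0.5 * sum(abs(nrm %*% d)))
  }
  # orthonormal basis of the projection plane
  o <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- o - sum(o * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  pr <- function(p) cbind(p %*% e1, p %*% e2)
  a2 <- pr(fc$a); b2 <- pr(fc$b); c2 <- pr(fc$c)
  lim <- range(c(a2[, 1], b2[, 1], c2[, 1], a2[, 2], b2[, 2], c2[, 2]))
  pad <- diff(lim) * 1e-3 + 1e-12
  lo <- lim[1] - pad
  px <- (diff(lim) + 2 * pad) / resolution
  centers <- lo + (seq_len(resolution) - 0.5) * px
  covered <- matrix(FALSE, resolution, resolution)
  sgn <- function(p1, p2, x, y)
    (p2[1] - p1[1]) * (y - p1[2]) - (p2[2] - p1[2]) * (x - p1[1])
  for (i in seq_len(nrow(a2))) {
    tri <- rbind(a2[i, ], b2[i, ], c2[i, ])
    ix <- which(centers >= min(tri[, 1]) - px & centers <= max(tri[, 1]) + px)
    iy <- which(centers >= min(tri[, 2]) - px & centers <= max(tri[, 2]) + px)
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(x = centers[ix], y = centers[iy])
    s1 <- sgn(tri[1, ], tri[2, ], g$x, g$y)
    s2 <- sgn(tri[2, ], tri[3, ], g$x, g$y)
    s3 <- sgn(tri[3, ], tri[1, ], g$x, g$y)
    inside <- (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
    if (any(inside)) {
      idx <- cbind(rep(ix, times = length(iy)),
                   rep(iy, each = length(ix)))[inside, , drop = FALSE]
      covered[idx] <- TRUE
    }
  }
  sum(covered) * px^2
}
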
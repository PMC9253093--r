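#' Theoretical planispiral conch specifications
#'
#' A `conch_spec` holds the parameters of a theoretical planispiral conch
#' built on a logarithmic spiral: the whorl section shape (a superellipse by
#' default, or an imported polyline normalized to unit whorl height), the
#' whorl-height expansion factor per revolution `W`, the umbilical exposure
#' (dorsal-margin radius as a fraction of the venter radius), the section
#' inflation (breadth/height), shell and septal thickness ratios, and the
#' septal spacing. Piecewise ontogenetic changes are given as
#' `ontogeny_segments`, a list of `list(start_deg, end_deg, ...)` overrides.
#'
#' Coordinates: the coiling axis is y, the coiling plane is x-z (z vertical),
#' and the spiral angle increases toward the aperture.
#'
#' @param expansion_per_rev whorl-height expansion factor W per 360 degrees
#'   (> 1).
#' @param umbilical_exposure dorsal margin radius / venter radius, in `[0, 1)`.
#'   Values below `1/W` wrap the new whorl over earlier whorls (involute
#'   conchs); the overlapping part of each section is conformed to the outer
#'   boundary of the previous whorl, which is the shared wall of real shells.
#' @param inflation whorl-section breadth / height.
#' @param total_revolutions number of spiral revolutions.
#' @param body_chamber_angle degrees of spiral occupied by the soft body,
#'   measured back from the aperture.
#' @param shell_thickness_ratio wall thickness / inner whorl height
#'   (default 0.031).
#' @param septal_thickness_ratio septum thickness / inner whorl height
#'   (default 0.021).
#' @param septal_spacing_deg angular spacing of septa (default 23).
#' @param step_deg spiral sampling step; must divide 360.
#' @param n_section points per whorl section (even).
#' @param section_exponent superellipse exponent of the default section.
#' @param whorl_section `"superellipse"` or a k x 2 closed polyline (will be
#'   normalized to unit height; must be simple).
#' @param ontogeny_segments list of piecewise overrides (see above).
#' @param initial_radius venter radius at spiral angle 0, cm.
#' @param name label.
#' @return An object of class `conch_spec`.
#' @export
conch_spec <- function(expansion_per_rev = 2,
                       umbilical_exposure = 0.3,
                       inflation = 1,
                       total_revolutions = 3,
                       body_chamber_angle = 250,
                       shell_thickness_ratio = 0.031,
                       septal_thickness_ratio = 0.021,
                       septal_spacing_deg = 23,
                       step_deg = 2,
                       n_section = 40,
                       section_exponent = 2.5,
                       whorl_section = "superellipse",
                       ontogeny_segments = list(),
                       initial_radius = 1,
                       name = "conch") {
  if (expansion_per_rev <= 1) stop("expansion_per_rev must be > 1")
  if (umbilical_exposure < 0 || umbilical_exposure >= 1)
    stop("umbilical_exposure must be in [0, 1)")
  if (shell_thickness_ratio <= 0 || shell_thickness_ratio >= 0.2)
    stop("shell_thickness_ratio must be in (0, 0.2)")
  if (septal_thickness_ratio <= 0 || septal_thickness_ratio >= 0.2)
    stop("septal_thickness_ratio must be in (0, 0.2)")
  if (abs(360 / step_deg - round(360 / step_deg)) > 1e-9)
    stop("step_deg must divide 360")
  if (is.matrix(whorl_section))
    whorl_section <- normalize_section(whorl_section)
  spec <- list(expansion_per_rev = expansion_per_rev,
               umbilical_exposure = umbilical_exposure,
               inflation = inflation,
               total_revolutions = total_revolutions,
               body_chamber_angle = body_chamber_angle,
               shell_thickness_ratio = shell_thickness_ratio,
               septal_thickness_ratio = septal_thickness_ratio,
               septal_spacing_deg = septal_spacing_deg,
               step_deg = step_deg,
               n_section = as.integer(n_section),
               section_exponent = section_exponent,
               whorl_section = whorl_section,
               ontogeny_segments = ontogeny_segments,
               initial_radius = initial_radius,
               name = name)
  class(spec) <- "conch_spec"
  spec
}

#' @export
print.conch_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "conch_spec '%s': W=%.3g, umbilical exposure=%.3g, inflation=%.3g,\n",
    "  %.3g revolutions, body chamber %.4g deg, septa every %g deg\n"),
    x$name, x$expansion_per_rev, x$umbilical_exposure, x$inflation,
    x$total_revolutions, x$body_chamber_angle, x$septal_spacing_deg))
  invisible(x)
}

# normalize an imported section polyline: centered, unit height (radial
# extent); errors on self-intersection
normalize_section <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L || ncol(poly) != 2L)
    stop("whorl_section polyline must be a k x 2 matrix, k >= 3")
  if (polygon_self_intersects(poly))
    stop("imported whorl section polyline is self-intersecting")
  h <- diff(range(poly[, 1]))
  ctr <- c(mean(range(poly[, 1])), mean(range(poly[, 2])))
  out <- sweep(poly, 2, ctr) / h
  if (polygon_area(out) < 0) out <- out[rev(seq_len(nrow(out))), ]
  out
}

polygon_area <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # skip shared-endpoint neighbours
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(o, a, b)
    (a[, 1] - o[, 1]) * (b[, 2] - o[, 2]) - (a[, 2] - o[, 2]) * (b[, 1] - o[, 1])
  p1m <- matrix(p1, nrow(q1), 2, byrow = TRUE)
  p2m <- matrix(p2, nrow(q1), 2, byrow = TRUE)
  d1 <- d(q1, q2, p1m); d2 <- d(q1, q2, p2m)
  d3 <- d(p1m, p2m, q1); d4 <- d(p1m, p2m, q2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# ---- ontogenetic parameter curves -----------------------------------------

# piecewise-constant parameters along the spiral; segments override defaults
conch_params_at <- function(spec, theta) {
  W <- rep(spec$expansion_per_rev, length(theta))
  u <- rep(spec$umbilical_exposure, length(theta))
  infl <- rep(spec$inflation, length(theta))
  for (seg in spec$ontogeny_segments) {
    sel <- theta >= seg$start_deg & theta < seg$end_deg
    if (!is.null(seg$expansion_per_rev)) W[sel] <- seg$expansion_per_rev
    if (!is.null(seg$umbilical_exposure)) u[sel] <- seg$umbilical_exposure
    if (!is.null(seg$inflation)) infl[sel] <- seg$inflation
  }
  list(W = W, u = u, infl = infl)
}

# venter radius r_v(theta) = r0 * exp( int_0^theta log W(phi) / 360 dphi ),
# exact for piecewise-constant W
venter_radius <- function(spec, theta) {
  brk <- sort(unique(c(0, unlist(lapply(spec$ontogeny_segments, function(s)
    c(s$start_deg, s$end_deg))))))
  vapply(theta, function(th) {
    if (th <= 0) return(spec$initial_radius *
                          exp(log(conch_params_at(spec, 0)$W) * th / 360))
    lo <- sort(unique(c(0, brk[brk > 0 & brk < th])))
    hi <- c(lo[-1], th)
    Wm <- conch_params_at(spec, (lo + hi) / 2)$W
    spec$initial_radius * exp(sum(log(Wm) * (hi - lo)) / 360)
  }, numeric(1))
}

# section frame at theta: venter/dorsal radii and superellipse half-axes
section_frame <- function(spec, theta) {
  p <- conch_params_at(spec, theta)
  r_v <- venter_radius(spec, theta)
  r_d <- p$u * r_v
  h <- r_v - r_d
  list(r_v = r_v, r_d = r_d, h = h, rc = (r_v + r_d) / 2,
       a = h / 2, b = p$infl * h / 2)
}

# unit section shape: k x 2 (radial, axial), counter-clockwise, extent [-1,1]
unit_section <- function(spec) {
  if (is.matrix(spec$whorl_section)) return(spec$whorl_section * 2)
  k <- spec$n_section
  t <- 2 * pi * (seq_len(k) - 1) / k
  e <- 2 / spec$section_exponent
  cbind(sign(cos(t)) * abs(cos(t))^e, sign(sin(t)) * abs(sin(t))^e)
}

# outer radial boundary rho_max(y) of the (unclipped) section at theta;
# -Inf outside the section's breadth. Used to conform involute whorls to the
# whorl one or more revolutions back. Analytic for superellipse sections.
section_outer_boundary <- function(spec, theta, y) {
  fr <- section_frame(spec, theta)
  if (is.matrix(spec$whorl_section)) {
    poly <- cbind(fr$rc + spec$whorl_section[, 1] * 2 * fr$a,
                  spec$whorl_section[, 2] * 2 * fr$b)
    return(poly_xmax_at(poly, y))
  }
  n <- spec$section_exponent
  out <- rep(-Inf, length(y))
  inside <- abs(y) <= fr$b
  out[inside] <- fr$rc + fr$a * (1 - abs(y[inside] / fr$b)^n)^(1 / n)
  out
}

poly_xmax_at <- function(poly, yq) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), , drop = FALSE]
  out <- rep(-Inf, length(yq))
  for (i in seq_len(n)) {
    y1 <- a[i, 2]; y2 <- b[i, 2]
    if (y1 == y2) next
    tt <- (yq - y1) / (y2 - y1)
    hit <- tt >= 0 & tt <= 1
    if (any(hit)) {
      x <- a[i, 1] + tt[hit] * (b[i, 1] - a[i, 1])
      out[hit] <- pmax(out[hit], x)
    }
  }
  out
}

#' Whorl section curve at an ontogenetic angle
#'
#' Returns the closed planar whorl-section polyline (radial, axial
#' coordinates in cm) at spiral angle `angle_deg`, scaled to the whorl height
#' at that angle and conformed to earlier whorls where the conch is involute.
#'
#' @param spec a [conch_spec()].
#' @param angle_deg spiral angle in degrees.
#' @param clip conform the dorsal side to earlier whorls (default TRUE).
#' @return k x 2 matrix (columns: radial, axial), counter-clockwise, not
#'   closed (last point connects to the first).
#' @export
generate_whorl_section <- function(spec, angle_deg, clip = TRUE) {
  fr <- section_frame(spec, angle_deg)
  us <- unit_section(spec)
  sec <- cbind(fr$rc + us[, 1] * fr$a, us[, 2] * fr$b)
  if (clip && angle_deg >= 360) {
    gap <- 1e-4 * fr$r_v # keep conformed walls strictly separated
    back <- angle_deg - 360
    bound0 <- -Inf # previous-whorl boundary on the symmetry plane
    while (back >= 0) {
      bound <- section_outer_boundary(spec, back, sec[, 2])
      if (all(!is.finite(bound))) break
      bound0 <- max(bound0, section_outer_boundary(spec, back, 0))
      sec[, 1] <- pmax(sec[, 1], ifelse(is.finite(bound), bound + gap, -Inf))
      back <- back - 360
    }
    # the whorl height left after conforming must at least hold the wall
    t_wall <- spec$shell_thickness_ratio * fr$h /
      (1 + 2 * spec$shell_thickness_ratio)
    if (is.finite(bound0) && fr$r_v - max(fr$r_d, bound0) < 4 * t_wall)
      stop(sprintf(paste0(
        "whorl section at %.4g deg overlaps the previous whorl beyond ",
        "tolerance; increase expansion_per_rev or umbilical_exposure"),
        angle_deg))
  }
  sec
}

# inner (shell-interior) section: the outer section shrunk about its frame
# center so that the wall thickness equals shell_thickness_ratio of the inner
# whorl height (t = r h / (1 + 2 r) in terms of the outer height h)
inner_whorl_section <- function(spec, angle_deg, outer = NULL) {
  fr <- section_frame(spec, angle_deg)
  if (is.null(outer)) outer <- generate_whorl_section(spec, angle_deg)
  r <- spec$shell_thickness_ratio
  t <- r * fr$h / (1 + 2 * r)
  ctr <- c(fr$rc, 0)
  s_r <- (fr$a - t) / fr$a
  s_y <- (fr$b - t) / fr$b
  if (s_r <= 0 || s_y <= 0) stop("shell thickness exceeds whorl section size")
  cbind(ctr[1] + (outer[, 1] - ctr[1]) * s_r, outer[, 2] * s_y)
}

# place a 2D section (radial, axial) into 3D at spiral angle theta:
# P = rho * (cos th, 0, sin th) + (0, y, 0)
ring3d <- function(sec, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(sec[, 1] * cos(th), sec[, 2], sec[, 1] * sin(th))
}

# closed swept solid through a list of 3D rings (equal point counts);
# fan-capped at both ends and oriented outward (positive volume)
sweep_solid <- function(rings, name = NULL) {
  k <- nrow(rings[[1]])
  nr <- length(rings)
  if (nr < 2L) stop("need at least two rings to sweep")
  v <- do.call(rbind, rings)
  j <- seq_len(k)
  jn <- c(2:k, 1L)
  side <- vector("list", nr - 1L)
  for (i in seq_len(nr - 1L)) {
    o1 <- (i - 1L) * k
    o2 <- i * k
    side[[i]] <- rbind(cbind(o1 + j, o2 + j, o1 + jn),
                       cbind(o1 + jn, o2 + j, o2 + jn))
  }
  c1 <- nrow(v) + 1L
  c2 <- nrow(v) + 2L
  v <- rbind(v, colMeans(rings[[1]]), colMeans(rings[[nr]]))
  cap1 <- cbind(c1, j, jn)
  o <- (nr - 1L) * k
  cap2 <- cbind(c2, o + jn, o + j)
  m <- tri_mesh(v, do.call(rbind, c(side, list(cap1, cap2))), name = name)
  if (signed_volume(m, check = FALSE) < 0) m <- mesh_invert(m)
  m
}

# spiral angles sampled for a sweep over [from, to], including both ends
sweep_angles <- function(spec, from, to) {
  if (to <= from) stop("empty sweep interval")
  lo <- ceiling(from / spec$step_deg) * spec$step_deg
  hi <- floor(to / spec$step_deg) * spec$step_deg
  inner <- if (lo <= hi) seq(lo, hi, by = spec$step_deg) else numeric(0)
  sort(unique(c(from, inner[inner > from & inner < to], to)))
}

# ---- conch surfaces and model components ----------------------------------

#' Generate the outer and inner shell surfaces of a theoretical conch
#'
#' Sweeps the whorl section along a logarithmic spiral: each section is
#' rotated about the coiling axis, scaled by `W^(step/360)`, and positioned
#' between the dorsal margin (set by the umbilical exposure, conformed to
#' earlier whorls when involute) and the venter. The inner surface is offset
#' inward by the shell thickness. Both surfaces are capped at the apex and
#' the aperture and are watertight. Regeneration from an identical spec is
#' bit-identical.
#'
#' @param spec a [conch_spec()].
#' @return An object of class `conch`, a list with `outer` and `inner`
#'   [tri_mesh()] surfaces, the `spec`, the aperture frame
#'   (`aperture_normal`, `hyponome_point`) and `theta_end`.
#' @export
generate_conch <- function(spec) {
  theta_end <- spec$total_revolutions * 360
  th <- sweep_angles(spec, 0, theta_end)
  outer2d <- lapply(th, function(t) generate_whorl_section(spec, t))
  inner2d <- Map(function(t, o) inner_whorl_section(spec, t, o), th, outer2d)
  outer <- sweep_solid(Map(ring3d, outer2d, th), name = "water_displaced")
  inner <- sweep_solid(Map(ring3d, inner2d, th), name = "shell_interior")
  a <- theta_end * pi / 180
  structure(list(outer = outer, inner = inner, spec = spec,
                 theta_end = theta_end,
                 aperture_normal = c(-sin(a), 0, cos(a)),
                 hyponome_point = venter_radius(spec, theta_end) *
                   c(cos(a), 0, sin(a))),
            class = "conch")
}

#' @export
print.conch <- function(x, ...) {
  cat(sprintf("conch '%s': outer %d faces, inner %d faces, %.3g revolutions\n",
              x$spec$name, nrow(x$outer$faces), nrow(x$inner$faces),
              x$theta_end / 360))
  invisible(x)
}

# inner-tube solid swept over [from, to] degrees of spiral
inner_tube_sweep <- function(spec, from, to, name = NULL) {
  th <- sweep_angles(spec, from, to)
  rings <- lapply(th, function(t)
    ring3d(inner_whorl_section(spec, t), t))
  sweep_solid(rings, name = name)
}

# septum positions (deg) given the phragmocone extent
septum_angles <- function(spec, theta_end) {
  theta_ps <- theta_end - spec$body_chamber_angle
  if (theta_ps < spec$septal_spacing_deg)
    stop("body chamber shorter than one septal spacing leaves no phragmocone")
  k <- seq_len(floor(theta_ps / spec$septal_spacing_deg))
  sort(theta_ps - (k - 1) * spec$septal_spacing_deg)
}

# angular half-thickness (deg) of the septal slab at theta
septum_half_thickness <- function(spec, theta) {
  fr <- section_frame(spec, theta)
  r <- spec$shell_thickness_ratio
  h_in <- fr$h * (1 - 2 * r / (1 + 2 * r))
  t_s <- spec$septal_thickness_ratio * h_in
  (t_s / fr$rc) * 180 / pi / 2
}

#' Insert septa and extract the cameral volumes
#'
#' Septa are placed every `septal_spacing_deg` along the spiral of the
#' phragmocone (the part of the tube adapical of the body chamber), each a
#' thin slab of the inner shell tube with thickness
#' `septal_thickness_ratio` times the inner whorl height. The chamber voids
#' between consecutive septa (and the apical void below the first septum)
#' form the cameral volumes. Chambers, septa, the soft body and the shell
#' wall partition the displaced-water solid exactly, so the component volumes
#' sum to the displaced volume by construction.
#'
#' @param conch a [generate_conch()] result.
#' @return List with `septa` (list of [tri_mesh()]), `cameral_volumes`
#'   (multi-component [tri_mesh()]), `chambers` (the individual chamber
#'   meshes) and `septum_angles_deg`.
#' @export
insert_septa <- function(conch) {
  spec <- conch$spec
  sa <- septum_angles(spec, conch$theta_end)
  hw <- vapply(sa, function(t) septum_half_thickness(spec, t), numeric(1))
  septa <- Map(function(t, h) {
    inner_tube_sweep(spec, t - h, t + h,
                     name = sprintf("septum_%.0fdeg", t))
  }, sa, hw)
  lo <- c(0, sa + hw)
  hi <- c(sa - hw, NA)
  chambers <- lapply(seq_along(sa), function(i)
    inner_tube_sweep(spec, lo[i], hi[i],
                     name = sprintf("chamber_%02d", i)))
  list(septa = septa,
       chambers = chambers,
       cameral_volumes = mesh_merge(chambers, name = "cameral_volumes"),
       septum_angles_deg = sa)
}

#' Soft-body mesh filling the body chamber
#'
#' The soft body fills the inner shell tube adapertural of the final septum,
#' terminating flush with the aperture plane (a conservative estimate with no
#' protruding head profile).
#'
#' @param conch a [generate_conch()] result.
#' @param body_chamber_angle degrees of spiral occupied; defaults to the
#'   spec's value.
#' @return A watertight [tri_mesh()], or `NULL` when the angle is 0.
#' @export
partition_soft_body <- function(conch,
                                body_chamber_angle = conch$spec$body_chamber_angle) {
  spec <- conch$spec
  if (body_chamber_angle < 0 || body_chamber_angle > conch$theta_end)
    stop("body_chamber_angle exceeds the spiral extent")
  if (body_chamber_angle == 0) return(NULL)
  spec$body_chamber_angle <- body_chamber_angle
  theta_ps <- conch$theta_end - body_chamber_angle
  from <- if (theta_ps >= spec$septal_spacing_deg) {
    sa <- septum_angles(spec, conch$theta_end)
    max(sa) + septum_half_thickness(spec, max(sa))
  } else theta_ps
  inner_tube_sweep(spec, from, conch$theta_end, name = "soft_body")
}

#' Full multi-component conch model
#'
#' Builds every component needed for hydrostatics: the shell (outer surface
#' plus inverted inner surface, i.e. the wall solid, unified with the septa),
#' the soft body, the cameral volumes and the displaced-water envelope.
#'
#' @param spec a [conch_spec()].
#' @return An object of class `conch_model`: a list with `shell`, `septa`,
#'   `soft_body`, `cameral_volumes`, `water_displaced`, `chambers`,
#'   `aperture_normal`, `hyponome_point`, `body_chamber_angle` and `spec`.
#' @export
conch_model <- function(spec) {
  conch <- generate_conch(spec)
  sep <- insert_septa(conch)
  sb <- partition_soft_body(conch)
  shell_wall <- mesh_merge(conch$outer, mesh_invert(conch$inner),
                           name = "shell_wall")
  shell <- mesh_merge(c(list(shell_wall), sep$septa), name = "shell")
  structure(list(shell = shell,
                 shell_wall = shell_wall,
                 septa = sep$septa,
                 chambers = sep$chambers,
                 cameral_volumes = sep$cameral_volumes,
                 soft_body = sb,
                 water_displaced = conch$outer,
                 aperture_normal = conch$aperture_normal,
                 hyponome_point = conch$hyponome_point,
                 body_chamber_angle = spec$body_chamber_angle,
                 spec = spec),
            class = "conch_model")
}

#' @export
print.conch_model <- function(x, ...) {
  cat(sprintf(paste0(
    "conch_model '%s': %d chambers, body chamber %.4g deg\n",
    "  V(displaced)=%.4g, V(shell)=%.4g, V(chambers)=%.4g, V(soft)=%.4g cm^3\n"),
    x$spec$name, length(x$chambers), x$body_chamber_angle,
    signed_volume(x$water_displaced, check = FALSE),
    signed_volume(x$shell, check = FALSE),
    signed_volume(x$cameral_volumes, check = FALSE),
    if (is.null(x$soft_body)) 0 else signed_volume(x$soft_body, check = FALSE)))
  invisible(x)
}

# ---- morphospace -----------------------------------------------------------

#' Conch measurements from a specification
#'
#' Analytic measurements at the aperture: conch diameter `D`, umbilical
#' diameter `U`, apertural whorl height `ah` and breadth `ab`, plus the true
#' whorl expansion rate `W`.
#'
#' @param spec a [conch_spec()].
#' @return Named list of measurements (cm).
#' @export
conch_measurements <- function(spec) {
  theta_end <- spec$total_revolutions * 360
  r1 <- venter_radius(spec, theta_end)
  r_half <- venter_radius(spec, theta_end - 180)
  p <- conch_params_at(spec, theta_end - 1e-9)
  list(D = r1 + r_half,
       U = p$u * (r1 + r_half),
       ah = (1 - p$u) * r1,
       ab = p$infl * (1 - p$u) * r1,
       W = (r1 / r_half)^2)
}

#' Westermann morphospace coordinates
#'
#' Maps conch measurements onto a ternary morphospace whose corners are high
#' whorl expansion (oxycones), high umbilical exposure (serpenticones) and
#' high conch inflation (sphaerocones). The classic ternary diagram's exact
#' normalization varies across the morphospace literature, so the default
#' scheme here is the package's own documented choice: raw indices
#' `(W - 1) / 2`, `(U / D) / u_ref` and `(ab / ah) / th_ref`, each clamped to
#' `[0, 1]`, then normalized to sum to 1. Reference scales are configurable.
#'
#' @param D conch diameter.
#' @param U umbilical diameter (must be < D).
#' @param ah apertural whorl height.
#' @param ab apertural whorl breadth.
#' @param W whorl expansion rate per revolution; when `NULL` it is estimated
#'   from `D` and `ah` (venter ratio of abutting whorls), capped at `w_cap`.
#' @param u_ref,th_ref,w_cap normalization constants of the default scheme.
#' @return An object of class `morphospace_point`: named numeric
#'   `(w_exp, u_exp, th_infl)` summing to 1.
#' @export
westermann_coordinates <- function(D, U, ah, ab, W = NULL,
                                   u_ref = 0.6, th_ref = 2, w_cap = 3) {
  if (any(c(D, ah, ab) <= 0) || U < 0) stop("measurements must be positive")
  if (U >= D) stop("umbilical diameter must be smaller than the diameter")
  if (ah >= D) stop("apertural height cannot exceed the diameter")
  if (is.null(W)) {
    W <- if (ah >= D / 2) w_cap else min(((D / 2) / (D / 2 - ah))^2, w_cap)
  }
  raw <- c(w_exp = min(max((W - 1) / 2, 0), 1),
           u_exp = min(U / D / u_ref, 1),
           th_infl = min(ab / ah / th_ref, 1))
  if (sum(raw) == 0) stop("degenerate measurements map to the empty point")
  structure(raw / sum(raw), class = "morphospace_point")
}

#' @export
print.morphospace_point <- function(x, ...) {
  cat(sprintf("morphospace point: w=%.3f, u=%.3f, th=%.3f\n",
              x[["w_exp"]], x[["u_exp"]], x[["th_infl"]]))
  invisible(x)
}

#' Demonstration conch specifications for the four morphotypes
#'
#' Qualitative stand-ins for the serpenticone, oxycone, sphaerocone and
#' morphospace-center morphologies: evolute-compressed, involute-compressed,
#' involute-inflated and intermediate planispiral conchs.
#'
#' @param step_deg,n_section resolution overrides applied to every spec.
#' @return Named list of [conch_spec()] objects.
#' @export
demo_conch_specs <- function(step_deg = 2, n_section = 40) {
  list(
    serpenticone = conch_spec(expansion_per_rev = 1.6,
                              umbilical_exposure = 0.625,
                              inflation = 0.45,
                              total_revolutions = 4,
                              body_chamber_angle = 225.9,
                              step_deg = step_deg, n_section = n_section,
                              name = "serpenticone"),
    oxycone = conch_spec(expansion_per_rev = 2.8,
                         umbilical_exposure = 0.05,
                         inflation = 0.3,
                         total_revolutions = 3,
                         body_chamber_angle = 34.5,
                         step_deg = step_deg, n_section = n_section,
                         name = "oxycone"),
    sphaerocone = conch_spec(expansion_per_rev = 1.8,
                             umbilical_exposure = 0.05,
                             inflation = 1.8,
                             total_revolutions = 3,
                             body_chamber_angle = 267,
                             step_deg = step_deg, n_section = n_section,
                             name = "sphaerocone"),
    center = conch_spec(expansion_per_rev = 2,
                        umbilical_exposure = 0.3,
                        inflation = 1,
                        total_revolutions = 3,
                        body_chamber_angle = 218.6,
                        step_deg = step_deg, n_section = n_section,
                        name = "center"))
}
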
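#' Material density table
#'
#' Default densities adopted for ectocochleate hydrostatics: soft body
#' 1.049 g/cm^3 (bulk tissue with a seawater-filled mantle cavity and thin
#' calcitic mouthparts), shell 2.54 g/cm^3 (aragonite), cameral liquid
#' 1.025 g/cm^3 (seawater), cameral gas 0.001 g/cm^3. The ambient
#' (displaced) water density defaults to seawater and can be lowered for
#' pool water.
#'
#' @param soft_body,shell,cameral_liquid,cameral_gas,water_displaced
#'   densities in g/cm^3.
#' @return A named list of class `density_table`.
#' @export
density_table <- function(soft_body = 1.049, shell = 2.54,
                          cameral_liquid = 1.025, cameral_gas = 0.001,
                          water_displaced = 1.025) {
  d <- list(soft_body = soft_body, shell = shell,
            cameral_liquid = cameral_liquid, cameral_gas = cameral_gas,
            water_displaced = water_displaced)
  if (any(unlist(d) <= 0)) stop("densities must be > 0")
  if (cameral_gas >= cameral_liquid)
    stop("cameral_gas density must be below cameral_liquid density")
  class(d) <- "density_table"
  d
}

component_volume <- function(x) {
  if (inherits(x, "tri_mesh")) signed_volume(x, check = FALSE) else x$volume
}

component_center <- function(x) {
  if (inherits(x, "tri_mesh")) mesh_centroid(x, check = FALSE) else x$center
}

#' Hydrostatic model of a multi-component body
#'
#' Wraps the component solids needed by the buoyancy calculations: the
#' displaced-water envelope, the soft body, the shell (walls plus septa) and
#' the cameral (chamber) volumes. Components may be [tri_mesh()] objects or
#' plain `list(volume=, center=)` stand-ins, which makes closed-form test
#' models easy to express.
#'
#' @param water_displaced,soft_body,shell,cameral component solids.
#' @param densities a [density_table()].
#' @param hyponome_point 3D point at the ventral edge of the aperture (cm).
#' @param aperture_normal unit direction the soft body faces.
#' @return An object of class `hydrostatic_model`.
#' @export
hydrostatic_model <- function(water_displaced, soft_body, shell, cameral,
                              densities = density_table(),
                              hyponome_point = NULL,
                              aperture_normal = NULL) {
  structure(list(water_displaced = water_displaced, soft_body = soft_body,
                 shell = shell, cameral = cameral, densities = densities,
                 hyponome_point = hyponome_point,
                 aperture_normal = aperture_normal),
            class = "hydrostatic_model")
}

#' @rdname hydrostatic_model
#' @param model a [conch_model()].
#' @export
as_hydrostatic_model <- function(model, densities = density_table()) {
  hydrostatic_model(water_displaced = model$water_displaced,
                    soft_body = model$soft_body,
                    shell = model$shell,
                    cameral = model$cameral_volumes,
                    densities = densities,
                    hyponome_point = model$hyponome_point,
                    aperture_normal = model$aperture_normal)
}

#' Chamber fill fraction for neutral buoyancy
#'
#' Solves the neutral-buoyancy condition (organismal mass equals displaced
#' mass) for the chamber contents:
#'
#' \deqn{\Phi = \frac{(V_{wd}\rho_{wd} - V_{sb}\rho_{sb} -
#'   V_{sh}\rho_{sh})/V_{ct} - \rho_{cl}}{\rho_{cg} - \rho_{cl}}}
#'
#' Note on reading: this formula, evaluated as written, is the *gas* fraction
#' of the total chamber volume — when the chambers must be entirely liquid
#' (residual chamber density equal to the liquid density) it returns 0, and
#' when entirely gas it returns 1. The complement `1 - phi` is the liquid
#' fraction, which is the quantity usually quoted as "percent cameral
#' liquid"; both are returned, and downstream reports state which reading
#' they quote.
#'
#' @param model a [hydrostatic_model()] (or anything with the four component
#'   volumes) — alternatively pass bare volumes.
#' @param densities a [density_table()]; defaults to the model's table.
#' @param V_wd,V_sb,V_sh,V_ct volumes (cm^3) overriding the model components.
#' @return List with `phi` (gas fraction as the formula evaluates),
#'   `liquid_fraction` (`1 - phi`), `residual_density`, `mass_residual`
#'   (organismal minus displaced mass with the solved contents, g) and
#'   `attainable` (`phi` within `[0, 1]`).
#' @export
chamber_fill_fraction <- function(model = NULL, densities = NULL,
                                  V_wd = NULL, V_sb = NULL, V_sh = NULL,
                                  V_ct = NULL) {
  if (!is.null(model)) {
    if (is.null(densities)) densities <- model$densities
    if (is.null(V_wd)) V_wd <- component_volume(model$water_displaced)
    if (is.null(V_sb)) V_sb <- if (is.null(model$soft_body)) 0 else
      component_volume(model$soft_body)
    if (is.null(V_sh)) V_sh <- component_volume(model$shell)
    if (is.null(V_ct)) V_ct <- component_volume(model$cameral)
  }
  if (is.null(densities)) densities <- density_table()
  if (V_ct <= 0) stop("total chamber volume must be > 0")
  d <- densities
  R <- (V_wd * d$water_displaced - V_sb * d$soft_body - V_sh * d$shell) / V_ct
  phi <- (R - d$cameral_liquid) / (d$cameral_gas - d$cameral_liquid)
  organismal <- V_sb * d$soft_body + V_sh * d$shell +
    V_ct * (phi * d$cameral_gas + (1 - phi) * d$cameral_liquid)
  res <- list(phi = phi, liquid_fraction = 1 - phi, residual_density = R,
              mass_residual = organismal - V_wd * d$water_displaced,
              attainable = phi >= 0 && phi <= 1)
  if (!res$attainable)
    res$note <- sprintf(
      "not neutrally buoyant at this geometry (phi = %.4g outside [0, 1])",
      phi)
  res
}

#' Mass-weighted total center of mass
#'
#' @param masses numeric vector of component masses (g), or a list of
#'   `list(mass=, center=)` components (then `centers` is ignored).
#' @param centers matrix (n x 3) of component centers (cm).
#' @return Length-3 numeric: the total center of mass.
#' @export
total_center_of_mass <- function(masses, centers = NULL) {
  if (is.list(masses) && is.null(centers)) {
    centers <- do.call(rbind, lapply(masses, `[[`, "center"))
    masses <- vapply(masses, `[[`, numeric(1), "mass")
  }
  centers <- matrix(centers, ncol = 3)
  total <- sum(masses)
  if (total <= 0) stop("total mass must be > 0")
  colSums(centers * masses) / total
}

#' Hydrostatic stability index
#'
#' `St = |B - M| / V^(1/3)`: the separation of the centers of buoyancy and
#' mass normalized by the cube root of the displaced volume — dimensionless
#' and scale-independent.
#'
#' @param B center of buoyancy (cm).
#' @param M center of mass (cm).
#' @param V displaced volume (cm^3).
#' @return The stability index.
#' @export
stability_index <- function(B, M, V) {
  if (V <= 0) stop("volume must be > 0")
  sqrt(sum((B - M)^2)) / V^(1 / 3)
}

# minimal rotation bringing B vertically above M; errors when B == M
equilibrium_rotation <- function(B, M, tol = 1e-12) {
  d <- B - M
  n <- sqrt(sum(d^2))
  if (n < tol) stop("B and M coincide: no defined equilibrium orientation")
  rotation_between(d / n, c(0, 0, 1))
}

#' Apertural orientation at hydrostatic equilibrium
#'
#' The model is first rotated so the center of buoyancy sits vertically
#' above the center of mass (the minimal such rotation); the returned angle
#' is the elevation of the aperture-facing direction from the horizontal:
#' 0 degrees faces horizontally, +90 straight up, -90 straight down.
#'
#' @param aperture_normal unit direction the soft body faces (pre-rotation).
#' @param B,M centers of buoyancy and mass (cm, pre-rotation).
#' @return Angle in degrees.
#' @export
apertural_orientation <- function(aperture_normal, B, M) {
  R <- equilibrium_rotation(B, M)
  n <- as.vector(R %*% aperture_normal)
  n <- n / sqrt(sum(n^2))
  asin(max(-1, min(1, n[3]))) * 180 / pi
}

#' Thrust angle
#'
#' Elevation, after equilibration, of the segment from the hyponome (ventral
#' edge of the aperture) to the midpoint of the hydrostatic centers. 0
#' degrees is idealized horizontal backward thrust; +90 transmits energy
#' into downward movement most efficiently, -90 into upward movement.
#'
#' @param hyponome_point hyponome location (cm, pre-rotation).
#' @inheritParams apertural_orientation
#' @return Angle in degrees.
#' @export
thrust_angle <- function(hyponome_point, B, M) {
  R <- equilibrium_rotation(B, M)
  mid <- as.vector(R %*% ((B + M) / 2))
  hyp <- as.vector(R %*% hyponome_point)
  d <- mid - hyp
  horiz <- sqrt(sum(d[1:2]^2))
  if (horiz < 1e-12 && abs(d[3]) < 1e-12)
    stop("hyponome coincides with the midpoint of the hydrostatic centers")
  atan2(d[3], horiz) * 180 / pi
}

#' Complete hydrostatic solution
#'
#' Computes the chamber fill solving neutral buoyancy, the centers of
#' buoyancy and mass (chamber liquid and gas both placed at the center of
#' volume of all chambers — a minor assumption given capillary retention of
#' liquid at the septal margins), the stability index, and the apertural and
#' thrust angles.
#'
#' @param model a [hydrostatic_model()] or [conch_model()].
#' @param densities a [density_table()].
#' @return An object of class `hydrostatic_result`.
#' @export
hydrostatics <- function(model, densities = NULL) {
  if (inherits(model, "conch_model"))
    model <- as_hydrostatic_model(model, densities %||% density_table())
  if (is.null(densities)) densities <- model$densities
  d <- densities
  V_wd <- component_volume(model$water_displaced)
  V_sb <- if (is.null(model$soft_body)) 0 else
    component_volume(model$soft_body)
  V_sh <- component_volume(model$shell)
  V_ct <- component_volume(model$cameral)
  fill <- chamber_fill_fraction(densities = d, V_wd = V_wd, V_sb = V_sb,
                                V_sh = V_sh, V_ct = V_ct)
  B <- component_center(model$water_displaced)
  cam_ctr <- component_center(model$cameral)
  comps <- list(
    list(mass = V_sb * d$soft_body,
         center = if (V_sb > 0) component_center(model$soft_body) else
           c(0, 0, 0)),
    list(mass = V_sh * d$shell, center = component_center(model$shell)),
    list(mass = (1 - fill$phi) * V_ct * d$cameral_liquid, center = cam_ctr),
    list(mass = fill$phi * V_ct * d$cameral_gas, center = cam_ctr))
  M <- total_center_of_mass(comps)
  res <- list(phi = fill$phi, liquid_fraction = fill$liquid_fraction,
              attainable = fill$attainable,
              mass_residual = fill$mass_residual,
              B = B, M = M,
              St = stability_index(B, M, V_wd),
              total_mass = sum(vapply(comps, `[[`, numeric(1), "mass")),
              displaced_mass = V_wd * d$water_displaced,
              volumes = c(water_displaced = V_wd, soft_body = V_sb,
                          shell = V_sh, cameral = V_ct))
  res$apertural_angle <- if (!is.null(model$aperture_normal))
    tryCatch(apertural_orientation(model$aperture_normal, B, M),
             error = function(e) NA_real_) else NA_real_
  res$thrust_angle <- if (!is.null(model$hyponome_point))
    tryCatch(thrust_angle(model$hyponome_point, B, M),
             error = function(e) NA_real_) else NA_real_
  class(res) <- "hydrostatic_result"
  res
}

#' @export
print.hydrostatic_result <- function(x, ...) {
  cat(sprintf(paste0(
    "hydrostatic result: displaced mass %.4g g\n",
    "  chamber gas fraction (formula reading) %.4f, liquid fraction %.4f%s\n",
    "  St = %.5f, apertural angle = %.2f deg, thrust angle = %.2f deg\n"),
    x$displaced_mass, x$phi, x$liquid_fraction,
    if (x$attainable) "" else "  [NOT neutrally buoyant]",
    x$St, x$apertural_angle, x$thrust_angle))
  invisible(x)
}

#' Scale a model to a target displaced mass
#'
#' Uniform scaling so that displaced volume times ambient water density
#' equals the target mass; the stability index is scale-invariant and
#' unchanged.
#'
#' @param model a [conch_model()] or [hydrostatic_model()] whose components
#'   are meshes.
#' @param target_mass displaced mass to reach, g.
#' @param densities a [density_table()] supplying the ambient density.
#' @return List with the scaled `model` and the linear `factor` applied.
#' @export
scale_to_displaced_mass <- function(model, target_mass = 982,
                                    densities = density_table()) {
  if (target_mass <= 0) stop("target mass must be > 0")
  V <- component_volume(model$water_displaced)
  factor <- (target_mass / (densities$water_displaced * V))^(1 / 3)
  scale_component <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "tri_mesh")) return(mesh_scale(x, factor))
    if (is.list(x) && !is.null(x$volume))
      return(list(volume = x$volume * factor^3, center = x$center * factor))
    x
  }
  for (nm in intersect(names(model),
                       c("water_displaced", "soft_body", "shell",
                         "shell_wall", "cameral", "cameral_volumes")))
    model[[nm]] <- scale_component(model[[nm]])
  if (!is.null(model$septa)) model$septa <- lapply(model$septa, scale_component)
  if (!is.null(model$chambers))
    model$chambers <- lapply(model$chambers, scale_component)
  if (!is.null(model$hyponome_point))
    model$hyponome_point <- model$hyponome_point * factor
  list(model = model, factor = factor)
}

#' Fit the body chamber to a target cameral-liquid fraction
#'
#' Bisection on the body-chamber angle until the neutral-buoyancy liquid
#' fraction of the chamber volume matches the target (extant Nautilus
#' retains roughly 12% of the phragmocone volume as liquid). The liquid
#' fraction decreases monotonically with the body-chamber angle over the
#' physically sensible bracket: a larger soft body is denser than the water
#' it displaces, so more chamber gas is needed.
#'
#' @param spec a [conch_spec()].
#' @param liquid_target target liquid fraction of chamber volume.
#' @param tol absolute tolerance on the achieved fraction.
#' @param bracket angular search bracket (degrees of body chamber).
#' @param densities a [density_table()].
#' @param max_iter bisection iteration cap.
#' @return List with `body_chamber_angle`, `liquid_fraction`, the fitted
#'   `model` and `hydro` result.
#' @export
fit_body_chamber <- function(spec, liquid_target = 0.12, tol = 0.005,
                             bracket = c(20, 330),
                             densities = density_table(), max_iter = 40) {
  liquid_at <- function(angle) {
    s <- spec
    s$body_chamber_angle <- angle
    chamber_fill_fraction(as_hydrostatic_model(conch_model(s), densities))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- liquid_at(lo)$liquid_fraction
  fhi <- liquid_at(hi)$liquid_fraction
  # liquid fraction decreases with angle: need flo >= target >= fhi
  if ((flo - liquid_target) * (fhi - liquid_target) > 0)
    stop(sprintf(paste0(
      "liquid target %.3g not bracketed: fraction is %.4g at %g deg and ",
      "%.4g at %g deg"), liquid_target, flo, lo, fhi, hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- liquid_at(mid)$liquid_fraction
    if (abs(fm - liquid_target) <= tol) break
    if ((fm - liquid_target) * (flo - liquid_target) > 0) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  s <- spec
  s$body_chamber_angle <- mid
  model <- conch_model(s)
  list(body_chamber_angle = mid, liquid_fraction = fm, model = model,
       hydro = hydrostatics(model, densities))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
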
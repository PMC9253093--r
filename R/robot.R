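#' Robot mass components and budgets
#'
#' A biomimetic conch robot is balanced by listing every component of unique
#' density with its mass and local center of mass, then solving for the
#' 3D-printed thermoplastic (PETG) hull: its mass is whatever is left to
#' reach neutral buoyancy, and its center is placed so that the composite
#' center of mass lands on the target inferred from the virtual hydrostatic
#' model. Fixed components (motor, batteries, electronics, trim liquid) are
#' immutable during solving.
#'
#' @param name component label.
#' @param mass mass in g (alternatively give `mesh` + `density`).
#' @param center length-3 local center of mass (cm).
#' @param movable logical: solvable (PETG, counterweight) or fixed.
#' @param mesh optional [tri_mesh()]; with `density`, mass and center are
#'   computed from it.
#' @param density g/cm^3, used with `mesh`.
#' @param izz_own optional own-axis vertical moment of inertia (g cm^2)
#'   about the component's center, used by [compare_inertia()].
#' @return A `mass_component`.
#' @export
mass_component <- function(name, mass = NULL, center = NULL, movable = FALSE,
                           mesh = NULL, density = NULL, izz_own = NULL) {
  if (!is.null(mesh)) {
    it <- inertia_tensor(mesh, density = density %||% mesh$density)
    mass <- it$mass
    center <- it$center
    if (is.null(izz_own)) izz_own <- it$tensor[3, 3]
  }
  if (is.null(mass) || is.null(center))
    stop("component needs mass and center (or a mesh with density)")
  if (mass <= 0) stop("component mass must be > 0")
  structure(list(name = name, mass = mass, center = as.numeric(center),
                 movable = movable, izz_own = izz_own),
            class = "mass_component")
}

#' @rdname mass_component
#' @param components list of [mass_component()]; must contain one movable
#'   component named `"PETG"` (mass/center may be `NA` placeholders before
#'   solving).
#' @param displaced_mass mass of the water displaced by the robot (g).
#' @param target_M length-3 target total center of mass (cm), from the
#'   virtual hydrostatic model.
#' @export
mass_budget <- function(components, displaced_mass, target_M) {
  stopifnot(displaced_mass > 0, length(target_M) == 3)
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("component names must be unique")
  if (!"PETG" %in% nm) {
    components <- c(components, list(structure(
      list(name = "PETG", mass = NA_real_, center = rep(NA_real_, 3),
           movable = TRUE, izz_own = NULL), class = "mass_component")))
  }
  structure(list(components = components, displaced_mass = displaced_mass,
                 target_M = as.numeric(target_M)),
            class = "mass_budget")
}

budget_fixed <- function(budget) {
  Filter(function(c) c$name != "PETG", budget$components)
}

budget_component <- function(budget, name) {
  i <- which(vapply(budget$components, `[[`, character(1), "name") == name)
  if (!length(i)) stop("no component named ", name)
  budget$components[[i[1]]]
}

#' PETG mass required for neutral buoyancy
#'
#' The printed-hull mass is the displaced mass minus the mass of every other
#' component.
#'
#' @param budget a [mass_budget()].
#' @return Mass in g.
#' @export
petg_mass_for_neutrality <- function(budget) {
  fixed <- sum(vapply(budget_fixed(budget), `[[`, numeric(1), "mass"))
  m <- budget$displaced_mass - fixed
  if (m <= 0)
    stop(sprintf(
      "components too heavy for neutral buoyancy (fixed %.4g g >= displaced %.4g g)",
      fixed, budget$displaced_mass))
  m
}

#' PETG center placement
#'
#' Per axis, `D_PETG = (M * m_total - sum(D_i * m_i)) / m_PETG`, where the
#' first term uses the total mass including the PETG and the sum runs over
#' the fixed components — the only algebraically consistent reading, with
#' the round-trip guarantee that the mass-weighted mean over all components
#' returns the target center exactly.
#'
#' @param budget a [mass_budget()].
#' @param m_petg PETG mass; defaults to [petg_mass_for_neutrality()].
#' @return Length-3 PETG center (cm).
#' @export
petg_center <- function(budget, m_petg = petg_mass_for_neutrality(budget)) {
  if (m_petg < 1e-12) stop("PETG mass ~ 0: center indeterminate")
  fixed <- budget_fixed(budget)
  m_i <- vapply(fixed, `[[`, numeric(1), "mass")
  D_i <- do.call(rbind, lapply(fixed, `[[`, "center"))
  m_total <- sum(m_i) + m_petg
  (budget$target_M * m_total - colSums(D_i * m_i)) / m_petg
}

#' Solve a robot mass budget
#'
#' Fills in the PETG mass and center so the budget is simultaneously
#' neutrally buoyant and centered on the target. Idempotent: re-solving a
#' solved budget changes nothing.
#'
#' @param budget a [mass_budget()].
#' @return The budget with the PETG component solved and a `solved` flag.
#' @export
solve_mass_budget <- function(budget) {
  m <- petg_mass_for_neutrality(budget)
  ctr <- petg_center(budget, m)
  i <- which(vapply(budget$components, `[[`, character(1), "name") == "PETG")
  budget$components[[i]]$mass <- m
  budget$components[[i]]$center <- ctr
  budget$solved <- TRUE
  budget
}

#' Recompute the total center of mass of a budget
#'
#' @param budget a (solved) [mass_budget()].
#' @return Length-3 center (cm).
#' @export
budget_center <- function(budget) {
  total_center_of_mass(lapply(budget$components, function(c)
    list(mass = c$mass, center = c$center)))
}

#' Position a counterweight to reach a target stability index
#'
#' The counterweight's horizontal position is chosen so the horizontal
#' components of the total center of mass are unchanged, and its depth so
#' the resulting stability index (with the center of buoyancy fixed) meets
#' the target. Lowering the counterweight monotonically increases St.
#'
#' @param budget a solved [mass_budget()] (without the counterweight).
#' @param mass counterweight mass, g.
#' @param target_St stability index to reach.
#' @param B center of buoyancy of the robot (cm).
#' @param V displaced volume (cm^3).
#' @param z_min lowest feasible counterweight depth inside the hull (cm).
#' @return List with the counterweight `position`, the resulting `St` and
#'   the updated `budget`. Errors when the hull is too shallow, reporting
#'   the maximum attainable St.
#' @export
place_counterweight <- function(budget, mass, target_St, B, V,
                                z_min = -Inf) {
  M0 <- budget_center(budget)
  m0 <- sum(vapply(budget$components, `[[`, numeric(1), "mass"))
  if (mass <= 0) {
    return(list(position = NULL, St = stability_index(B, M0, V),
                budget = budget))
  }
  m_tot <- m0 + mass
  # keep horizontal components: x_c = M0_x etc.; choose z for the target
  sep_needed <- target_St * V^(1 / 3)
  # after adding: M_z = (m0 M0_z + mass z_c) / m_tot, want B_z - M_z = sep
  z_c <- ((B[3] - sep_needed) * m_tot - m0 * M0[3]) / mass
  if (z_c < z_min) {
    M_min <- (m0 * M0[3] + mass * z_min) / m_tot
    st_max <- stability_index(B, c(M0[1], M0[2], M_min), V)
    stop(sprintf(
      "hull too shallow to reach St = %.4g; maximum attainable %.4g",
      target_St, st_max))
  }
  cw <- mass_component("counterweight", mass = mass,
                       center = c(M0[1], M0[2], z_c), movable = TRUE)
  budget$components <- c(budget$components, list(cw))
  list(position = c(M0[1], M0[2], z_c),
       St = stability_index(B, budget_center(budget), V),
       budget = budget)
}

#' Compare moments of inertia and the vacuum yaw rate
#'
#' Sums the per-component moments of inertia about the shared vertical axis
#' (moments of inertia are additive), returns the robot/animal ratio, and
#' computes the angular velocity a torque would produce in a vacuum,
#' `omega = torque * t / Izz`.
#'
#' @param robot,animal lists of components: [tri_mesh()] objects with
#'   densities or `list(mass=, center=, izz_own=)`.
#' @param pivot point on the shared vertical axis (cm).
#' @param torque applied torque in g cm^2 / s^2 (dyn cm); use
#'   `thrust_N * 1e5 * lever_cm` for a thrust in newtons.
#' @param t jet duration, s.
#' @return List with `izz_robot`, `izz_animal` (g cm^2), `ratio`, and
#'   vacuum angular velocities `omega_vac_robot`, `omega_vac_animal`
#'   (rad/s).
#' @export
compare_inertia <- function(robot, animal, pivot = c(0, 0, 0),
                            torque = NULL, t = 1) {
  izr <- izz_total(robot, pivot)
  iza <- izz_total(animal, pivot)
  out <- list(izz_robot = izr, izz_animal = iza, ratio = izr / iza)
  if (!is.null(torque)) {
    out$omega_vac_robot <- torque * t / izr
    out$omega_vac_animal <- torque * t / iza
  }
  out
}

#' Demonstration robot mass budget
#'
#' A synthetic component table shaped like a real robot build list (motor,
#' batteries, electronics cartridge, trim liquid, counterweight, PETG hull).
#' The bulk densities behind the fixed masses are placeholders, not
#' measured values.
#'
#' @param displaced_mass displaced mass, g.
#' @param target_M target total center of mass (cm).
#' @return A [mass_budget()].
#' @export
demo_mass_budget <- function(displaced_mass = 982,
                             target_M = c(0, 0, -0.5)) {
  comps <- list(
    mass_component("motor", mass = 40, center = c(2.5, 0, -2)),
    mass_component("battery_7v4", mass = 48, center = c(-1.5, 1, 0.5)),
    mass_component("battery_3v7", mass = 12, center = c(-1.5, -1, 0.5)),
    mass_component("electronics", mass = 25, center = c(-2, 0, 1.5)),
    mass_component("counterweight_bismuth", mass = 120,
                   center = c(0.3, 0, -4.5)),
    mass_component("trim_liquid", mass = 9, center = c(1, 0, -1)),
    mass_component("rubber_valve", mass = 3, center = c(0, 2, 0)))
  mass_budget(comps, displaced_mass = displaced_mass, target_M = target_M)
}
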
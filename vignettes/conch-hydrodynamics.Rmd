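---
title: "Hydrostatics and jet-propulsion hydrodynamics of planispiral conchs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrostatics and jet-propulsion hydrodynamics of planispiral conchs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conchydro)
```

## The scientific problem

Externally shelled cephalopods (ammonoids and nautiloids) carried a chambered
phragmocone that made them close to neutrally buoyant, and moved by jetting
water through a hyponome. Their conch geometry — how fast the whorl expands,
how much of the earlier whorls stays exposed at the umbilicus, and how
inflated the whorl section is — set the physics they lived with: drag while
jetting backwards, hydrostatic stability (the righting moment that keeps the
aperture where the animal needs it), and the ease of turning about the
vertical axis. Compressed, streamlined conchs coast efficiently but resist
yaw; inflated, sphere-like conchs spin easily but stall quickly. conchydro
implements the complete computational chain for quantifying that tradeoff:
conch generation, mesh hydrostatics, robot mass budgets, a rigid-body
jet-propulsion simulator, kinematic analysis, drag estimation, and group
statistics.

## Conch generation

A theoretical planispiral conch is a whorl section swept along a logarithmic
spiral. `conch_spec()` parameterizes:

* `expansion_per_rev` (`W`) — venter radius multiplier per 360 degrees; the
  venter radius is `r0 * W^(theta/360)` (piecewise ontogeny integrates
  `log W` exactly over the spiral angle).
* `umbilical_exposure` (`u`) — the dorsal margin of each section sits at
  radius `u * r_venter`. Whorls just touch at `u = 1/W`; smaller values wrap
  the section over earlier whorls (involute conchs). The overlapping part of
  a section is conformed to the outer boundary of the whorl one (or more)
  revolutions back in the same radial plane — which is exactly the shared
  dorsal wall of a real shell — so swept solids never self-intersect. A tiny
  separation (1e-4 of the venter radius) keeps conformed walls numerically
  distinct. If conforming leaves less than four wall thicknesses of whorl
  height, generation stops with an error rather than emitting a degenerate
  tube.
* `inflation` — section breadth over height; the default section is a
  superellipse of exponent 2.5 (configurable; digitized polylines are
  accepted and validated against self-intersection).
* wall and septum thicknesses — 3.1% and 2.1% of *inner* whorl height,
  measured caliper ratios from *Nautilus pompilius*; the wall offset solves
  `t = ratio * h_inner` with `h_inner = h - 2t` exactly.
* `septal_spacing_deg` — 23 degrees, the rounded mean adult septal spacing
  of *N. pompilius*.

The key structural decision is that **every hydrostatic component is a
partition of the same swept solid**. The displaced-water envelope is the
outer sweep; the shell wall is the outer sweep plus the inverted inner
sweep; septa are thin angular slabs of the inner tube; chambers are the
inner tube between septa; the soft body is the inner tube adapertural of the
final septum. Because all components share ring-for-ring identical section
polygons, the conservation identity

> shell + septa + chambers + soft body = water displaced

holds by construction (to sweep-resolution differences of order 1e-6
relative), rather than depending on mesh boolean operations.

Two deliberate simplifications follow from this design:

* **Septa are flat swept slabs**, not domed caps morphed from a CT-scanned
  septum. Hydrostatically a septum contributes through its volume (thickness
  times section area) and its center; its curvature moves that center by a
  fraction of a chamber length and is far below the other approximations in
  play. Dropping concavity keeps the partition exact.
* **The soft body ends flush with the aperture plane** (no protruding head).
  This is a conservative soft-body estimate; a protrusion would add a few
  percent of soft-body volume just adapertural of the plane and would have
  to be added to the displaced envelope simultaneously, leaving the fill
  fraction nearly unchanged.

## Hydrostatics

Neutral buoyancy requires organismal mass to equal displaced mass. With the
default densities (soft body 1.049, shell 2.54, cameral liquid 1.025,
cameral gas 0.001, ambient water 1.025 g/cm^3) the chamber contents solve

```
Phi = ((V_wd rho_wd - V_sb rho_sb - V_sh rho_sh) / V_ct - rho_cl)
      / (rho_cg - rho_cl)
```

**Reading this formula matters.** Evaluated as written it is the *gas*
fraction of the chamber volume: if the residual chamber density equals the
liquid density, `Phi = 0`; if it equals the gas density, `Phi = 1`. The
quantity usually quoted as "percent cameral liquid" is the complement.
`chamber_fill_fraction()` returns both (`phi` and `liquid_fraction`,
summing to one exactly) plus the mass-balance residual, and every report in
the package states which reading it quotes. The formula is implemented
verbatim; no silent sign "fix" is applied.

`fit_body_chamber()` reproduces the body-chamber calibration: bisection on
the body-chamber angle until the equilibrium liquid fraction matches the
*Nautilus*-like target of 12% of chamber volume (tolerance 0.005). The
liquid fraction is monotone decreasing in the angle over the physical
bracket — a larger soft body is denser than the water it displaces, so more
gas is needed — which the tests verify by dense scan. The four demonstration
morphotypes ship with body-chamber angles fitted this way (serpenticone
225.9, oxycone 34.5, sphaerocone 267, center 218.6 degrees). The short
oxycone body chamber is a consequence of its strong expansion rate
concentrating volume at the aperture; real oxycone body chambers are short,
though not this short — the demo specs are qualitative morphotype stand-ins,
not reconstructions of figured specimens (whose per-segment array
parameters are not available).

Other quantities follow the standard definitions: the center of buoyancy is
the centroid of the displaced-water solid; the center of mass is the
mass-weighted mean over components, with chamber liquid and gas both placed
at the chamber-volume centroid (capillary retention spreads liquid around
the septal margins, making this a minor assumption); the stability index is
`St = |B - M| / V^(1/3)`, dimensionless and scale-free. Apertural and
thrust angles are measured after rotating the model so that B sits
vertically above M — the *minimal* such rotation, making the result
invariant to how the input model was oriented. Sign conventions: apertural
angle 0 faces horizontally, +90 up; thrust angle is the elevation of
hyponome-to-midpoint(B, M), 0 for ideal horizontal backward thrust, +90
when thrust transmits most efficiently into downward movement.

## Robot mass budgets

The robot build recipe is algebra on a component table: the printed-PETG
mass is displaced mass minus everything else
(`petg_mass_for_neutrality()`), and its center solves, per axis,

```
D_PETG = (M m_total - sum_fixed D_i m_i) / m_PETG
```

where the first term uses the **total** mass including the PETG and the sum
runs over fixed components only — the only non-circular reading of the
balance, verified by the round-trip property that the recomputed composite
center lands on the target to 1e-9 cm on randomized budgets. The bismuth
counterweight is placed on the vertical line through the composite center
(horizontal components preserved by construction) at the depth that yields
a requested stability index; an infeasible hull depth errors with the
maximum attainable St. The trim-liquid slot (~9 g, syringe-adjustable in
the physical robot) is an ordinary fixed component; its center shift when
partially drained is accepted as negligible, matching its few-gram share of
a ~1 kg budget. Component masses and bulk densities in
`demo_mass_budget()` are placeholders shaped like a real build list, not
measured values.

## The trial simulator

The simulator replaces pool experiments as the forward model, so every
analysis stage has ground truth. Linear trials integrate

```
(m + m_a) dv/dt = T(t) - 0.5 rho Cd A v^2
```

with an explicit RK4 at a 1 ms internal step (pulse boundaries land on step
edges, so step-halving converges below 1e-8 m), resampled to the 23.975
frames/s of the video record. Thrust is a plateau with exponential rise and
decay (time constant 50 ms, configurable; `tau = 0` gives an ideal square
pulse), normalized so the time-average over the 1 s pulse equals the
configured mean of 0.3 N — the conservative *Nautilus*-like jet. Yaw trials
integrate `Izz domega/dt = T(t) L - c_rot omega |omega|` with the thrust
torqued through the hyponome lever arm, counter-clockwise from above.

Tracking points ride rigidly on the body (inter-point distance constant to
1e-12 before noise), with superimposed pitch rocking (default 4 degrees at
0.8 Hz — the experiments report displacement generally within 5 degrees),
buoyancy-driven vertical drift at the quadratic-drag terminal speed of a
0.5 g residual weight, a seeded lateral ambient drift, and Gaussian
position noise of 2 mm per coordinate. The 2 mm default keeps the
reconstructed inter-point distance SD near 3 mm, under the 8.5 mm
calibration ceiling of the motion-capture record; the generator self-checks
this.

Added mass defaults to 0.5 of displaced mass for sphere-like bodies and 0.2
for compressed ones (configurable); no measured value exists, and the
approach treats it as constant over a trial.

### Morphotype parameter sets and the yaw calibration

`morphotype_params()` encodes the four ~1 kg, 15 cm-scale study bodies.
Translational drag coefficients are the reported robot values (serpenticone
~0.5, oxycone ~0.14, sphaerocone ~0.61, center ~0.5) with frontal areas
graded from the full 15 cm-sphere section down to 30% of it for the
oxycone. The rotational side has no published drag law, so quadratic yaw
drag is the declared stand-in, and its coefficients are the package's own
calibration chosen (analytically, before any trial was run) to sit in the
reported regime: the sphaerocone spins essentially freely (c_rot = 1e3
g cm^2) and exceeds three net revolutions on a one-second pulse, the
compressed morphotypes (c_rot = 3e5-3.5e5) stay under one revolution with
one-second angular velocities roughly an order of magnitude below the
vacuum value `tau t / Izz`, and the center is intermediate (2e4). One
reported feature cannot be reproduced jointly with these: a sphaerocone
peak angular velocity only ~5 times the oxycone's. Under any single
quadratic drag law, parameters that give the order-of-magnitude vacuum gap
and >3 revolutions force a peak-omega ratio nearer 10. The package keeps
the vacuum gap and the revolution contrast and accepts the looser peak
ratio; yaw oscillations from the robot meeting its own wake are explicitly
not modeled.

## Kinematics and statistics

Speeds use the midpoint of the two tracking points, differenced per frame;
the horizontal-only (2d) variant is the default reporting mode because
imperfect buoyancy contaminates the vertical channel. Acceleration is an
OLS slope of the 2d speed over the motor-on window. Rocking is the
tracking-pair angle from vertical minus its static value. Yaw unwraps the
horizontal bearing of the pair into a continuous net angle (so reversing
the frame order negates it exactly).

Two operationalizations are configurable because the experimental record
does not state them: peak velocity (and peak angular velocity) is the
maximum of a centered 5-frame moving average — the tracking points sit far
from the body center, so raw frame differences oscillate with rocking — and
"rest" is a speed below 1 cm/s sustained for 0.5 s. Raw series are always
retained.

Group comparison is a Welch heteroscedastic one-way ANOVA (the variant is
chosen to match the post hoc test's unequal-variance assumptions) followed
by Games-Howell pairwise comparisons: Welch t statistics,
Welch-Satterthwaite degrees of freedom, p-values from the
studentized-range distribution with `q = t sqrt(2)`. The implementation is
validated against an independent reference implementation on a frozen
dataset and holds its nominal 5% level in a 1000-replicate null Monte
Carlo. Below ~2 degrees of freedom the studentized-range quantile is
numerically unstable and the pairwise p-value falls back to the Welch t
test; with realistic trial counts (9-15 per group) this path is never
taken.

## Drag estimation

Coasting after a single pulse decays as `v(t) = v0 / (1 + k v0 t)`, the
exact solution of quadratic-drag coasting, with
`k = rho Cd A / (2 (m + m_a))`. `fit_drag_coefficient()` fits this curve to
the 2d speed series over the coasting window by nonlinear least squares on
`v` (not `log v`) and recovers `Cd` from `k`. Conventions the fit records
in its output, since the experimental account does not fix them: the
reference area is the motion-normal projected area of the displaced-water
body (`frontal_area()`, rasterized silhouette with an exact convex-body
alternative), and the effective mass includes a constant added-mass term.
Frames after the course bearing has rotated by more than 60 degrees are
refused — yaw late in a coast corrupts the deceleration record and tends to
overpredict the tail of the modeled curve. The window is asserted to start
after motor-off, so the thrust phase can never leak into the fit. On
noise-free synthetic coasting the recovery is unbiased within 2% across
the drag-coefficient and speed grid of the study.

## Numerical choices and problem sizes

* Degenerate faces below 1e-12 cm^2 are dropped (with a logged count)
  before integration; watertightness requires every edge in exactly two
  faces with opposite winding.
* Demo conchs default to 1-2 degree spiral steps and 40-point sections; the
  test suite uses 4-6 degree steps and 20-32-point sections, which leaves
  every identity it checks (partition conservation, mass balance,
  morphospace placement) unchanged while keeping a full run of the suite in
  the low minutes. The acceptance checks use 15 trials per group for the
  tradeoff comparison and 1000 Monte Carlo replicates for the test-level
  check.
* The equilibration rotation is the minimal rotation taking B - M to
  vertical, tie-broken as such; B = M raises an error (no defined
  equilibrium).
* Ternary morphospace normalization: the classic ternary diagram's exact
  normalization is adopted from the morphospace literature rather than
  restated in the experimental account, so the package documents its own
  default — `w = (W - 1)/2`, `u = (U/D)/0.6`, `th = (ab/ah)/2`, clamped to
  `[0, 1]` and normalized to sum to one, with the whorl expansion rate
  taken from the spiral when known and otherwise estimated from diameter
  and apertural height (capped at W = 3). Reference scales are arguments;
  under the defaults the four demo morphotypes land in their expected
  corner thirds and the center spec lands on (1/3, 1/3, 1/3).

## What passing tests do and do not show

The simulator is a rigid-body point model with quadratic drag: it contains
no wake, no Reynolds-number dependence of Cd, no added-mass variation with
velocity, and no coupling between yaw and translation. Recovery tests
(drag coefficients, rocking amplitude, yaw revolutions) therefore
demonstrate that the *analysis* chain is correct and unbiased against its
own forward model — they cannot certify the forward model against a real
pool. The same applies to the morphotype parameter sets: they reproduce the
reported qualitative regime (compressed coasts farther and faster; inflated
out-turns it by an order of magnitude; Games-Howell separates the groups),
not the reported numbers themselves, which came from physical trials whose
raw tracks are not available. Where the package had to choose between
mutually incompatible reported features of the yaw regime, the choice and
its reasoning are stated above rather than hidden in defaults.
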
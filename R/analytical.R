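#' Prosthesis loop geometry
#'
#' Describes the crimping loop of a stapes piston prosthesis as a (possibly
#' open) elastic ring around the lenticular process of the incus. All lengths
#' are millimetres; the package works throughout in the mm-MPa-N unit system
#' (1 MPa x 1 mm^2 = 1 N).
#'
#' @param inner_diameter Loop inner diameter (mm). Matches the incus
#'   lenticular-process diameter up to the radial interference.
#' @param outer_diameter Loop outer diameter (mm); must exceed
#'   `inner_diameter`.
#' @param band_width Axial width `w` of the loop band (mm).
#' @param coverage_angle Arc of the incus circumference in contact with the
#'   loop, in degrees; 360 is a closed ring, the complement is the crimping
#'   opening. Default 216 (coverage fraction 0.6), the value calibrated so
#'   the open-ring model reproduces the reference PTFE pressure table.
#' @param interference Radial interference `dr` (mm) between the free loop and
#'   the incus surface; default 2e-3 mm (2 micrometres).
#'
#' @return An object of class `ring_spec` with derived fields `thickness`
#'   (radial wall `t`), `mean_radius` (`rm`) and `inner_radius` (`ri`).
#' @examples
#' ring_spec(0.8, 1.2)
#' @export
ring_spec <- function(inner_diameter, outer_diameter, band_width = 0.4,
                      coverage_angle = 216, interference = 2e-3) {
  stopifnot(is.numeric(inner_diameter), is.numeric(outer_diameter),
            is.numeric(band_width), is.numeric(coverage_angle),
            is.numeric(interference))
  if (!(inner_diameter > 0))
    stop("invalid geometry: inner_diameter must be positive")
  if (!(outer_diameter > inner_diameter))
    stop("invalid geometry: outer_diameter must exceed inner_diameter")
  if (!(band_width > 0))
    stop("invalid geometry: band_width must be positive")
  if (!(coverage_angle > 0 && coverage_angle <= 360))
    stop("domain error: coverage_angle must lie in (0, 360] degrees")
  if (interference < 0)
    stop("invalid geometry: interference must be non-negative")
  out <- list(
    inner_diameter = inner_diameter,
    outer_diameter = outer_diameter,
    band_width = band_width,
    coverage_angle = coverage_angle,
    interference = interference,
    thickness = (outer_diameter - inner_diameter) / 2,
    mean_radius = (inner_diameter + outer_diameter) / 4,
    inner_radius = inner_diameter / 2
  )
  class(out) <- "ring_spec"
  out
}

#' @export
print.ring_spec <- function(x, ...) {
  cat(sprintf(
    "Loop ring: ID %.3f mm, OD %.3f mm (t = %.3f mm), w = %.3f mm\n",
    x$inner_diameter, x$outer_diameter, x$thickness, x$band_width))
  cat(sprintf("  coverage %g deg, interference %.4g mm\n",
              x$coverage_angle, x$interference))
  invisible(x)
}

#' Linear-elastic material
#'
#' @param name Label, e.g. `"titanium"`.
#' @param youngs_modulus Young's modulus E in MPa.
#' @param poisson Poisson's ratio, in `[0, 0.5)`.
#' @param strength_limits Named numeric vector of strength limits in MPa
#'   (e.g. `c(von_mises = 60)` for cortical bone).
#' @return Object of class `material`.
#' @examples
#' material("PTFE", 500, 0.46, c(tensile = 25, compressive = 30))
#' @export
material <- function(name, youngs_modulus, poisson,
                     strength_limits = numeric()) {
  if (!(youngs_modulus > 0)) stop("youngs_modulus must be positive")
  if (!(poisson >= 0 && poisson < 0.5)) stop("poisson must lie in [0, 0.5)")
  out <- list(name = name, youngs_modulus = youngs_modulus, poisson = poisson,
              strength_limits = strength_limits)
  class(out) <- "material"
  out
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("Material %s: E = %g MPa, nu = %g\n",
              x$name, x$youngs_modulus, x$poisson))
  invisible(x)
}

#' Default materials of the incus-prosthesis model
#'
#' Titanium (E = 110 GPa, nu = 0.30), PTFE (E = 0.5 GPa, nu = 0.46, tensile
#' limit 25 MPa, compressive limit 30 MPa) and cortical bone (E = 14 GPa,
#' nu = 0.30, von Mises strength proxy 60 MPa), all linear elastic and
#' isotropic.
#'
#' @return A `material` object.
#' @name default_materials
NULL

#' @rdname default_materials
#' @export
mat_titanium <- function() material("titanium", 110e3, 0.30)

#' @rdname default_materials
#' @export
mat_ptfe <- function() {
  material("PTFE", 500, 0.46, c(tensile = 25, compressive = 30))
}

#' @rdname default_materials
#' @export
mat_cortical_bone <- function() {
  material("cortical_bone", 14e3, 0.30, c(von_mises = 60))
}

#' Closed-ring interference pressure
#'
#' Average interface pressure of a closed thick ring shrunk onto a rigid
#' cylinder with radial interference `dr`, from the thin/thick-ring reduction
#' of the Lame solution:
#' \deqn{p = \frac{E \, \Delta r}{r_m (r_m/t + \nu)}}
#' with `rm` the mean radius and `t` the radial wall thickness of the ring.
#'
#' @param ring A [ring_spec()].
#' @param mat A [material()] for the ring (the incus is treated as rigid at
#'   this stage; the FE model relaxes that).
#' @return Pressure in MPa. Strictly increasing in the interference and, at
#'   fixed inner diameter, in the wall thickness.
#' @examples
#' closed_ring_pressure(ring_spec(0.8, 1.2), mat_ptfe())
#' @export
closed_ring_pressure <- function(ring, mat) {
  stopifnot(inherits(ring, "ring_spec"), inherits(mat, "material"))
  if (!(ring$thickness > 0 && ring$mean_radius > 0))
    stop("invalid geometry: ring thickness and mean radius must be positive")
  mat$youngs_modulus * ring$interference /
    (ring$mean_radius * (ring$mean_radius / ring$thickness + mat$poisson))
}

#' Open-ring compliance factor
#'
#' Pressure-reduction factor of an open (split) ring relative to a closed one.
#' The circumferential stiffness of an open ring scales approximately with its
#' angular coverage, so the average interface pressure carries the factor
#' `theta/360`; the closed-to-open stiffness *ratio* is its inverse
#' `360/theta`. A closed ring (`theta = 360`) has factor exactly 1.
#'
#' @param coverage_angle Covered arc in degrees, in `(0, 360]`.
#' @return Dimensionless factor in `(0, 1]`.
#' @examples
#' compliance_factor(216) # 0.6
#' @export
compliance_factor <- function(coverage_angle) {
  if (!is.numeric(coverage_angle) ||
      any(!(coverage_angle > 0 & coverage_angle <= 360)))
    stop("domain error: coverage_angle must lie in (0, 360] degrees")
  coverage_angle / 360
}

#' Open-ring (loop) interface pressure
#'
#' Average pressure a split self-crimping loop exerts on the incus:
#' closed-ring pressure times the open-ring compliance factor.
#'
#' @inheritParams closed_ring_pressure
#' @return Pressure in MPa; never exceeds the closed-ring pressure.
#' @examples
#' open_ring_pressure(ring_spec(0.8, 1.2), mat_ptfe()) # ~0.405 MPa
#' @export
open_ring_pressure <- function(ring, mat) {
  closed_ring_pressure(ring, mat) * compliance_factor(ring$coverage_angle)
}

#' Contact length of the loop on the incus
#'
#' Arc length of the covered fraction of the incus circumference,
#' `Lc = (theta/360) * 2 pi ri`.
#'
#' @param ring A [ring_spec()].
#' @return Length in mm.
#' @export
contact_length <- function(ring) {
  stopifnot(inherits(ring, "ring_spec"))
  compliance_factor(ring$coverage_angle) * 2 * pi * ring$inner_radius
}

#' Contact area of the loop on the incus
#'
#' `Ac = w * Lc`, the band width times the covered arc length.
#'
#' @param ring A [ring_spec()].
#' @return Area in mm^2.
#' @export
contact_area <- function(ring) {
  stopifnot(inherits(ring, "ring_spec"))
  if (!(ring$band_width > 0))
    stop("invalid geometry: band_width must be positive")
  ring$band_width * contact_length(ring)
}

#' Mean contact pressure from a crimping force
#'
#' Inverts `F = p * Ac`: the average interface pressure produced when a
#' crimping force `F` is spread over the loop contact area.
#'
#' @param force Crimping force in N (1 mN = 0.001 N).
#' @param ring A [ring_spec()].
#' @return Pressure in MPa. Exact inverse of [force_from_pressure()].
#' @examples
#' pressure_from_force(0.3, ring_spec(0.8, 1.0, band_width = 0.2))
#' @export
pressure_from_force <- function(force, ring) {
  if (any(force < 0)) stop("force must be non-negative")
  ac <- contact_area(ring)
  if (!(ac > 0)) stop("degenerate geometry: zero contact area")
  force / ac
}

#' Crimping force from a mean contact pressure
#'
#' `F = p * Ac` in the mm-MPa-N system.
#'
#' @param pressure Mean interface pressure in MPa.
#' @param ring A [ring_spec()].
#' @return Force in N.
#' @export
force_from_pressure <- function(pressure, ring) {
  if (any(pressure < 0)) stop("pressure must be non-negative")
  pressure * contact_area(ring)
}

#' Full pressure/force budget of one loop configuration
#'
#' @inheritParams closed_ring_pressure
#' @return A one-row data frame with closed-ring pressure, compliance factor,
#'   loop pressure, contact length/area and the equivalent crimping force
#'   `F = ploop * Ac`.
#' @export
pressure_result <- function(ring, mat) {
  p <- closed_ring_pressure(ring, mat)
  phi <- compliance_factor(ring$coverage_angle)
  ploop <- p * phi
  lc <- contact_length(ring)
  ac <- contact_area(ring)
  data.frame(
    closed_ring_pressure = p, compliance_factor = phi,
    loop_pressure = ploop, contact_length = lc, contact_area = ac,
    force = ploop * ac
  )
}

#' Loop pressure table over outer diameters
#'
#' Evaluates the open-ring pressure model for a set of loop outer diameters at
#' fixed inner diameter, the self-crimping PTFE configuration sweep.
#'
#' @param outer_diameters Numeric vector of loop ODs (mm).
#' @param inner_diameter Loop ID (mm), default 0.8.
#' @param mat Ring [material()], default PTFE.
#' @param coverage_angle Covered arc (degrees), default 216.
#' @param interference Radial interference (mm), default 2e-3.
#' @param band_width Axial band width (mm), default 0.4.
#' @return Data frame with one row per OD: closed-ring and loop pressures
#'   (MPa) and the loop pressure rounded to 3 decimals.
#' @examples
#' pressure_table(c(1.2, 1.4, 1.8))
#' @export
pressure_table <- function(outer_diameters, inner_diameter = 0.8,
                           mat = mat_ptfe(), coverage_angle = 216,
                           interference = 2e-3, band_width = 0.4) {
  rows <- lapply(outer_diameters, function(od) {
    rg <- ring_spec(inner_diameter, od, band_width = band_width,
                    coverage_angle = coverage_angle,
                    interference = interference)
    data.frame(outer_diameter = od,
               closed_ring_pressure = closed_ring_pressure(rg, mat),
               loop_pressure = open_ring_pressure(rg, mat))
  })
  out <- do.call(rbind, rows)
  out$loop_pressure_rounded <- round(out$loop_pressure, 3)
  out
}
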
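#' Bundle geometry
#'
#' Describes one suspended DNA bundle: its length and diameter in the
#' circular idealization, plus optional major/minor diameters of an
#' elliptical cross section used for mode-splitting calculations. All
#' lengths are SI metres.
#'
#' @param length Suspended length L in metres.
#' @param diameter Nominal diameter d in metres (circular idealization).
#' @param d_max,d_min Major and minor diameters of the elliptical cross
#'   section, in metres. Default to `diameter` (circular section).
#' @return An object of class `bundle_geometry` with fields `length`,
#'   `diameter`, `d_max`, `d_min` and derived `radius`, `area`
#'   (A = pi R^2) and `moment` (I = pi R^4 / 4).
#' @examples
#' g <- bundle_geometry(length = 12e-6, diameter = 100e-9)
#' g$area / (pi * (50e-9)^2)  # 1
#' @export
bundle_geometry <- function(length, diameter, d_max = diameter, d_min = diameter) {
  stopifnot(is.numeric(length), is.numeric(diameter),
            is.numeric(d_max), is.numeric(d_min))
  if (!is.finite(length) || length <= 0)
    stop("bundle length must be finite and positive (metres)")
  if (!is.finite(diameter) || diameter <= 0)
    stop("bundle diameter must be finite and positive (metres)")
  if (!is.finite(d_max) || !is.finite(d_min) || d_min <= 0 || d_min > d_max)
    stop("elliptical diameters must satisfy 0 < d_min <= d_max")
  r <- diameter / 2
  structure(list(
    length   = length,
    diameter = diameter,
    d_max    = d_max,
    d_min    = d_min,
    radius   = r,
    area     = pi * r^2,
    moment   = pi * r^4 / 4
  ), class = "bundle_geometry")
}

#' Material state of a bundle
#'
#' Effective elastic and inertial parameters of the bundle material under
#' one experimental condition, in SI units.
#'
#' @param young_modulus Effective Young's modulus E in Pa.
#' @param density Mass density rho in kg m^-3 (1700 for pristine DNA,
#'   about 1500 for intercalated DNA).
#' @param axial_stress Axial tensile stress sigma in Pa; defaults to 0
#'   (the suspension process leaves tensile stress negligibly small).
#' @return An object of class `material_state`.
#' @export
material_state <- function(young_modulus, density, axial_stress = 0) {
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stop("young_modulus must be finite and positive (Pa)")
  if (!is.finite(density) || density <= 0)
    stop("density must be finite and positive (kg m^-3)")
  if (!is.finite(axial_stress) || axial_stress < 0)
    stop("axial_stress must be finite and non-negative (Pa)")
  structure(list(
    young_modulus = young_modulus,
    density       = density,
    axial_stress  = axial_stress
  ), class = "material_state")
}

is_circular <- function(geometry) {
  isTRUE(all.equal(geometry$d_max, geometry$d_min, tolerance = 0))
}

#' Resonator mass
#'
#' Mass of the circular-cylinder idealization of the bundle,
#' m = rho * pi * R^2 * L.
#'
#' @param geometry A [bundle_geometry()].
#' @param material A [material_state()].
#' @return Mass in kg.
#' @examples
#' g <- bundle_geometry(10e-6, 100e-9)
#' s <- material_state(5.3e9, 1700)
#' kg_to_ag(mass_of_bundle(g, s))  # ~1.34e5 ag
#' @export
mass_of_bundle <- function(geometry, material) {
  material$density * geometry$area * geometry$length
}

#' @rdname unit_conversions
#' @export
kg_to_ag <- function(kg) kg * 1e21

#' Unit conversions used at presentation boundaries
#'
#' All internal computation is strictly SI; attograms, GPa and Hz/ag appear
#' only when reporting. 1 ag = 1e-21 kg.
#'
#' @param kg,ag,pa,hz_per_kg Values in the units named by the argument.
#' @return The converted value.
#' @name unit_conversions
#' @export
ag_to_kg <- function(ag) ag * 1e-21

#' @rdname unit_conversions
#' @export
pa_to_gpa <- function(pa) pa / 1e9

#' @rdname unit_conversions
#' @export
hz_per_kg_to_hz_per_ag <- function(hz_per_kg) hz_per_kg * 1e-21
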
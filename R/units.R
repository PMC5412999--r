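# Unit conversions between areal surface densities (umol/m2) and molar
# concentrations (mol/L or mmol/L), plus the Gibbs free-energy helper.

GAS_CONSTANT <- 8.31446261815324 # J / (mol K)

#' Suspension geometry
#'
#' The specific surface area of the solid and its suspension concentration
#' together set the conversion between areal surface densities (µmol m⁻²)
#' and volumetric concentrations (mol L⁻¹): their product is the total
#' surface area per litre of suspension.
#'
#' @param surface_area Specific surface area of the solid, m² g⁻¹.
#' @param solids_conc Suspended-solid concentration, g L⁻¹.
#' @return An object of class `iex_geometry`.
#' @examples
#' goethite <- iex_geometry(surface_area = 29.50, solids_conc = 3.43)
#' site_capacity_molar(4.4, goethite)
#' @export
iex_geometry <- function(surface_area, solids_conc) {
  assert_positive(surface_area, "surface_area")
  assert_positive(solids_conc, "solids_conc")
  structure(list(surface_area = surface_area, solids_conc = solids_conc),
            class = "iex_geometry")
}

#' @export
print.iex_geometry <- function(x, ...) {
  cat(sprintf("<iex_geometry> %.4g m2/g x %.4g g/L = %.4g m2/L\n",
              x$surface_area, x$solids_conc, area_per_litre(x)))
  invisible(x)
}

area_per_litre <- function(geometry) {
  stopifnot(inherits(geometry, "iex_geometry"))
  geometry$surface_area * geometry$solids_conc # m2 / L
}

#' Convert a site density to a molar capacity (and back)
#'
#' `site_capacity_molar()` converts an areal site density Γ_max (µmol m⁻²)
#' to the equivalent molar capacity (mmol L⁻¹) of the suspension;
#' `site_capacity_areal()` is its exact inverse.
#'
#' @param gamma_max Site density, µmol m⁻² (≥ 0).
#' @param capacity Molar site capacity, mmol L⁻¹ (≥ 0).
#' @param geometry An [iex_geometry()].
#' @return A numeric vector in mmol L⁻¹ (resp. µmol m⁻²).
#' @examples
#' g <- iex_geometry(100, 1) # 100 m2/L effective loading
#' site_capacity_molar(2.0, g) # 0.2 mmol/L
#' @export
site_capacity_molar <- function(gamma_max, geometry) {
  assert_nonnegative(gamma_max, "gamma_max")
  gamma_max * area_per_litre(geometry) / 1000
}

#' @rdname site_capacity_molar
#' @export
site_capacity_areal <- function(capacity, geometry) {
  assert_nonnegative(capacity, "capacity")
  capacity * 1000 / area_per_litre(geometry)
}

# mol/L <-> umol/m2 (internal, used by the solver)
gamma_to_molar <- function(gamma, geometry) gamma * 1e-6 * area_per_litre(geometry)
molar_to_gamma <- function(conc, geometry) conc * 1e6 / area_per_litre(geometry)

#' Gibbs free energy of an exchange reaction
#'
#' ΔG° = −RT ln K = RT ln(10) · pK, reported in kJ mol⁻¹.  A negative pK
#' (large K) therefore gives a negative, favourable ΔG°.
#'
#' @param pK −log10 of the equilibrium constant (concentration basis).
#' @param temperature Absolute temperature, K (default 293.15 K = 20 °C).
#' @return ΔG° in kJ mol⁻¹.
#' @examples
#' gibbs_free_energy(-18.72) # about -105 kJ/mol
#' @export
gibbs_free_energy <- function(pK, temperature = 293.15) {
  assert_positive(temperature, "temperature")
  GAS_CONSTANT * temperature * log(10) * pK / 1000
}
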
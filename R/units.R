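## Physical constants (CODATA; kB in kcal/mol/K, e exact SI).
.kB_kcal <- 1.987204259e-3
.e_coulomb <- 1.602176634e-19

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in Kelvin. Default 310 K, the
#'   physiological temperature at which the channel simulations that this
#'   package targets are thermostatted (kT = 0.616 kcal/mol).
#' @return kT in kcal/mol.
#' @examples
#' kT_kcal(310)
#' @export
kT_kcal <- function(temperature = 310) .kB_kcal * temperature

#' Unit converters
#'
#' The package works in Angstrom / picosecond / kcal/mol; Gromacs-style
#' inputs are nm and kJ/mol. These helpers convert between the two.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name unit-converters
#' @examples
#' nm_to_angstrom(1.45)   # 14.5 A
#' kj_to_kcal(4.184)      # 1 kcal/mol
NULL

#' @rdname unit-converters
#' @export
nm_to_angstrom <- function(x) x * 10

#' @rdname unit-converters
#' @export
angstrom_to_nm <- function(x) x / 10

#' @rdname unit-converters
#' @export
kj_to_kcal <- function(x) x / 4.184

#' @rdname unit-converters
#' @export
kcal_to_kj <- function(x) x * 4.184
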
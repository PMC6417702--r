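# Physical constants (CODATA 2018, SI). g = 2 is used for organic radicals
# throughout; with these values g*mu_B/h = 27.99 MHz/mT.
.const <- list(
  mu_B = 9.2740100783e-24, # Bohr magneton, J/T
  hbar = 1.054571817e-34,  # reduced Planck constant, J s
  h    = 6.62607015e-34,   # Planck constant, J s
  k_B  = 1.380649e-23,     # Boltzmann constant, J/K
  eV   = 1.602176634e-19,  # electron volt, J
  mu_0 = 4 * pi * 1e-7     # vacuum permeability, T^2 m^3 / J
)

#' Electron gyromagnetic ratio
#'
#' Returns `g * mu_B / hbar`, the conversion factor between magnetic field and
#' angular frequency. All Hamiltonians in the package are expressed in angular
#' frequency units (rad/s), i.e. divided by hbar, so a field-like coupling of
#' `a` millitesla enters a Hamiltonian as `gyromagnetic(g) * a * 1e-3`.
#'
#' @param g dimensionless Lande g-factor (default 2, organic radicals).
#' @return scalar, rad s^-1 T^-1.
#' @export
gyromagnetic <- function(g = 2) g * .const$mu_B / .const$hbar

# field-like coupling (mT or uT) -> angular frequency (rad/s)
omega_from_mT <- function(a_mT, g = 2) gyromagnetic(g) * a_mT * 1e-3
omega_from_uT <- function(B_uT, g = 2) gyromagnetic(g) * B_uT * 1e-6

# cycles (MHz) <-> angular frequency (rad/s)
omega_from_MHz <- function(nu_MHz) 2 * pi * nu_MHz * 1e6
MHz_from_omega <- function(omega) omega / (2 * pi * 1e6)

#' Larmor precession frequency of a free electron
#'
#' `g * mu_B * B0 / h` in MHz: the resonance frequency of an unpaired electron
#' with no hyperfine interactions (e.g. superoxide) in a static field `B0`.
#' At B0 = 50 uT and g = 2 this is 1.4 MHz.
#'
#' @param B0_uT static field in microtesla.
#' @param g g-factor (default 2).
#' @return frequency in MHz.
#' @export
larmor_frequency <- function(B0_uT, g = 2) {
  g * .const$mu_B * B0_uT * 1e-6 / .const$h / 1e6
}
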
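# Screening workflow: characteristic-time calculators and the go/no-go gates
# that decide whether an RF magnetic-field effect on a radical-pair reaction
# is possible at all.

#' Characteristic RF interaction time
#'
#' `tau_RF = 2 pi hbar / (g mu_B B1)`: the time the RF field needs to act on
#' the electron spins. It depends only on the field strength, not on frequency
#' or polarization. At B1 = 50 uT and g = 2, tau_RF = 714 ns. If
#' `tau_RF >> tau_0` (radical-pair lifetime) the field cannot act before the
#' pair has reacted and any RF effect is excluded.
#'
#' @param B1_uT RF amplitude, microtesla.
#' @param g g-factor (default 2).
#' @return time in seconds (`Inf` when `B1 = 0`).
#' @export
tau_rf <- function(B1_uT, g = 2) {
  stopifnot(B1_uT >= 0)
  if (B1_uT == 0) return(Inf)
  2 * pi * .const$hbar / (g * .const$mu_B * B1_uT * 1e-6)
}

#' Marcus electron-transfer rate constant
#'
#' `k = (2 pi / hbar) |V_ab|^2 (4 pi lambda k_B T)^(-1/2)
#'      exp(-(dG + lambda)^2 / (4 lambda k_B T))`,
#' the non-adiabatic Marcus rate for a charge-transfer step creating or
#' destroying a radical pair. Maximal (activationless) at `dG = -lambda` and
#' symmetric about that point.
#'
#' @param V_ab_eV transition matrix element, eV.
#' @param delta_G_eV free-energy change of the transfer, eV.
#' @param lambda_eV reorganization energy, eV (> 0).
#' @param temperature_K temperature, K (> 0).
#' @return rate constant, s^-1.
#' @export
marcus_rate <- function(V_ab_eV, delta_G_eV, lambda_eV, temperature_K = 300) {
  stopifnot(lambda_eV > 0, temperature_K > 0)
  V <- V_ab_eV * .const$eV
  dG <- delta_G_eV * .const$eV
  lam <- lambda_eV * .const$eV
  kBT <- .const$k_B * temperature_K
  (2 * pi / .const$hbar) * V^2 / sqrt(4 * pi * lam * kBT) *
    exp(-(dG + lam)^2 / (4 * lam * kBT))
}

#' Escape rate from the binding time
#'
#' `k_e = 1/tau_b`: the rate at which one radical diffuses away, ending the
#' radical-pair stage.
#'
#' @param tau_b_s binding time, s (> 0).
#' @return rate constant, s^-1.
#' @export
escape_rate <- function(tau_b_s) {
  stopifnot(tau_b_s > 0)
  1 / tau_b_s
}

#' Order-of-magnitude singlet-triplet mixing rate
#'
#' `k_mix ~ g mu_B a / (2 pi hbar)` for a typical hyperfine coupling `a`:
#' about 28 us^-1 at a = 1 mT. Used as a guess for the interconversion rate
#' when nothing else is known.
#'
#' @param a_mT typical hyperfine coupling, mT (> 0).
#' @param g g-factor (default 2).
#' @return rate in s^-1.
#' @export
kmix_estimate <- function(a_mT, g = 2) {
  stopifnot(a_mT > 0)
  omega_from_mT(a_mT, g) / (2 * pi)
}

#' Radical-pair lifetime estimate
#'
#' If the fastest reaction channel is reachable from the initial spin state
#' (or is spin-independent), the lifetime is `1/k_fast`. If the pair is born
#' in a state whose own channel is slow and must interconvert first, the
#' singlet-triplet mixing rate gates the decay and `tau_0 ~ 1/k_mix`.
#'
#' @param rates a [rate_set()].
#' @param kmix singlet-triplet interconversion rate, s^-1 (see
#'   [kmix_estimate()]).
#' @param initial_state_reacts does the fastest channel react from the initial
#'   state? Default: the pair is singlet-born, so TRUE when `kS >= kT` or when
#'   both channels are open (`kS > 0`).
#' @return lifetime tau_0 in seconds.
#' @export
lifetime_estimate <- function(rates, kmix = NULL,
                              initial_state_reacts = rates$kS > 0) {
  k_fast <- max(rates$kS, rates$kT)
  if (k_fast <= 0) stop("at least one rate constant must be > 0")
  if (initial_state_reacts) return(1 / k_fast)
  if (is.null(kmix)) stop("kmix is required when the fast channel is not ",
                          "reachable from the initial state")
  1 / kmix
}

#' RF-effect screening verdict
#'
#' Applies the decision gates of the screening workflow, in order:
#' \enumerate{
#'   \item `tau_RF > F * tau_0` -> `RF_TOO_WEAK` (field has no time to act);
#'   \item `tau_R < tau_0 / F` (if a relaxation time is supplied) ->
#'     `RELAXATION_TOO_FAST` (thermal equilibrium before the field matters);
#'   \item distance from `nu_RF` to the nearest catalog resonance exceeds
#'     `dnu_tol` -> `OFF_RESONANCE`;
#'   \item exchange field-equivalent `eta` exceeding the largest hyperfine
#'     coupling -> `EXCHANGE_SUPPRESSED` (singlet-triplet mixing blocked).
#' }
#' The verdict is "possible" iff no gate fires. The "much greater" factor `F`
#' and the resonance tolerance are engineering defaults (the underlying
#' inequalities are asymptotic) and can be overridden.
#'
#' @param tau_0 radical-pair lifetime, s.
#' @param tau_RF RF interaction time, s (see [tau_rf()]).
#' @param nu_rf_MHz RF frequency under consideration, MHz (optional; gate 3
#'   is skipped when missing).
#' @param resonances a [resonance_catalog()] (optional; needed for gate 3).
#' @param tau_R spin-relaxation time, s (optional; user-supplied, gate 2).
#' @param eta_mT exchange field equivalent, mT.
#' @param a_max_mT largest hyperfine coupling, mT.
#' @param factor the "much greater than" factor F (default 10).
#' @param dnu_tol_MHz resonance-match tolerance; the default
#'   `max(1, 2 (1/(pi tau_0) + 1/tau_RF) 1e-6)` MHz combines the
#'   lifetime-broadening width `k/pi` with the drive (power-broadening) width
#'   `1/tau_RF`: a Lorentzian line falls below roughly a tenth of its peak
#'   beyond ~1.5 FWHM from the center, and the factor 2 adds margin for the
#'   Zeeman-split multiplet structure around each hyperfine feature.
#' @return a `workflow_report` list: `timescales`, `verdict`
#'   ("possible"/"excluded"), `reasons` (character vector of gate codes, empty
#'   when possible), `nearest_resonance_MHz`.
#' @export
rf_verdict <- function(tau_0, tau_RF, nu_rf_MHz = NULL, resonances = NULL,
                       tau_R = NULL, eta_mT = 0, a_max_mT = Inf,
                       factor = 10, dnu_tol_MHz = NULL) {
  if (missing(tau_0) || missing(tau_RF) || !is.finite(tau_0)) {
    stop("tau_0 and tau_RF are required")
  }
  if (is.null(dnu_tol_MHz)) {
    rf_width <- if (is.finite(tau_RF)) 1 / tau_RF else 0
    dnu_tol_MHz <- max(1, 2 * (1 / (pi * tau_0) + rf_width) / 1e6)
  }
  reasons <- character(0)
  if (tau_RF > factor * tau_0) reasons <- c(reasons, "RF_TOO_WEAK")
  if (!is.null(tau_R) && tau_R < tau_0 / factor) {
    reasons <- c(reasons, "RELAXATION_TOO_FAST")
  }
  nearest <- NA_real_
  if (!is.null(nu_rf_MHz) && !is.null(resonances)) {
    gap <- abs(abs(resonances$freq_MHz) - nu_rf_MHz)
    nearest <- abs(resonances$freq_MHz)[which.min(gap)]
    if (min(gap) > dnu_tol_MHz) reasons <- c(reasons, "OFF_RESONANCE")
  }
  if (is.finite(a_max_mT) && eta_mT > a_max_mT) {
    reasons <- c(reasons, "EXCHANGE_SUPPRESSED")
  }
  structure(list(
    timescales = list(tau_0 = tau_0, tau_RF = tau_RF, tau_R = tau_R),
    nu_rf_MHz = if (is.null(nu_rf_MHz)) NA_real_ else nu_rf_MHz,
    nearest_resonance_MHz = nearest,
    dnu_tol_MHz = dnu_tol_MHz,
    factor = factor,
    verdict = if (length(reasons) == 0) "possible" else "excluded",
    reasons = reasons
  ), class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("RF-effect screening report\n")
  ts <- x$timescales
  cat(sprintf("  tau_0  = %.4g s\n  tau_RF = %.4g s\n", ts$tau_0, ts$tau_RF))
  if (!is.null(ts$tau_R)) cat(sprintf("  tau_R  = %.4g s\n", ts$tau_R))
  if (!is.na(x$nu_rf_MHz)) {
    cat(sprintf("  nu_RF = %.3g MHz (nearest resonance %.3g MHz, tol %.3g MHz)\n",
                x$nu_rf_MHz, x$nearest_resonance_MHz, x$dnu_tol_MHz))
  }
  cat("  verdict:", x$verdict)
  if (length(x$reasons)) cat("  [", paste(x$reasons, collapse = ", "), "]")
  cat("\n  (thresholds use the configurable 'much greater than' factor F =",
      x$factor, ")\n")
  invisible(x)
}

#' Full screening report for a configured system
#'
#' Convenience wrapper: computes `tau_RF` from the field configuration, the
#' lifetime from the rates, the resonance catalog from the `B1 = 0` spin
#' Hamiltonian, and applies [rf_verdict()].
#'
#' @param system a [spin_system()].
#' @param fields a [field_config()] (its `nu_MHz` is the frequency screened).
#' @param rates a [rate_set()].
#' @param tau_R optional spin-relaxation time, s.
#' @param ... passed to [rf_verdict()].
#' @return a `workflow_report`.
#' @export
workflow_report <- function(system, fields, rates, tau_R = NULL, ...) {
  a_all <- vapply(system$nuclei, `[[`, numeric(1), "a_mT")
  kmix <- if (length(a_all)) kmix_estimate(max(abs(a_all))) else NULL
  tau_0 <- lifetime_estimate(rates, kmix)
  H0 <- total_hamiltonian(system, field_config(fields$B0_uT, 0, 0))
  cat_res <- resonance_catalog(H0)
  rf_verdict(tau_0 = tau_0, tau_RF = tau_rf(fields$B1_uT),
             nu_rf_MHz = fields$nu_MHz, resonances = cat_res, tau_R = tau_R,
             eta_mT = system$eta_mT,
             a_max_mT = if (length(a_all)) max(abs(a_all)) else Inf, ...)
}
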
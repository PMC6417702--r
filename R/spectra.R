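# RF action spectra, frequency-amplitude maps, resonance catalogs and peak
# diagnostics.

#' RF action spectrum
#'
#' Singlet-product probability change `delta_phi_S(nu) = <Phi_S>(B1, nu) -
#' <Phi_S>(B1 = 0)` on a grid of RF frequencies at fixed amplitude `B1`. The
#' `nu = 0` point is well defined: the RF term then acts as a static transverse
#' field, so the change is generally non-zero there. The baseline `<Phi_S>(B1
#' = 0)` is computed once and cached in the result's attributes.
#'
#' @param system a [spin_system()] (isotropic internals).
#' @param rates a [rate_set()].
#' @param B0_uT static field, microtesla.
#' @param B1_uT RF amplitude, microtesla.
#' @param nu_MHz strictly increasing frequency grid in MHz
#'   (default 0 to 50 MHz in 0.1 MHz steps).
#' @param solver passed to [singlet_yield()].
#' @return data.frame of class `action_spectrum` with columns `nu_MHz`,
#'   `B1_uT`, `delta_phi_S`; attributes `phi_S0`, `B0_uT`, `rates`.
#' @export
action_spectrum <- function(system, rates, B0_uT, B1_uT,
                            nu_MHz = seq(0, 50, by = 0.1), solver = "auto") {
  stopifnot(length(nu_MHz) >= 1, !is.unsorted(nu_MHz, strictly = TRUE))
  phi0 <- singlet_yield(system, field_config(B0_uT, 0, 0), rates,
                        solver = solver)$phi_S
  delta <- vapply(nu_MHz, function(nu) {
    singlet_yield(system, field_config(B0_uT, B1_uT, nu), rates,
                  solver = solver)$phi_S - phi0
  }, numeric(1))
  out <- data.frame(nu_MHz = nu_MHz, B1_uT = B1_uT, delta_phi_S = delta)
  attr(out, "phi_S0") <- phi0
  attr(out, "B0_uT") <- B0_uT
  attr(out, "rates") <- unclass(rates)
  class(out) <- c("action_spectrum", "data.frame")
  out
}

#' Frequency-amplitude action map
#'
#' Stack of [action_spectrum()] slices over a grid of RF amplitudes; each
#' fixed-B1 slice is identical to the corresponding 1-D spectrum.
#'
#' @inheritParams action_spectrum
#' @param B1_grid vector of RF amplitudes in microtesla.
#' @return `action_spectrum` data.frame with one block per B1 value.
#' @export
field_frequency_map <- function(system, rates, B0_uT, B1_grid,
                                nu_MHz = seq(0, 50, by = 0.1), solver = "auto") {
  slices <- lapply(B1_grid, function(b1) {
    action_spectrum(system, rates, B0_uT, b1, nu_MHz, solver)
  })
  out <- do.call(rbind, lapply(slices, as.data.frame))
  attr(out, "phi_S0") <- attr(slices[[1]], "phi_S0")
  attr(out, "B0_uT") <- B0_uT
  attr(out, "rates") <- unclass(rates)
  class(out) <- c("action_spectrum", "data.frame")
  out
}

#' Resonance-frequency catalog of a spin Hamiltonian
#'
#' All pairwise eigenvalue differences `(E_i - E_j)/h` for `i != j` of a
#' time-independent (B1 = 0) Hamiltonian: the complete spectrum of RF
#' frequencies that can drive transitions in the spin system. For `n`
#' eigenvalues there are `n(n-1)` ordered-pair differences (each unordered
#' pair contributes one positive and one negative entry); exact degeneracies
#' produce zero differences which are counted separately.
#'
#' @param H Hermitian Hamiltonian in rad/s.
#' @param bin_MHz histogram bin width in MHz (default 1).
#' @param range_MHz histogram range for |difference| (default 0-60 MHz).
#' @return a `resonance_catalog` list: `freq_MHz` (signed, length n(n-1)),
#'   `histogram` (bin_lo, bin_hi, count over the magnitudes), `n_ordered`,
#'   `n_unordered`, `n_zero`.
#' @export
resonance_catalog <- function(H, bin_MHz = 1, range_MHz = c(0, 60)) {
  assert_hermitian(H, "Hamiltonian")
  ev <- MHz_from_omega(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  n <- length(ev)
  d <- outer(ev, ev, "-")
  freq <- d[row(d) != col(d)]
  mags <- abs(freq)
  edges <- seq(range_MHz[1], range_MHz[2], by = bin_MHz)
  # exact degeneracies (zero differences) are counted separately, not binned
  counts <- as.vector(table(cut(mags[mags > 0], breaks = edges, right = FALSE)))
  structure(list(
    freq_MHz = freq,
    histogram = data.frame(bin_lo = edges[-length(edges)],
                           bin_hi = edges[-1], count = counts),
    n_ordered = as.integer(n * (n - 1)),
    n_unordered = as.integer(n * (n - 1) / 2),
    n_zero = sum(mags == 0)
  ), class = "resonance_catalog")
}

#' @export
print.resonance_catalog <- function(x, ...) {
  cat("Resonance catalog:", x$n_ordered, "ordered-pair frequencies (",
      x$n_unordered, "unordered );", x$n_zero, "exact degeneracies\n")
  nz <- sort(unique(round(abs(x$freq_MHz[abs(x$freq_MHz) > 1e-9]), 3)))
  cat("  distinct |frequencies| (MHz):",
      paste(utils::head(nz, 12), collapse = ", "),
      if (length(nz) > 12) "..." else "", "\n")
  invisible(x)
}

#' Locate the extremal feature of an action spectrum
#'
#' Grid frequency with the largest `|delta_phi_S|` inside a window; ties are
#' broken toward the lower frequency.
#'
#' @param spectrum an [action_spectrum()] (single B1 slice).
#' @param window numeric length-2 MHz interval.
#' @return frequency in MHz.
#' @export
peak_locate <- function(spectrum, window) {
  stopifnot(length(window) == 2)
  df <- as.data.frame(spectrum)
  if (length(unique(df$B1_uT)) > 1) {
    stop("spectrum has multiple B1 slices; subset to one before peak_locate()")
  }
  df <- df[df$nu_MHz >= window[1] & df$nu_MHz <= window[2], ]
  if (nrow(df) == 0) stop("window [", window[1], ", ", window[2],
                          "] MHz does not overlap the spectrum grid")
  a <- abs(df$delta_phi_S)
  cand <- which(a == max(a))
  df$nu_MHz[cand[which.min(df$nu_MHz[cand])]]
}

#' Lorentzian linewidth (FWHM) of a spectral feature
#'
#' Least-squares Lorentzian fit `delta(nu) = A / (1 + ((nu - nu0)/(w/2))^2) + c`
#' in a window around an isolated peak; returns the full width at half maximum
#' `w`. For a well-isolated resonance of a radical pair with equal rate
#' constants `k`, lifetime broadening gives `w ~ k/pi` Hz.
#'
#' @param spectrum an [action_spectrum()].
#' @param peak_nu peak position in MHz (e.g. from [peak_locate()]).
#' @param halfwidth_MHz fit window half-width (default 2 MHz).
#' @return FWHM in MHz, with the fit stored in attribute `fit`.
#' @export
peak_width <- function(spectrum, peak_nu, halfwidth_MHz = 2) {
  df <- as.data.frame(spectrum)
  df <- df[abs(df$nu_MHz - peak_nu) <= halfwidth_MHz, ]
  if (nrow(df) < 5) stop("too few grid points around the peak for a fit")
  ipk <- which.min(abs(df$nu_MHz - peak_nu))
  A0 <- df$delta_phi_S[ipk]
  # initial width from the half-maximum crossings
  above <- abs(df$delta_phi_S) >= abs(A0) / 2
  w0 <- max(diff(range(df$nu_MHz[above])), 2 * median(diff(df$nu_MHz)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_phi_S ~ A / (1 + ((nu_MHz - nu0) / (w / 2))^2) + c0,
      data = df,
      start = list(A = A0, nu0 = peak_nu, w = w0, c0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("Lorentzian fit failed: ", conditionMessage(fit),
         "; residual scale of data: ", signif(stats::sd(df$delta_phi_S), 3))
  }
  w <- abs(unname(stats::coef(fit)["w"]))
  attr(w, "fit") <- fit
  w
}
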
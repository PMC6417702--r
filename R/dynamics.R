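# Density-operator evolution under the Liouville-von Neumann equation with
# Haberkorn reaction terms, and the quantum-yield solvers.

#' Spin-selective reaction rate constants
#'
#' @param kS singlet-channel rate constant, s^-1.
#' @param kT triplet-channel rate constant, s^-1.
#' @return a `rate_set` object.
#' @export
rate_set <- function(kS, kT = kS) {
  stopifnot(is.finite(kS), is.finite(kT), kS >= 0, kT >= 0)
  structure(list(kS = kS, kT = kT), class = "rate_set")
}

#' Initial density operator of a singlet-born radical pair
#'
#' `rho0 = P_S / Tr(P_S)`: the electron pair in the coherent singlet state,
#' nuclei maximally mixed. Unit trace and unit singlet probability at t = 0.
#'
#' @param system a [spin_system()].
#' @param projectors optional precomputed [projection_operators()].
#' @return complex density matrix on the full Hilbert space.
#' @export
initial_state <- function(system, projectors = projection_operators(system)) {
  P_S <- projectors$P_S
  P_S / Re(sum(diag(P_S)))
}

#' Liouvillian superoperator
#'
#' The linear map on vectorized density matrices implementing
#' `drho/dt = -i [H, rho] - (kS/2) {P_S, rho} - (kT/2) {P_T, rho}`
#' (H in rad/s). Column-major vectorization: `vec(A rho B) = (t(B) x A) vec(rho)`.
#'
#' @param H Hermitian Hamiltonian in rad/s.
#' @param rates a [rate_set()].
#' @param projectors singlet/triplet projectors from [projection_operators()].
#' @return dense complex matrix of dimension `nrow(H)^2`.
#' @export
liouvillian <- function(H, rates, projectors) {
  n <- nrow(H)
  id <- diag(n) + 0i
  L <- -1i * (kronecker(id, H) - kronecker(t(H), id))
  K <- (rates$kS / 2) * projectors$P_S + (rates$kT / 2) * projectors$P_T
  L - (kronecker(id, K) + kronecker(t(K), id))
}

# Stationary-solve yields from a time-independent Hamiltonian:
# A = integral of rho(t) dt solves L vec(A) = -vec(rho0), and
# Phi_X = k_X * Tr(P_X A). Exact for any kS, kT > 0.
yield_liouville_solve <- function(H, rates, projectors) {
  if (rates$kS == 0 && rates$kT == 0) {
    stop("both rate constants are zero: the Liouvillian is singular; ",
         "use propagate_lab_frame() for finite-time dynamics")
  }
  rho0 <- projectors$P_S / Re(sum(diag(projectors$P_S)))
  L <- liouvillian(H, rates, projectors)
  A <- matrix(solve(L, -as.vector(rho0)), nrow(H), nrow(H))
  phi_S <- rates$kS * Re(sum(diag(projectors$P_S %*% A)))
  phi_T <- rates$kT * Re(sum(diag(projectors$P_T %*% A)))
  list(phi_S = phi_S, phi_T = phi_T)
}

#' Singlet yield from the equal-rates spectral formula
#'
#' For `kS = kT = k` and a time-independent Hamiltonian the total singlet
#' yield has the closed form
#' `Phi_S = (1/Tr P_S) sum_{j,l} |<j|P_S|l>|^2 k^2 / (k^2 + (w_j - w_l)^2)`
#' over the eigenpairs of H. It avoids Liouville-space solves entirely (an
#' n^2-dimensional linear system becomes one n-dimensional Hermitian
#' eigendecomposition), which makes systems with thousands of spin states
#' tractable.
#'
#' @param system a [spin_system()] (used for the projectors).
#' @param H time-independent (rotating-frame) Hamiltonian, rad/s.
#' @param k common rate constant, s^-1 (> 0).
#' @param projectors optional precomputed projectors.
#' @return a `yield_result` list with `phi_S`, `phi_T`, `solver`.
#' @export
singlet_yield_equal_rates <- function(system, H, k,
                                      projectors = projection_operators(system)) {
  if (k <= 0) stop("k must be > 0")
  ed <- eigen(H, symmetric = TRUE)
  M <- Conj(t(ed$vectors)) %*% projectors$P_S %*% ed$vectors
  d <- outer(ed$values, ed$values, "-")
  phi_S <- sum(Mod(M)^2 * k^2 / (k^2 + d^2)) / Re(sum(diag(projectors$P_S)))
  structure(list(phi_S = phi_S, phi_T = 1 - phi_S,
                 solver = "spectral-equal-rates"), class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("Quantum yields (%s): Phi_S = %.6f, Phi_T = %.6f\n",
              x$solver, x$phi_S, x$phi_T))
  invisible(x)
}

#' Singlet and triplet quantum yields of a radical pair
#'
#' Computes `Phi_S = kS * integral_0^inf Tr(P_S rho(t)) dt` (and the triplet
#' analog) for a radical pair born in the singlet state, using the exact
#' time-independent rotating-frame Hamiltonian for the circularly polarized RF
#' field. Solver choice: the Liouville-space stationary solve works for any
#' `kS, kT > 0`; the spectral formula of [singlet_yield_equal_rates()] applies
#' when `kS == kT` and scales to large systems. `"auto"` picks the spectral
#' route for equal rates and the Liouville solve otherwise.
#'
#' @param system a [spin_system()] with isotropic internal interactions.
#' @param fields a [field_config()].
#' @param rates a [rate_set()].
#' @param orient an [orientation()]; for isotropic systems the yields are
#'   orientation-independent.
#' @param solver one of "auto", "liouville", "spectral".
#' @return a `yield_result` list with `phi_S`, `phi_T`, `solver`.
#' @export
singlet_yield <- function(system, fields, rates, orient = orientation(),
                          solver = c("auto", "liouville", "spectral")) {
  solver <- match.arg(solver)
  if (solver == "auto") {
    solver <- if (rates$kS == rates$kT && rates$kS > 0) "spectral" else "liouville"
  }
  projectors <- projection_operators(system)
  H <- rotating_frame_hamiltonian(system, fields, orient)
  if (solver == "spectral") {
    if (rates$kS != rates$kT) stop("spectral solver requires kS == kT")
    return(singlet_yield_equal_rates(system, H, rates$kS, projectors))
  }
  y <- yield_liouville_solve(H, rates, projectors)
  structure(list(phi_S = y$phi_S, phi_T = y$phi_T, solver = "liouville-solve"),
            class = "yield_result")
}

#' Time-ordered laboratory-frame propagation
#'
#' Integrates the Liouville-von Neumann equation with the explicitly
#' time-dependent laboratory-frame Hamiltonian, serving as the independent
#' correctness oracle for the rotating-frame solvers and as the only route for
#' anisotropic (dipolar) systems. Each step applies a Strang splitting: exact
#' Haberkorn reaction flow for half a step, exact unitary propagation under the
#' midpoint Hamiltonian, then the second reaction half-step. The step `dt`
#' must resolve both the RF period and the fastest internal frequency
#' (`dt <= 1/(20 nu_max)`); a coarser step triggers a warning.
#'
#' @param system a [spin_system()].
#' @param fields a [field_config()].
#' @param rates a [rate_set()].
#' @param t_end end time, s.
#' @param dt time step, s.
#' @param orient an [orientation()].
#' @param record_every store every k-th sample in the trajectory (all samples
#'   still contribute to the yield integrals).
#' @param check_positivity verify along the way that eigenvalues of rho stay
#'   above -1e-8 (diagnostic error otherwise).
#' @return data.frame with columns `t_s`, `phi_S`, `trace_rho`; attributes
#'   `yield_S`, `yield_T` hold the truncated integrals
#'   `k_X * integral_0^t_end phi_X dt` (Simpson rule).
#' @export
propagate_lab_frame <- function(system, fields, rates, t_end, dt,
                                orient = orientation(), record_every = 1L,
                                check_positivity = TRUE) {
  stopifnot(t_end > 0, dt > 0)
  projectors <- projection_operators(system)
  rho <- initial_state(system, projectors)
  n <- nrow(rho)
  # decompose H(t) = H_static + B1 (cos(wt+phi) Hx + sin(wt+phi) Hy) so the
  # stepping loop only recombines precomputed operators
  R <- euler_rotation_matrix(orient)
  H_static <- total_hamiltonian(system, field_config(fields$B0_uT, 0, 0),
                                orient, t = 0)
  Hx <- electron_axis_sum(system, drop(t(R) %*% c(1, 0, 0)))
  Hy <- electron_axis_sum(system, drop(t(R) %*% c(0, 1, 0)))
  B1_T <- fields$B1_uT * 1e-6
  w_rf <- omega_from_MHz(fields$nu_MHz)
  H_at <- function(t) {
    if (B1_T == 0) return(H_static)
    wt <- w_rf * t + fields$phi_rad
    H_static + B1_T * (cos(wt) * Hx + sin(wt) * Hy)
  }
  # fastest frequency: RF drive and the spread of H(0) eigenvalues
  ev0 <- eigen(H_at(0), symmetric = TRUE, only.values = TRUE)$values
  nu_max <- max(fields$nu_MHz * 1e6, (max(ev0) - min(ev0)) / (2 * pi), 1)
  if (dt > 1 / (20 * nu_max)) {
    warning(sprintf(
      "dt = %.3g s is coarser than 1/(20 nu_max) = %.3g s; results may not be converged",
      dt, 1 / (20 * nu_max)))
  }
  nsteps <- ceiling(t_end / dt)
  # exact reaction half-step: rho -> Kq rho Kq
  Kq <- exp(-rates$kS * dt / 4) * projectors$P_S +
    exp(-rates$kT * dt / 4) * projectors$P_T
  static_H <- B1_T == 0 || w_rf == 0
  M <- NULL
  if (static_H) {
    ed <- eigen(H_at(dt / 2), symmetric = TRUE)
    U <- ed$vectors %*% (exp(-1i * ed$values * dt) * Conj(t(ed$vectors)))
    M <- Kq %*% U %*% Kq
  }
  phi_S <- numeric(nsteps + 1)
  phi_T <- numeric(nsteps + 1)
  tr <- numeric(nsteps + 1)
  phi_S[1] <- Re(sum(diag(projectors$P_S %*% rho)))
  phi_T[1] <- Re(sum(diag(projectors$P_T %*% rho)))
  tr[1] <- Re(sum(diag(rho)))
  for (s in seq_len(nsteps)) {
    if (!static_H) {
      ed <- eigen(H_at((s - 0.5) * dt), symmetric = TRUE)
      U <- ed$vectors %*% (exp(-1i * ed$values * dt) * Conj(t(ed$vectors)))
      M <- Kq %*% U %*% Kq
    }
    rho <- M %*% rho %*% Conj(t(M))
    phi_S[s + 1] <- Re(sum(diag(projectors$P_S %*% rho)))
    phi_T[s + 1] <- Re(sum(diag(projectors$P_T %*% rho)))
    tr[s + 1] <- Re(sum(diag(rho)))
    if (check_positivity && (s %% 200L == 0L || s == nsteps)) {
      mineig <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
      if (mineig < -1e-8) {
        stop(sprintf("density matrix lost positivity (min eigenvalue %.3e at t = %.3e s)",
                     mineig, s * dt))
      }
    }
  }
  times <- seq(0, nsteps) * dt
  keep <- unique(c(seq(1, nsteps + 1, by = record_every), nsteps + 1))
  out <- data.frame(t_s = times[keep], phi_S = phi_S[keep], trace_rho = tr[keep])
  attr(out, "yield_S") <- rates$kS * simpson_integral(phi_S, dt)
  attr(out, "yield_T") <- rates$kT * simpson_integral(phi_T, dt)
  class(out) <- c("rp_trajectory", "data.frame")
  out
}

# composite Simpson rule on a uniform grid (trapezoid fallback on the last
# interval when the sample count is even)
simpson_integral <- function(y, dt) {
  n <- length(y)
  if (n < 3) return(sum(y) * dt - (y[1] + y[n]) * dt / 2)
  m <- if (n %% 2 == 1) n else n - 1
  i <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1
  w[m] <- 1
  total <- sum(w * y[i]) * dt / 3
  if (n %% 2 == 0) total <- total + (y[n - 1] + y[n]) * dt / 2
  total
}

#' Write a trajectory or spectrum table
#'
#' Delimiter-separated table with a commented header recording the parameter
#' set, readable back with `read.delim(..., comment.char = "#")`.
#'
#' @param x data.frame to write.
#' @param path output file.
#' @param params named list recorded as `# key: value` header lines.
#' @export
write_run_table <- function(x, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = ", ")), con)
  }
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
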
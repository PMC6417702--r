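# Hamiltonian builders. All Hamiltonians are returned in angular-frequency
# units (rad/s), i.e. H/hbar; field-like couplings in mT/uT are converted on
# entry through the gyromagnetic factor g*mu_B/hbar.

#' Field configuration
#'
#' Static field `B0` along the laboratory z-axis plus a circularly polarized
#' RF field of amplitude `B1` rotating in the laboratory xy-plane as
#' `B1 (cos(2 pi nu t + phi), sin(2 pi nu t + phi), 0)`. Only circular
#' polarization is supported: it is the case for which the rotating-frame
#' transformation is exact.
#'
#' @param B0_uT static field magnitude, microtesla (>= 0).
#' @param B1_uT RF amplitude, microtesla (>= 0).
#' @param nu_MHz RF frequency in MHz (cycles, not angular).
#' @param phi_rad RF phase in radians.
#' @param polarization only "circular" is supported.
#' @return a `field_config` object.
#' @export
field_config <- function(B0_uT, B1_uT = 0, nu_MHz = 0, phi_rad = 0,
                         polarization = "circular") {
  if (!identical(polarization, "circular")) {
    stop("unsupported polarization '", polarization,
         "': only circular-in-xy RF fields are supported")
  }
  stopifnot(B0_uT >= 0, B1_uT >= 0, nu_MHz >= 0)
  structure(list(B0_uT = B0_uT, B1_uT = B1_uT, nu_MHz = nu_MHz,
                 phi_rad = phi_rad, polarization = polarization),
            class = "field_config")
}

#' Molecular orientation as Euler angles
#'
#' z-x-z convention: rotation about z by `alpha`, about the initial x-axis by
#' `beta`, about z by `gamma`. The identity orientation is (0, 0, 0).
#'
#' @param alpha,beta,gamma angles in radians.
#' @return an `orientation` object.
#' @export
orientation <- function(alpha = 0, beta = 0, gamma = 0) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "orientation")
}

#' Euler rotation matrix (z-x-z)
#'
#' Proper rotation `Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`; orthogonal with
#' determinant +1.
#'
#' @param orient an [orientation()].
#' @return 3x3 numeric matrix.
#' @export
euler_rotation_matrix <- function(orient) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  rz(orient$alpha) %*% rx(orient$beta) %*% rz(orient$gamma)
}

# Sum over electrons of gamma_e * (S_e . axis) for a unit 3-vector expressed in
# the molecular frame. Used by the Zeeman and rotating-frame builders.
electron_axis_sum <- function(system, axis) {
  acc <- NULL
  for (e in 1:2) {
    ge <- gyromagnetic(system$g[e]) / gyromagnetic(2)  # relative weight
    term <- ge * (axis[1] * particle_spin(system, e, "x") +
                  axis[2] * particle_spin(system, e, "y") +
                  axis[3] * particle_spin(system, e, "z"))
    acc <- if (is.null(acc)) term else acc + term
  }
  gyromagnetic(2) * acc  # rad/s per tesla once multiplied by a field
}

#' Hyperfine Hamiltonian
#'
#' `H_HF = g mu_B sum_i a_i S_r(i) . I_i` with each nucleus coupled to the
#' electron of its own radical through its isotropic coupling `a_i` (mT).
#' Isotropic couplings make this term invariant under global spin rotations,
#' which is what permits the exact rotating-frame treatment.
#'
#' @param system a [spin_system()].
#' @return Hermitian complex matrix, rad/s.
#' @export
hyperfine_hamiltonian <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  dim <- hilbert_dimension(system)
  H <- matrix(0i, dim, dim)
  for (k in seq_along(system$nuclei)) {
    nuc <- system$nuclei[[k]]
    if (is.null(nuc$a_mT) || !is.finite(nuc$a_mT)) {
      stop("nucleus '", nuc$label, "' has no hyperfine coupling")
    }
    e <- nuc$radical           # electron position 1 or 2
    j <- 2L + k                # nucleus position in particle order
    H <- H + omega_from_mT(nuc$a_mT, system$g[e]) * two_site_dot(system, e, j)
  }
  assert_hermitian(H, "hyperfine Hamiltonian")
}

#' Zeeman Hamiltonian at time t
#'
#' Interaction of the two electron spins with the static field `B0` (along
#' laboratory z) and the circularly polarized RF field, with the molecular
#' orientation entering through the rotation matrix applied to the electron
#' spin operators. Nuclear Zeeman terms are omitted (2-3 orders of magnitude
#' smaller). At the identity orientation this reduces to
#' `g mu_B [B0 (S1z + S2z) + B1 ((S1x + S2x) cos(wt + phi) + (S1y + S2y) sin(wt + phi))]`.
#'
#' @param system a [spin_system()].
#' @param fields a [field_config()].
#' @param orient an [orientation()] (default identity).
#' @param t time in seconds.
#' @return Hermitian complex matrix, rad/s.
#' @export
zeeman_hamiltonian <- function(system, fields, orient = orientation(), t = 0) {
  stopifnot(inherits(fields, "field_config"))
  R <- euler_rotation_matrix(orient)
  wt <- omega_from_MHz(fields$nu_MHz) * t + fields$phi_rad
  B_lab <- c(fields$B1_uT * cos(wt), fields$B1_uT * sin(wt), fields$B0_uT) * 1e-6
  # (R S) . B = S . (R^T B): express the lab field in the molecular frame
  B_mol <- drop(t(R) %*% B_lab)
  H <- electron_axis_sum(system, B_mol)
  assert_hermitian(H, "Zeeman Hamiltonian")
}

#' Exchange Hamiltonian
#'
#' `H_ex = -2 J S1.S2`, parameterized by the field equivalent
#' `eta = -2J / (g mu_B)` in mT so that the singlet-triplet splitting equals
#' `g mu_B eta` in energy units. Large `eta` locks the electron pair in its
#' singlet/triplet manifolds and suppresses interconversion.
#'
#' @param system a [spin_system()].
#' @return Hermitian complex matrix, rad/s.
#' @export
exchange_hamiltonian <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  omega_from_mT(system$eta_mT) * two_site_dot(system, 1L, 2L)
}

#' Point-dipole dipole-dipole coupling tensor
#'
#' The symmetric traceless 3x3 tensor `D(r)` of the electron-electron magnetic
#' dipole-dipole interaction for point dipoles at separation `r`
#' (`H_dd = S1 . D(r) . S2`), in angular-frequency units.
#'
#' @param system a [spin_system()] with `r_nm` set.
#' @return 3x3 numeric matrix, rad/s.
#' @export
dipolar_tensor <- function(system) {
  if (is.null(system$r_nm)) stop("dipolar_vector r_nm is not set")
  r <- system$r_nm * 1e-9
  rn <- sqrt(sum(r^2))
  if (rn <= 0) stop("inter-radical distance |r| must be > 0")
  rhat <- r / rn
  pref <- system$g[1] * system$g[2] * .const$mu_0 * .const$mu_B^2 /
    (4 * pi * rn^3 * .const$hbar)
  pref * (3 * outer(rhat, rhat) - diag(3))
}

#' Dipole-dipole Hamiltonian
#'
#' `H_dd = S1 . D(r) . S2` with the point-dipole tensor of [dipolar_tensor()].
#' This term is anisotropic: it does not commute with global spin rotations,
#' so systems containing it must be propagated in the laboratory frame.
#'
#' @param system a [spin_system()] with `r_nm` set.
#' @return Hermitian complex matrix, rad/s.
#' @export
dipole_dipole_hamiltonian <- function(system) {
  D <- dipolar_tensor(system)
  ax <- c("x", "y", "z")
  dim <- hilbert_dimension(system)
  H <- matrix(0i, dim, dim)
  S1 <- lapply(ax, function(a) particle_spin(system, 1L, a))
  S2 <- lapply(ax, function(a) particle_spin(system, 2L, a))
  for (j in 1:3) for (k in 1:3) {
    if (D[j, k] != 0) H <- H + D[j, k] * (S1[[j]] %*% S2[[k]])
  }
  assert_hermitian(H, "dipole-dipole Hamiltonian")
}

has_dipolar <- function(system) !is.null(system$r_nm)

#' Full laboratory-frame Hamiltonian at time t
#'
#' Sum of the hyperfine, Zeeman (time-dependent), exchange and (if configured)
#' dipole-dipole terms.
#'
#' @inheritParams zeeman_hamiltonian
#' @return Hermitian complex matrix, rad/s.
#' @export
total_hamiltonian <- function(system, fields, orient = orientation(), t = 0) {
  H <- hyperfine_hamiltonian(system) +
    zeeman_hamiltonian(system, fields, orient, t)
  if (system$eta_mT != 0) H <- H + exchange_hamiltonian(system)
  if (has_dipolar(system)) H <- H + dipole_dipole_hamiltonian(system)
  H
}

#' Time-independent rotating-frame Hamiltonian
#'
#' In a frame co-rotating with the circularly polarized RF field about the
#' laboratory z-axis at the drive frequency, the Hamiltonian becomes
#' time-independent:
#' `H_rot = H_HF + H_ex + g mu_B B0 Sz,tot + g mu_B B1 (Sx,tot cos(phi) + Sy,tot sin(phi)) - w (Sz,tot + Iz,tot)`
#' (identity orientation; for a general orientation the laboratory axes are
#' expressed in the molecular frame). The counter-term `-w (Sz + Iz)` rotates
#' all spins, nuclei included: the isotropic hyperfine and exchange terms are
#' invariant only under such a global rotation, which is what makes the
#' transformation exact. The transformation requires all internal interactions
#' to be isotropic; with a dipolar term present an error is raised and the
#' laboratory-frame propagator [propagate_lab_frame()] must be used instead.
#'
#' @inheritParams zeeman_hamiltonian
#' @return Hermitian complex matrix, rad/s.
#' @export
rotating_frame_hamiltonian <- function(system, fields, orient = orientation()) {
  stopifnot(inherits(fields, "field_config"))
  if (has_dipolar(system)) {
    stop("rotating frame invalid for anisotropic internal interactions: ",
         "this system has a dipole-dipole term; use propagate_lab_frame()")
  }
  R <- euler_rotation_matrix(orient)
  zl <- drop(t(R) %*% c(0, 0, 1))  # lab axes in the molecular frame
  xl <- drop(t(R) %*% c(1, 0, 0))
  yl <- drop(t(R) %*% c(0, 1, 0))
  H <- hyperfine_hamiltonian(system)
  if (system$eta_mT != 0) H <- H + exchange_hamiltonian(system)
  H <- H + fields$B0_uT * 1e-6 * electron_axis_sum(system, zl)
  if (fields$B1_uT > 0) {
    rf_axis <- cos(fields$phi_rad) * xl + sin(fields$phi_rad) * yl
    H <- H + fields$B1_uT * 1e-6 * electron_axis_sum(system, rf_axis)
  }
  w <- omega_from_MHz(fields$nu_MHz)
  if (w != 0) {
    n <- n_particles(system)
    Fz <- matrix(0i, nrow(H), ncol(H))
    for (p in seq_len(n)) {
      Fz <- Fz + zl[1] * particle_spin(system, p, "x") +
        zl[2] * particle_spin(system, p, "y") +
        zl[3] * particle_spin(system, p, "z")
    }
    H <- H - w * Fz
  }
  assert_hermitian(H, "rotating-frame Hamiltonian")
}

#' Static-field shift of the single-radical hyperfine transition
#'
#' For one electron coupled to one spin-1/2 nucleus by an isotropic coupling
#' `a`, the zero-field levels are the total-spin F = 0 state at
#' `-(3/4) g mu_B a` and the three F = 1 states at `+(1/4) g mu_B a`, giving a
#' transition at `~28 MHz/mT * a`. A weak static field `B0` Zeeman-shifts the
#' F = 1, mF = +1 level, displacing that transition by approximately the half
#' Larmor frequency (about 0.7 MHz at 50 uT). The shift is computed by exact
#' diagonalization of `H = g mu_B a S.I + g mu_B B0 Sz` at `B0` and at zero
#' field, as the change of the F=0 -> (F=1, mF=+1) transition frequency.
#'
#' @param a_mT isotropic hyperfine coupling, mT.
#' @param B0_uT static field, microtesla.
#' @param g electron g-factor (default 2).
#' @return list with `nu0_MHz` (zero-field transition), `nu_MHz` (at `B0`) and
#'   `shift_MHz` (their difference).
#' @export
single_radical_transition <- function(a_mT, B0_uT, g = 2) {
  s <- spin_matrices(0.5)
  id <- diag(2) + 0i
  dot_si <- kronecker(s$x, s$x) + kronecker(s$y, s$y) + kronecker(s$z, s$z)
  Hat <- function(B_uT) {
    omega_from_mT(a_mT, g) * dot_si + omega_from_uT(B_uT, g) * kronecker(s$z, id)
  }
  tf <- function(B_uT) {
    ev <- eigen(Hat(B_uT), symmetric = TRUE, only.values = TRUE)$values
    # lowest level is F=0 (weak field), highest is F=1, mF=+1
    MHz_from_omega(max(ev) - min(ev))
  }
  nu0 <- tf(0)
  nu <- tf(B0_uT)
  list(nu0_MHz = nu0, nu_MHz = nu, shift_MHz = nu - nu0)
}
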
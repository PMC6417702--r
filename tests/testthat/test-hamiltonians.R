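test_that("hyperfine Hamiltonian reproduces the single-radical level structure", {
  # one coupled nucleus: F = 0 level at -(3/4) g muB a, F = 1 levels at +(1/4)
  sys <- one_nucleus_sys(a_mT = 1.0)
  H <- hyperfine_hamiltonian(sys)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  a_w <- gyromagnetic(2) * 1e-3
  # spectator electron doubles each multiplicity on the 8-dim space
  expect_equal(ev, c(rep(-0.75 * a_w, 2), rep(0.25 * a_w, 6)), tolerance = 1e-12)
  # transition frequency ~ 28 MHz at a = 1 mT
  tr <- single_radical_transition(1.0, 0)
  expect_equal(tr$nu0_MHz, 27.99, tolerance = 1e-3)
  # zero couplings give the zero matrix
  null_sys <- spin_system(list(nucleus("n1", 1, 0.5, 0), nucleus("n2", 2, 0.5, 0)))
  expect_equal(max(Mod(hyperfine_hamiltonian(null_sys))), 0)
})

test_that("Euler rotations are proper and compose as z-x-z", {
  expect_equal(euler_rotation_matrix(orientation(0, 0, 0)), diag(3))
  rot1 <- function(axis, t) {
    c_ <- cos(t); s_ <- sin(t)
    if (axis == "z") matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
    else matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
  }
  set.seed(7)
  for (i in 1:5) {
    ang <- stats::runif(3, -pi, pi)
    R <- euler_rotation_matrix(orientation(ang[1], ang[2], ang[3]))
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-14)
    expect_equal(det(R), 1, tolerance = 1e-12)
    oracle <- rot1("z", ang[1]) %*% rot1("x", ang[2]) %*% rot1("z", ang[3])
    expect_lt(max(abs(R - oracle)), 1e-13)
  }
})

test_that("Zeeman Hamiltonian matches its explicit identity-orientation form", {
  sys <- electron_pair_sys()
  w0 <- gyromagnetic(2) * 50e-6
  # static part: eigenvalues -w0, 0, 0, +w0 on the electron pair
  Hs <- zeeman_hamiltonian(sys, field_config(50, 0, 0))
  expect_equal(sort(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values),
               c(-w0, 0, 0, w0), tolerance = 1e-10)
  # RF part at t = 0, phi = 0 is g muB B1 (S1x + S2x)
  Hrf <- zeeman_hamiltonian(sys, field_config(0, 50, 10), t = 0)
  Sx_tot <- embed_operator(spin_matrices(0.5)$x, 1, sys) +
    embed_operator(spin_matrices(0.5)$x, 2, sys)
  expect_lt(frob(Hrf - w0 * Sx_tot), 1e-12 * w0)
  expect_error(field_config(50, 50, 10, polarization = "linear"),
               "unsupported polarization")
})

test_that("Zeeman eigenvalues are orientation-independent", {
  sys <- two_nucleus_sys()
  fld <- field_config(50, 50, 10)
  ref <- sort(eigen(zeeman_hamiltonian(sys, fld), symmetric = TRUE,
                    only.values = TRUE)$values)
  set.seed(21)
  for (i in 1:10) {
    om <- orientation(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                      stats::runif(1, 0, 2 * pi))
    ev <- sort(eigen(zeeman_hamiltonian(sys, fld, om), symmetric = TRUE,
                     only.values = TRUE)$values)
    expect_equal(ev, ref, tolerance = 1e-9)
  }
})

test_that("exchange term splits singlet and triplet manifolds by g muB eta", {
  sys <- electron_pair_sys(eta_mT = 1)
  H <- exchange_hamiltonian(sys)
  P <- projection_operators(sys)
  # P_S and P_T project onto eigenspaces
  expect_lt(frob(H %*% P$P_S - P$P_S %*% H), 1e-12 * frob(H))
  gap_w <- gyromagnetic(2) * 1e-3
  ev <- sort(unique(round(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 3)))
  expect_equal(diff(ev), gap_w, tolerance = 1e-6)
  expect_equal(max(Mod(exchange_hamiltonian(electron_pair_sys(eta_mT = 0)))), 0)
})

test_that("dipolar tensor is traceless, axial along r, and electron-exchange symmetric", {
  set.seed(3)
  for (i in 1:3) {
    sys <- spin_system(r_nm = stats::rnorm(3))
    D <- dipolar_tensor(sys)
    expect_lt(abs(sum(diag(D))), 1e-6 * max(abs(D)))
    expect_lt(max(abs(D - t(D))), 1e-12 * max(abs(D)))
  }
  Dz <- dipolar_tensor(spin_system(r_nm = c(0, 0, 1.5)))
  expect_equal(Dz[3, 3], -2 * Dz[1, 1], tolerance = 1e-12)
  expect_equal(Dz[1, 1], Dz[2, 2], tolerance = 1e-12)
  # swapping the electron labels leaves H_dd invariant: conjugate by the
  # permutation exchanging the two electron tensor slots
  sys <- spin_system(r_nm = c(0.3, -0.7, 1.1))
  H <- dipole_dipole_hamiltonian(sys)
  swap <- matrix(0, 4, 4)
  for (i in 0:1) for (j in 0:1) swap[2 * j + i + 1, 2 * i + j + 1] <- 1
  expect_lt(frob(swap %*% H %*% t(swap) - H), 1e-10 * frob(H))
})

test_that("all Hamiltonian builders return Hermitian operators", {
  sys <- spin_system(list(nucleus("N", 1, 1, 0.4), nucleus("H", 2, 0.5, 1.0)),
                     eta_mT = 0.3, r_nm = c(0.5, 0.5, 1))
  fld <- field_config(50, 50, 14.4, phi_rad = 0.7)
  om <- orientation(0.3, 1.1, -0.4)
  for (H in list(hyperfine_hamiltonian(sys),
                 zeeman_hamiltonian(sys, fld, om, t = 3e-8),
                 exchange_hamiltonian(sys),
                 dipole_dipole_hamiltonian(sys),
                 total_hamiltonian(sys, fld, om, t = 1e-8))) {
    expect_lt(frob(H - Conj(t(H))), 1e-12 * max(1, frob(H)))
  }
})

test_that("full Hamiltonian reduces to its explicit form at identity orientation", {
  sys <- two_nucleus_sys()
  fld <- field_config(50, 50, 10, phi_rad = 0.3)
  t <- 2.3e-8
  wt <- 2 * pi * 10e6 * t + 0.3
  w1 <- gyromagnetic(2) * 50e-6
  sx <- spin_matrices(0.5)$x; sy <- spin_matrices(0.5)$y; sz <- spin_matrices(0.5)$z
  S_tot <- function(op) embed_operator(op, 1, sys) + embed_operator(op, 2, sys)
  explicit <- hyperfine_hamiltonian(sys) + w1 * S_tot(sz) +
    w1 * (S_tot(sx) * cos(wt) + S_tot(sy) * sin(wt))
  expect_lt(frob(total_hamiltonian(sys, fld, t = t) - explicit),
            1e-12 * frob(explicit))
})

test_that("rotating frame: nu = 0 is a static transverse field and dipolar systems are rejected", {
  sys <- two_nucleus_sys()
  H0 <- rotating_frame_hamiltonian(sys, field_config(50, 50, 0))
  expect_lt(frob(H0 - total_hamiltonian(sys, field_config(50, 50, 0), t = 0)),
            1e-12 * frob(H0))
  sysd <- spin_system(list(nucleus("n1", 1, 0.5, 0.5)), r_nm = c(0, 0, 1))
  expect_error(rotating_frame_hamiltonian(sysd, field_config(50, 50, 10)),
               "rotating frame invalid")
})

test_that("static-field shift of the one-radical transition is about half the Larmor frequency", {
  tr <- single_radical_transition(0.5, 50)
  expect_equal(tr$shift_MHz, larmor_frequency(50) / 2, tolerance = 0.1)
  expect_gt(tr$nu_MHz, tr$nu0_MHz)
})
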
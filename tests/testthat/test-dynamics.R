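test_that("the initial state is a unit-trace singlet with maximally mixed nuclei", {
  for (sys in list(electron_pair_sys(), two_nucleus_sys())) {
    P <- projection_operators(sys)
    rho0 <- initial_state(sys, P)
    expect_equal(Re(sum(diag(rho0))), 1, tolerance = 1e-14)
    expect_equal(Re(sum(diag(P$P_S %*% rho0))), 1, tolerance = 1e-14)
    expect_equal(Re(sum(diag(P$P_T %*% rho0))), 0, tolerance = 1e-14)
  }
  # electron-only: the pure singlet projector itself
  sys <- electron_pair_sys()
  expect_lt(frob(initial_state(sys) - projection_operators(sys)$P_S), 1e-14)
})

test_that("the Liouvillian matches the master equation assembled by hand", {
  sys <- two_nucleus_sys()
  P <- projection_operators(sys)
  H <- rotating_frame_hamiltonian(sys, field_config(50, 50, 14.4))
  L <- liouvillian(H, rate_set(3e6, 8e5), P)
  set.seed(5)
  for (i in 1:3) {
    rho <- rand_hermitian(16)
    rhs <- master_rhs_oracle(H, rho, 3e6, 8e5, P$P_S, P$P_T)
    expect_lt(frob(matrix(L %*% as.vector(rho), 16, 16) - rhs),
              1e-9 * frob(rhs))
  }
})

test_that("trace and purity behave as the reaction terms dictate", {
  sys <- one_nucleus_sys()
  fld <- field_config(50, 50, 14.4)
  # no reactions: unitary evolution preserves trace and purity
  tr0 <- propagate_lab_frame(sys, fld, rate_set(0, 0), t_end = 2e-7, dt = 1e-9)
  expect_lt(max(abs(tr0$trace_rho - 1)), 1e-10)
  # equal rates: trace decays exactly as exp(-kt)
  k <- 2e6
  tr1 <- propagate_lab_frame(sys, fld, rate_set(k), t_end = 2e-6, dt = 1e-9,
                             record_every = 100)
  expect_lt(max(abs(tr1$trace_rho - exp(-k * tr1$t_s))), 1e-8)
})

test_that("yields conserve probability and the two solvers agree", {
  sys <- two_nucleus_sys()
  fld <- field_config(50, 50, 14.4)
  # unequal rates, Liouville solve: Phi_S + Phi_T = 1
  y <- singlet_yield(sys, fld, rate_set(2e6, 5e5))
  expect_equal(y$solver, "liouville-solve")
  expect_equal(y$phi_S + y$phi_T, 1, tolerance = 1e-8)
  expect_true(y$phi_S >= 0 && y$phi_S <= 1)
  # equal rates: spectral formula matches the Liouville solve to 1e-8
  for (nu in c(0, 7.7, 14.4, 28.7)) {
    f <- field_config(50, 50, nu)
    yl <- singlet_yield(sys, f, rate_set(1e6), solver = "liouville")
    ys <- singlet_yield(sys, f, rate_set(1e6), solver = "spectral")
    expect_equal(ys$phi_S, yl$phi_S, tolerance = 1e-8)
  }
  expect_error(singlet_yield(sys, fld, rate_set(0, 0)), "singular|zero")
})

test_that("the equal-rates spectral formula has the correct limits", {
  sys <- two_nucleus_sys()
  H0 <- matrix(0i, 16, 16)
  # H = 0: no mixing, the singlet-born pair reacts entirely through kS
  expect_equal(singlet_yield_equal_rates(sys, H0, 1e6)$phi_S, 1, tolerance = 1e-12)
  # k -> infinity: reaction outruns mixing
  H <- rotating_frame_hamiltonian(sys, field_config(50, 0, 0))
  expect_equal(singlet_yield_equal_rates(sys, H, 1e12)$phi_S, 1, tolerance = 1e-4)
  expect_error(singlet_yield_equal_rates(sys, H, 0), "k must be > 0")
})

test_that("rotating-frame yields equal lab-frame propagation on a one-nucleus pair", {
  sys <- one_nucleus_sys(0.5)
  rates <- rate_set(1e6)
  fld <- field_config(50, 50, 14.4)
  y_rot <- singlet_yield(sys, fld, rates)
  traj <- propagate_lab_frame(sys, fld, rates, t_end = 1e-5, dt = 5e-10,
                              record_every = 1000)
  expect_equal(attr(traj, "yield_S"), y_rot$phi_S, tolerance = 1e-4)
  expect_equal(attr(traj, "yield_S") + attr(traj, "yield_T"), 1,
               tolerance = 1e-4)
})

test_that("B1 = 0 propagation matches a direct Liouvillian matrix-exponential", {
  sys <- one_nucleus_sys(0.5)
  fld <- field_config(50, 0, 0)
  rates <- rate_set(1e6, 3e5)
  P <- projection_operators(sys)
  traj <- propagate_lab_frame(sys, fld, rates, t_end = 4e-7, dt = 5e-10)
  # oracle: vec(rho(t)) via eigendecomposition of the (non-Hermitian) Liouvillian
  L <- liouvillian(total_hamiltonian(sys, fld, t = 0), rates, P)
  ed <- eigen(L)
  v0 <- solve(ed$vectors, as.vector(initial_state(sys, P)))
  t_probe <- traj$t_s[c(201, 401, 801)]
  for (tp in t_probe) {
    rho_t <- matrix(ed$vectors %*% (exp(ed$values * tp) * v0), 8, 8)
    phi_oracle <- Re(sum(diag(P$P_S %*% rho_t)))
    expect_equal(traj$phi_S[traj$t_s == tp], phi_oracle, tolerance = 1e-6)
  }
})

test_that("density matrices stay Hermitian and positive along trajectories", {
  sys <- one_nucleus_sys(1.0)
  traj <- propagate_lab_frame(sys, field_config(50, 100, 28), rate_set(1e6),
                              t_end = 1e-6, dt = 1e-9)
  expect_true(all(traj$phi_S >= -1e-10))
  expect_true(all(traj$trace_rho <= 1 + 1e-10))
  # the propagator itself raises on positivity loss; reaching here means none
  succeed()
})

test_that("yields are independent of the RF phase for circular polarization", {
  sys <- two_nucleus_sys()
  ys <- vapply(c(0, pi / 2, pi), function(phi) {
    singlet_yield(sys, field_config(50, 50, 14.4, phi_rad = phi),
                  rate_set(1e6))$phi_S
  }, numeric(1))
  expect_lt(max(ys) - min(ys), 1e-8)
})

test_that("a too-coarse time step triggers the resolution warning", {
  sys <- one_nucleus_sys(0.5)
  expect_warning(
    propagate_lab_frame(sys, field_config(50, 50, 40), rate_set(1e7),
                        t_end = 1e-7, dt = 5e-9),
    "coarser")
})
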
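test_that("tau_RF is inversely proportional to B1 and 714 ns at 50 uT", {
  expect_equal(tau_rf(50) * 1e9, 714, tolerance = 1e-3)
  expect_equal(tau_rf(100), tau_rf(50) / 2, tolerance = 1e-12)
  expect_equal(tau_rf(500) * 1e9, 71.4, tolerance = 1e-3)
  expect_identical(tau_rf(0), Inf)
})

test_that("the Marcus rate is maximal and symmetric about dG = -lambda and scales as |V|^2", {
  lam <- 0.8
  k0 <- marcus_rate(0.01, -lam, lam)       # activationless
  expect_gt(k0, marcus_rate(0.01, -lam + 0.2, lam))
  expect_gt(k0, marcus_rate(0.01, -lam - 0.2, lam))
  expect_equal(marcus_rate(0.01, -lam + 0.15, lam),
               marcus_rate(0.01, -lam - 0.15, lam), tolerance = 1e-12)
  expect_equal(marcus_rate(0.02, -lam, lam) / k0, 4, tolerance = 1e-12)
  # activationless: exponential factor is exactly 1
  kBT <- 1.380649e-23 * 300
  V <- 0.01 * 1.602176634e-19
  lamJ <- lam * 1.602176634e-19
  pref <- 2 * pi / 1.054571817e-34 * V^2 / sqrt(4 * pi * lamJ * kBT)
  expect_equal(k0, pref, tolerance = 1e-10)
  # unimodality across a dG scan
  dgs <- seq(-2, 0.5, 0.05)
  ks <- vapply(dgs, marcus_rate, numeric(1), V_ab_eV = 0.01, lambda_eV = lam)
  expect_equal(dgs[which.max(ks)], -lam, tolerance = 0.051)
  expect_true(all(diff(ks[dgs <= -lam]) > 0))
  expect_true(all(diff(ks[dgs >= -lam]) < 0))
})

test_that("escape and mixing rate calculators give the textbook magnitudes", {
  expect_equal(escape_rate(1e-6), 1e6)
  expect_equal(escape_rate(1e-7), 1e7)
  expect_equal(escape_rate(escape_rate(3.7e-8)), 3.7e-8)  # reciprocal round-trip
  expect_equal(kmix_estimate(1) / 1e6, 28, tolerance = 0.01)   # ~28 us^-1 at 1 mT
  expect_equal(kmix_estimate(0.5), kmix_estimate(1) / 2)       # linear in a
})

test_that("lifetime estimates follow the initial-state accessibility rules", {
  # spin-independent kinetics: tau_0 = 1/k
  expect_equal(lifetime_estimate(rate_set(1e6, 1e6)), 1e-6)
  # singlet-born, fast channel only from the triplet: gated by interconversion
  expect_equal(lifetime_estimate(rate_set(0, 1e9), kmix = 3e7,
                                 initial_state_reacts = FALSE), 1 / 3e7)
  # singlet-born with a fast singlet channel: tau_0 = 1/k_S
  expect_equal(lifetime_estimate(rate_set(1e9, 0)), 1e-9)
  expect_error(lifetime_estimate(rate_set(0, 0)), "at least one rate")
  expect_error(lifetime_estimate(rate_set(0, 1e9), initial_state_reacts = FALSE),
               "kmix")
})

test_that("screening gates fire on the documented conditions", {
  sys <- two_nucleus_sys(0.5)
  rc <- resonance_catalog(total_hamiltonian(sys, field_config(50, 0, 0)))
  # RF too weak: tau_RF = 714 ns >> tau_0 = 1 ns
  v1 <- rf_verdict(tau_0 = 1e-9, tau_RF = tau_rf(50))
  expect_identical(v1$verdict, "excluded")
  expect_true("RF_TOO_WEAK" %in% v1$reasons)
  # relaxation too fast: tau_R = 1 ns << tau_0 = 1 us
  v2 <- rf_verdict(tau_0 = 1e-6, tau_RF = tau_rf(50), tau_R = 1e-9)
  expect_true("RELAXATION_TOO_FAST" %in% v2$reasons)
  # on-resonance two-nucleus case at 14.4 MHz: possible
  v3 <- rf_verdict(tau_0 = 1e-6, tau_RF = tau_rf(50), nu_rf_MHz = 14.4,
                   resonances = rc)
  expect_identical(v3$verdict, "possible")
  expect_length(v3$reasons, 0)
  # far off resonance beyond the catalog: excluded
  v4 <- rf_verdict(tau_0 = 1e-6, tau_RF = tau_rf(50), nu_rf_MHz = 200,
                   resonances = rc)
  expect_true("OFF_RESONANCE" %in% v4$reasons)
  # exchange dominating the hyperfine scale
  v5 <- rf_verdict(tau_0 = 1e-6, tau_RF = tau_rf(50), eta_mT = 2, a_max_mT = 1)
  expect_true("EXCHANGE_SUPPRESSED" %in% v5$reasons)
})

test_that("strengthening B1 never flips a possible verdict to RF_TOO_WEAK", {
  for (tau0 in c(1e-7, 1e-6, 1e-5)) {
    fired <- vapply(c(5, 50, 500), function(b1) {
      "RF_TOO_WEAK" %in% rf_verdict(tau_0 = tau0, tau_RF = tau_rf(b1))$reasons
    }, logical(1))
    expect_true(all(diff(as.integer(fired)) <= 0))  # monotone non-increasing
  }
})

test_that("verdicts are consistent with the computed action spectrum", {
  sys <- two_nucleus_sys(0.25)
  rates <- rate_set(1e6)
  rc <- resonance_catalog(total_hamiltonian(sys, field_config(50, 0, 0)))
  grid <- seq(3, 30, 0.25)
  sp <- action_spectrum(sys, rates, 50, 50, nu_MHz = grid)
  spectrum_max <- max(abs(sp$delta_phi_S))
  for (nu in c(12, 13, 15, 16, 22)) {  # between the 7.7 and 28.7 MHz features
    v <- rf_verdict(tau_0 = 1e-6, tau_RF = tau_rf(50), nu_rf_MHz = nu,
                    resonances = rc)
    if ("OFF_RESONANCE" %in% v$reasons) {
      d_here <- abs(sp$delta_phi_S[which.min(abs(sp$nu_MHz - nu))])
      expect_lt(d_here, 0.1 * spectrum_max)
    }
  }
})

test_that("workflow_report assembles timescales and resonances from a configuration", {
  sys <- two_nucleus_sys(0.5)
  rep <- workflow_report(sys, field_config(50, 50, 14.4), rate_set(1e6))
  expect_identical(rep$verdict, "possible")
  expect_equal(rep$timescales$tau_0, 1e-6)
  rep2 <- workflow_report(sys, field_config(50, 50, 14.4), rate_set(1e9))
  expect_true("RF_TOO_WEAK" %in% rep2$reasons)
})
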
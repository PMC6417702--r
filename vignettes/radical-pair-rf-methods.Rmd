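---
title: "Methods: radical-pair spin dynamics under weak RF magnetic fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radical-pair spin dynamics under weak RF magnetic fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfspin)
```

## The physical problem

Weak radiofrequency (RF) magnetic fields in the MHz range have been reported
to change reactive-oxygen-species levels in living cells even though the
photon energies involved are far below thermal energies. The candidate
mechanism is the radical pair mechanism: two transiently bound radicals are
created together in a spin-correlated (singlet) electronic state, coherently
interconvert between singlet and triplet configurations under their hyperfine
and Zeeman interactions, and react through spin-selective channels. An
oscillating magnetic field that is resonant with a transition of the spin
system redistributes population between the spin states and thereby changes
the branching between the singlet and triplet products — for instance between
superoxide recombining to O2 and superoxide escaping into the cell.

`rfspin` simulates this process quantitatively for radical pairs with
isotropic hyperfine couplings, and wraps the simulation in a screening
workflow that can exclude RF effects on much cheaper grounds (characteristic
times, resonance analysis) before any density-matrix propagation is run.

## Model

A radical pair is two spin-1/2 electrons, one per radical, plus any number of
spin-1/2 or spin-1 nuclei, each hyperfine-coupled to its own radical's
electron. The Hilbert space is the tensor product over particles in a fixed
order (electron 1, electron 2, nuclei in declaration order); its dimension is
the product of the multiplicities `2s+1`. All Hamiltonians are handled in
angular-frequency units (rad/s): a coupling of `a` mT enters as
`g mu_B a / hbar`, with `g = 2` (organic radicals) and CODATA constants, so
that 1 mT corresponds to 27.99 MHz.

The Hamiltonian terms are

* **hyperfine**: `g mu_B sum_i a_i S_r(i).I_i`, isotropic scalars only;
* **Zeeman**: static field `B0` along the laboratory z axis plus a circularly
  polarized RF field `B1 (cos(wt + phi), sin(wt + phi), 0)`, acting on the
  electron spins; the molecular orientation enters through an Euler rotation
  (z-x-z) applied to the spin operators; nuclear Zeeman terms are neglected
  (smaller by the electron/nucleus mass ratio);
* **exchange**: `-2J S1.S2`, parameterized by the field equivalent
  `eta = -2J/(g mu_B)` in mT;
* **dipole-dipole**: point dipoles at separation `r`, a symmetric traceless
  tensor coupling; the only anisotropic term supported.

The state evolves under the Liouville-von Neumann equation with Haberkorn
reaction terms,

```
drho/dt = -i[H, rho] - (kS/2){P_S, rho} - (kT/2){P_T, rho},
```

where `P_S = 1/4 - S1.S2` and `P_T = 3/4 + S1.S2` are the singlet and triplet
projectors and `kS`, `kT` the spin-selective rate constants. The pair is born
in the coherent singlet state with maximally mixed nuclei,
`rho0 = P_S / Tr(P_S)`. The observables are the product quantum yields
`Phi_S = kS \int Tr(P_S rho) dt` and the triplet analog; with both rates
positive they sum to one. An RF **action spectrum** is the change
`delta <Phi_S>(nu) = <Phi_S>(B1, nu) - <Phi_S>(B1 = 0)`.

## Rotating frame and solvers

For a circularly polarized single-frequency drive the time dependence can be
removed exactly by passing to a frame rotating about the laboratory z axis at
the drive frequency `w = 2 pi nu`:

```
H_rot = H_HF + H_ex + g mu_B B0 Sz,tot
      + g mu_B B1 (Sx,tot cos phi + Sy,tot sin phi) - w (Sz,tot + Iz,tot).
```

Two points matter here. First, the counter-term rotates *all* spins, nuclei
included, even though the nuclei do not couple to the field: the isotropic
hyperfine term is invariant only under such a global rotation, and this is
exactly what makes the transformation exact. (Whether to include the nuclear
term is not obvious a priori; we settled it by requiring bit-level agreement
with laboratory-frame time-ordered propagation, which the test suite verifies
to better than 1e-4 in the yields across 0-45 MHz.) Second, the
transformation is exact only while every internal interaction is isotropic;
a dipolar term breaks it, and the builder refuses and points to the
laboratory-frame propagator instead.

With a time-independent `H_rot`, the yields follow from a stationary linear
solve: `L vec(A) = -vec(rho0)` for `A = \int rho dt`, then
`Phi_X = k_X Tr(P_X A)`. This is exact (no time truncation) and is the
default for unequal rates up to dimension 64 (a 4096-dimensional Liouville
space). When `kS = kT = k` there is a cheaper closed form over the eigenpairs
of `H_rot`,

```
Phi_S = (1/Tr P_S) sum_{j,l} |<j|P_S|l>|^2 k^2 / (k^2 + (w_j - w_l)^2),
```

which replaces the Liouville-space solve by one Hermitian eigendecomposition
and is what makes systems with thousands of states (the FAD-like preset has
2304) tractable. The two routes agree to 1e-8 wherever both apply; this
dual-solver agreement is a standing test.

The laboratory-frame propagator integrates the master equation directly with
a Strang splitting per step: exact reaction flow for half a step (the
reaction superoperator has the closed-form flow
`rho -> e^{-Kt/2} rho e^{-Kt/2}` with `K = kS P_S + kT P_T`), exact unitary
under the midpoint Hamiltonian, then the second reaction half-step. It
carries a step-resolution warning (`dt <= 1/(20 nu_max)`), checks positivity
of `rho` along the way (eigenvalues below -1e-8 raise a diagnostic error
rather than being clipped), and serves as the independent oracle for the
rotating-frame solvers.

## Orientation averaging

Cells tumble, so observable yields are orientation averages over the Euler
angles with the `sin(beta)` measure. For isotropic systems the yields are
orientation-independent and the average equals the single-orientation yield;
the package uses this shortcut automatically (and the test suite confirms the
full quadrature agrees to 1e-10). For dipolar systems a Gauss-Legendre rule
in `cos(beta)` (8 nodes by default) crossed with uniform periodic rules in
`alpha` and `gamma` (8 nodes each) is used; periodic trapezoid rules are
spectrally accurate for the two periodic angles, and the quadrature
convergence is itself tested (successive refinements at least halve the
change). Total product yields scale the averaged quantum yields by
`N = N_RPs x N_cells`; the observable *fractions* are independent of `N`.

## The screening workflow

Full spin dynamics is rarely the first thing to compute. The screening gates
operate on three characteristic times plus a resonance analysis:

* `tau_RF = 2 pi hbar / (g mu_B B1)` — the time the RF field needs to act
  (714 ns at 50 uT); if `tau_RF >> tau_0` the pair reacts before the field
  can do anything (`RF_TOO_WEAK`);
* `tau_R` — a user-supplied spin-relaxation time; `tau_R << tau_0` means
  thermal equilibrium erases the coherence first (`RELAXATION_TOO_FAST`);
* the resonance catalog — all `n(n-1)` ordered pairwise eigenvalue
  differences of the `B1 = 0` Hamiltonian, in MHz; an RF frequency far from
  every catalog entry cannot drive any transition (`OFF_RESONANCE`);
* exchange/dipolar strength above the hyperfine scale locks the electron
  manifolds and suppresses interconversion (`EXCHANGE_SUPPRESSED`).

The literature states these gates as asymptotic inequalities without numeric
thresholds. We adopt a "much greater than" factor `F = 10` for both time
gates, and for the resonance gate a tolerance
`max(1, 2(1/(pi tau_0) + 1/tau_RF)) 1e-6` MHz: the first term is the
lifetime-broadening FWHM `k/pi`, the second the drive (power-broadening)
width, and the factor 2 covers the Zeeman-split multiplet spread around each
hyperfine feature (a Lorentzian falls below a tenth of its peak beyond about
1.5 FWHM). Both are configurable, and the report prints them as the
engineering choices they are. The test suite checks the gate against the
full spectra of the two-nucleus models: wherever `OFF_RESONANCE` fires, the
computed `|delta <Phi_S>|` is below 10% of the spectrum maximum.

Rate-constant helpers round out the workflow module: the Marcus
electron-transfer rate (standard non-adiabatic form, with the
`(4 pi lambda kB T)^{-1/2}` prefactor and `4 lambda kB T` in the exponent),
the escape rate `1/tau_b`, and the order-of-magnitude mixing rate
`k_mix ~ g mu_B a / (2 pi hbar)` (28 us^-1 at 1 mT).

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `a_i` | mT | preset: `a2 = 1.0`, `a1` tunable | sets resonance positions at ~28 MHz/mT + 0.7 MHz |
| `B0` | uT | 50 (geomagnetic scale) | Zeeman-splits levels; shifts transitions by ~half the Larmor frequency |
| `B1` | uT | 50 | RF amplitude; sets `tau_RF` and power broadening |
| `nu` | MHz | scan 0-50, step 0.1 | drive frequency (cycles, not angular) |
| `kS`, `kT` | s^-1 | 1e6 | spin-selective reaction rates; `k/pi` sets linewidths |
| `eta` | mT | 0 | exchange field equivalent; comparable to `a` suppresses response |
| `r` | nm | unset | enables the dipolar term, forces lab-frame treatment |

The two-nucleus preset reproduces the canonical behaviors: features at
`28 MHz/mT * a1 + 0.7 MHz` (7.7 / 21.7 / 42.7 MHz for a1 = 0.25 / 0.75 /
1.50 mT) plus the fixed `a2` feature at 28.7 MHz; a non-zero response at
`nu = 0` (the RF term is then a static transverse field); attenuation of all
features once `B1` approaches the hyperfine scale; suppression under
exchange.

## What the built-in models emulate, and what they do not

The presets are *generic* model systems, not parameterizations of a specific
protein: they reproduce the structure of real action spectra (resonances set
by hyperfine couplings, lifetime broadening, low-frequency response) but not
the spectrum of any particular radical pair. The FAD/superoxide preset fixes
the spin topology (8 nuclei on the flavin radical, two of them spin-1;
superoxide bare, hence a free-electron Larmor resonance at 1.4 MHz per 50 uT)
but deliberately ships no hyperfine values — they are not established within
this package's sources and must be supplied from quantum-chemistry
literature. Passing tests therefore demonstrate correctness of the spin
dynamics machinery, not agreement with any measured cellular response.
Anisotropic hyperfine tensors, linearly polarized or multi-frequency drives,
g-tensor anisotropy, nuclear Zeeman/quadrupole terms and Redfield relaxation
are out of scope; relaxation enters only as the user-supplied `tau_R` gate.

## Numerical choices and edge cases

* Dense complex linear algebra throughout (LAPACK via base R); Liouville
  solves are used up to Hilbert dimension 64, the spectral formula beyond.
* Hamiltonian builders assert Hermiticity at 1e-12 relative tolerance.
* `nu = 0` in a spectrum is evaluated with the RF term as a static transverse
  field (the `w -> 0` limit of the rotating frame, which is continuous).
* Both rates zero makes the yield integral divergent; the solver refuses and
  points to finite-time propagation.
* Exact eigenvalue degeneracies produce zero entries in the resonance
  catalog; they are kept in the `n(n-1)` count but reported separately, and
  the histogram bins only the non-zero magnitudes. Both the ordered
  (`n(n-1)`) and unordered (`n(n-1)/2`) counts are reported since either
  convention is found in practice.
* `peak_locate` breaks exact ties toward the lower frequency;
  `peak_width` fits a four-parameter Lorentzian (amplitude, center, FWHM,
  offset) by Levenberg-Marquardt and fails loudly with residual diagnostics
  rather than returning a silent number.
* One count discrepancy is documented rather than resolved: for the 8-nucleus
  flavin model the product of multiplicities gives 2304 spin states
  (4 x 2^6 x 3^2), and this is the number the package uses and reports; a
  published description of the same system quotes 6528 states without
  stating the counting convention. The product formula is the one consistent
  with the tensor-product construction used here.

## Design decisions on open points

* **Frequency convention.** All interfaces use `nu` in MHz as cycles, with
  the drive argument `2 pi nu t + phi`; the resonance positions quoted above
  (7.7, 28.7 MHz, ...) match transition frequencies in cycles, which fixes
  the convention unambiguously.
* **Long-lifetime limit.** For the two-nucleus model the computed singlet
  yield in the slow-reaction regime settles near 0.31 at `B1 = 0` and near
  0.30 under a resonant 50 uT drive (both solvers agree to 1e-8). The
  statistical complete-mixing value `Tr(P_S)/dim = 1/4` is *not* reached by
  this 16-state model: at `B1 = 0` the total Fz is conserved and even the
  driven rotating-frame Hamiltonian retains structured eigenstates, so the
  ergodic limit that 1/4 presumes does not apply. The package reports the
  computed value; the tests record this measured behavior.
* **Problem sizes in the test suite.** The frame-equivalence checks run a
  one-nucleus pair (dimension 8) for 10 lifetimes at `dt = 0.5 ns` across
  five drive frequencies; spectra in tests and in the acceptance script use
  0.1 MHz grids restricted to the windows of interest. These sizes keep the
  whole suite under a minute while leaving every assertion tolerance-bound,
  and they are stated here as the package's chosen verification conditions.

## Worked example

```{r example, eval = FALSE}
cfg <- preset("two_nucleus", a1_mT = 0.25)
sp <- action_spectrum(cfg$system, cfg$rates, B0_uT = 50, B1_uT = 50,
                      nu_MHz = seq(3, 15, 0.1))
peak_locate(sp, c(3, 15))   # ~7.7 MHz: 28 MHz/mT * 0.25 mT + 0.7 MHz

rep <- workflow_report(cfg$system, field_config(50, 50, 14.4), cfg$rates)
rep$verdict
```
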
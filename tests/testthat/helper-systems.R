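# Shared fixtures: model systems built in code, plus brute-force oracles kept
# independent of the package internals they check.

two_nucleus_sys <- function(a1_mT = 0.5, eta_mT = 0) {
  spin_system(list(nucleus("n1", 1L, 0.5, a1_mT),
                   nucleus("n2", 2L, 0.5, 1.0)),
              eta_mT = eta_mT)
}

one_nucleus_sys <- function(a_mT = 0.5) {
  spin_system(list(nucleus("n1", 1L, 0.5, a_mT)))
}

electron_pair_sys <- function(eta_mT = 0, r_nm = NULL) {
  spin_system(eta_mT = eta_mT, r_nm = r_nm)
}

# Brute-force Kronecker assembly oracle for operator embedding: loops over all
# slots explicitly instead of splitting into pre/post identity blocks.
kron_embed_oracle <- function(op, index, mult) {
  out <- matrix(1 + 0i, 1, 1)
  for (j in seq_along(mult)) {
    factor <- if (j == index) op else diag(mult[j]) + 0i
    out <- kronecker(out, factor)
  }
  out
}

# Right-hand side of the master equation assembled directly from matrix
# products (oracle for the vectorized Liouvillian).
master_rhs_oracle <- function(H, rho, kS, kT, P_S, P_T) {
  -1i * (H %*% rho - rho %*% H) -
    (kS / 2) * (P_S %*% rho + rho %*% P_S) -
    (kT / 2) * (P_T %*% rho + rho %*% P_T)
}

frob <- function(M) sqrt(sum(Mod(M)^2))

rand_hermitian <- function(n) {
  A <- matrix(stats::rnorm(n * n), n) + 1i * matrix(stats::rnorm(n * n), n)
  (A + Conj(t(A))) / 2
}
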
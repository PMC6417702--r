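# Spin-operator algebra and composite-space construction.
#
# Basis convention: particles are ordered electron of radical 1, electron of
# radical 2, then nuclei in declaration order; the full Hilbert space is the
# lexicographic tensor product in that order. Each particle contributes a
# factor of (2s+1) to the dimension.

#' Single-particle spin matrices
#'
#' Angular-momentum matrices for a spin-s particle on its (2s+1)-dimensional
#' space, in the standard |s, m> basis ordered m = s, s-1, ..., -s. They
#' satisfy the cyclic commutation relations `[Sx, Sy] = i Sz` and
#' `Sx^2 + Sy^2 + Sz^2 = s(s+1) I`.
#'
#' @param s spin quantum number; 1/2 and 1 are supported.
#' @return list with complex matrices `x`, `y`, `z`.
#' @export
spin_matrices <- function(s) {
  if (!isTRUE(s %in% c(0.5, 1))) {
    stop("unsupported spin: s must be 1/2 or 1, got ", s)
  }
  m <- seq(s, -s)
  n <- length(m)
  sz <- diag(m) + 0i
  # raising operator: <m+1|S+|m> = sqrt(s(s+1) - m(m+1))
  sp <- matrix(0i, n, n)
  for (k in seq_len(n - 1)) {
    sp[k, k + 1] <- sqrt(s * (s + 1) - m[k + 1] * (m[k + 1] + 1))
  }
  sm <- Conj(t(sp))
  list(x = (sp + sm) / 2, y = (sp - sm) / (2i), z = sz)
}

#' Define a nucleus of a radical pair
#'
#' @param label free-text name (e.g. "N5", "H6").
#' @param radical index of the radical the nucleus belongs to (1 or 2); its
#'   hyperfine coupling connects it to that radical's electron only.
#' @param spin nuclear spin quantum number, 1/2 (protons) or 1 (14N).
#' @param a_mT isotropic hyperfine coupling in millitesla.
#' @return a `nucleus` object.
#' @export
nucleus <- function(label, radical, spin, a_mT) {
  stopifnot(radical %in% c(1L, 2L), is.finite(a_mT))
  if (!spin %in% c(0.5, 1)) {
    stop("unsupported spin: nucleus '", label, "' must have spin 1/2 or 1")
  }
  structure(list(label = as.character(label), radical = as.integer(radical),
                 spin = spin, a_mT = a_mT), class = "nucleus")
}

#' Define a radical-pair spin system
#'
#' A radical pair consists of exactly two unpaired electrons (spin 1/2, one
#' per radical) plus any number of magnetic nuclei, each carrying one isotropic
#' hyperfine coupling to its own radical's electron. Optionally the two
#' electrons interact through an exchange term (strength given as the
#' field-equivalent `eta = -2J/(g mu_B)` in mT) and/or a point-dipole
#' dipole-dipole term at separation `r_nm` (nm, 3-vector from radical 1 to
#' radical 2).
#'
#' @param nuclei list of [nucleus()] objects (may be empty).
#' @param g per-electron g-factors, length-2 numeric (default c(2, 2)).
#' @param eta_mT exchange strength as field equivalent, mT (default 0).
#' @param r_nm optional inter-radical vector in nm; enables the dipolar term.
#' @return a `spin_system` object.
#' @export
spin_system <- function(nuclei = list(), g = c(2, 2), eta_mT = 0, r_nm = NULL) {
  if (length(g) != 2 || any(!is.finite(g))) {
    stop("g must be two finite per-electron g-factors")
  }
  if (inherits(nuclei, "nucleus")) nuclei <- list(nuclei)
  ok <- vapply(nuclei, inherits, logical(1), what = "nucleus")
  if (!all(ok)) stop("nuclei must be a list of nucleus() objects")
  if (!is.null(r_nm)) {
    if (length(r_nm) != 3 || any(!is.finite(r_nm))) {
      stop("r_nm must be a finite 3-vector")
    }
    if (sqrt(sum(r_nm^2)) <= 0) stop("inter-radical distance |r| must be > 0")
  }
  stopifnot(is.finite(eta_mT))
  spins <- c(0.5, 0.5, vapply(nuclei, `[[`, numeric(1), "spin"))
  sys <- structure(list(
    g = as.numeric(g),
    nuclei = nuclei,
    eta_mT = eta_mT,
    r_nm = r_nm,
    spins = spins,          # per particle, electrons first
    mult = 2 * spins + 1    # per-particle multiplicities
  ), class = "spin_system")
  sys
}

#' @export
print.spin_system <- function(x, ...) {
  cat("Radical-pair spin system\n")
  cat("  electrons: 2 (g =", paste(x$g, collapse = ", "), ")\n")
  cat("  nuclei:", length(x$nuclei), "\n")
  for (n in x$nuclei) {
    cat(sprintf("    %-4s radical %d  spin %-3s a = %g mT\n",
                n$label, n$radical, format(n$spin), n$a_mT))
  }
  if (x$eta_mT != 0) cat("  exchange eta =", x$eta_mT, "mT\n")
  if (!is.null(x$r_nm)) {
    cat("  dipolar r =", paste(x$r_nm, collapse = ", "), "nm\n")
  }
  cat("  Hilbert dimension:", hilbert_dimension(x), "\n")
  invisible(x)
}

#' Hilbert-space dimension of a spin system
#'
#' Product of the per-particle multiplicities (2s+1): 16 for two electrons and
#' two spin-1/2 nuclei, 2304 for two electrons, six protons and two spin-1
#' nitrogens.
#'
#' @param system a [spin_system()].
#' @return integer dimension.
#' @export
hilbert_dimension <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  as.integer(round(prod(system$mult)))
}

n_particles <- function(system) length(system$spins)

#' Embed a single-particle operator into the full Hilbert space
#'
#' Tensor product with identities on every other particle, in the package's
#' fixed particle order (electron 1, electron 2, nuclei in declaration order).
#'
#' @param op square complex matrix on the single-particle space.
#' @param index particle position (1-based).
#' @param system a [spin_system()].
#' @return complex matrix on the full space.
#' @export
embed_operator <- function(op, index, system) {
  mult <- system$mult
  stopifnot(index >= 1, index <= length(mult))
  if (nrow(op) != mult[index] || ncol(op) != mult[index]) {
    stop("dimension mismatch: operator is ", nrow(op), "x", ncol(op),
         " but particle ", index, " has multiplicity ", mult[index])
  }
  pre  <- if (index > 1) prod(mult[seq_len(index - 1)]) else 1
  post <- if (index < length(mult)) prod(mult[seq(index + 1, length(mult))]) else 1
  out <- kronecker(diag(pre), op)
  if (post > 1) out <- kronecker(out, diag(post))
  out + 0i
}

# Scalar product of the spin vectors of particles i < j on the full space,
# built directly as a sum of Kronecker chains (no full-space matrix products,
# so it stays cheap for large systems).
two_site_dot <- function(system, i, j) {
  stopifnot(i < j)
  mult <- system$mult
  si <- spin_matrices(system$spins[i])
  sj <- spin_matrices(system$spins[j])
  pre  <- if (i > 1) prod(mult[seq_len(i - 1)]) else 1
  mid  <- if (j - i > 1) prod(mult[seq(i + 1, j - 1)]) else 1
  post <- if (j < length(mult)) prod(mult[seq(j + 1, length(mult))]) else 1
  acc <- NULL
  for (ax in c("x", "y", "z")) {
    term <- kronecker(si[[ax]], diag(mid))
    term <- kronecker(term, sj[[ax]])
    if (pre > 1) term <- kronecker(diag(pre), term)
    if (post > 1) term <- kronecker(term, diag(post))
    acc <- if (is.null(acc)) term else acc + term
  }
  acc
}

# Full-space spin component (x/y/z) of one particle.
particle_spin <- function(system, index, axis) {
  embed_operator(spin_matrices(system$spins[index])[[axis]], index, system)
}

#' Singlet and triplet projection operators
#'
#' `P_S = 1/4 I - S1.S2` and `P_T = 3/4 I + S1.S2` on the full Hilbert space.
#' They are orthogonal idempotents with `P_S + P_T = I`; the singlet projector
#' has trace equal to the nuclear-space dimension.
#'
#' @param system a [spin_system()].
#' @return list with complex matrices `P_S` and `P_T`.
#' @export
projection_operators <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  dim <- hilbert_dimension(system)
  s1s2 <- two_site_dot(system, 1L, 2L)
  id <- diag(dim) + 0i
  list(P_S = id / 4 - s1s2, P_T = 3 * id / 4 + s1s2)
}

# Hermiticity guard used by the Hamiltonian builders.
assert_hermitian <- function(H, label = "Hamiltonian", rtol = 1e-12) {
  scale <- max(1, max(Mod(H)))
  if (max(Mod(H - Conj(t(H)))) > rtol * scale) {
    stop(label, " is not Hermitian within tolerance")
  }
  invisible(H)
}
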
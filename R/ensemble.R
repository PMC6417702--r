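# Orientation averaging over the cell ensemble and conversion of yields to
# observable product totals/fractions.

#' Orientation-averaging quadrature specification
#'
#' Euler-angle quadrature for averaging over all radical-pair orientations:
#' Gauss-Legendre nodes in cos(beta) (the sin(beta) measure absorbed in the
#' substitution) and uniform periodic rules in alpha and gamma. Weights are
#' normalized so that averaging the constant 1 returns 1.
#'
#' @param n_alpha,n_beta,n_gamma node counts (>= 1).
#' @param N number of radical pairs per cell times number of cells (scaling
#'   used by [total_yields()]).
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(n_alpha = 8, n_beta = 8, n_gamma = 8, N = 1) {
  stopifnot(n_alpha >= 1, n_beta >= 1, n_gamma >= 1, N > 0)
  structure(list(n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
                 n_gamma = as.integer(n_gamma), N = N),
            class = "ensemble_spec")
}

# quadrature nodes: data.frame(alpha, beta, gamma, weight), weights sum to 1
euler_quadrature <- function(spec) {
  if (spec$n_beta == 1) {
    beta <- pi / 2       # single-node Gauss-Legendre: midpoint of cos(beta)
    w_beta <- 1
  } else {
    gl <- pracma::gaussLegendre(spec$n_beta, -1, 1)
    beta <- acos(gl$x)
    w_beta <- gl$w / 2
  }
  alpha <- 2 * pi * (seq_len(spec$n_alpha) - 1) / spec$n_alpha
  gamma <- 2 * pi * (seq_len(spec$n_gamma) - 1) / spec$n_gamma
  grid <- expand.grid(alpha = alpha, beta = beta, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies alpha fastest, then beta, then gamma
  grid$weight <- rep(rep(w_beta, each = spec$n_alpha), times = spec$n_gamma) /
    (spec$n_alpha * spec$n_gamma)
  grid
}

#' Ensemble (orientation) average of the quantum yields
#'
#' `<Phi_S> = (1/8 pi^2) int Phi_S(Omega) sin(beta) dbeta dalpha dgamma`.
#' For systems whose internal interactions are all isotropic (scalar hyperfine
#' couplings and exchange only) the single-pair yields are independent of
#' orientation and the average equals the identity-orientation yield; the
#' quadrature is bypassed. With a dipolar term the yields are computed per
#' quadrature node: via the stationary Liouville solve when `B1 = 0` (the
#' laboratory Hamiltonian is then time-independent) or via truncated
#' laboratory-frame propagation otherwise.
#'
#' @param system a [spin_system()].
#' @param fields a [field_config()].
#' @param rates a [rate_set()].
#' @param spec an [ensemble_spec()].
#' @param method "auto" bypasses the quadrature for isotropic systems (their
#'   yields are orientation-independent); "quadrature" forces the full Euler
#'   integral, e.g. to verify the isotropy shortcut; "shortcut" requires an
#'   isotropic system.
#' @param t_end,dt propagation controls, only used for anisotropic systems
#'   with `B1 > 0` (defaults: 10 mean lifetimes, RF-resolving step).
#' @return list with `phi_S`, `phi_T`, `method` ("isotropic" or "quadrature"),
#'   `n_nodes`.
#' @export
orientation_average <- function(system, fields, rates, spec = ensemble_spec(),
                                method = c("auto", "shortcut", "quadrature"),
                                t_end = NULL, dt = NULL) {
  method <- match.arg(method)
  isotropic <- !has_dipolar(system)
  if (method == "shortcut" && !isotropic) {
    stop("the isotropy shortcut requires a system without a dipolar term")
  }
  if (isotropic && method != "quadrature") {
    y <- singlet_yield(system, fields, rates)
    return(list(phi_S = y$phi_S, phi_T = y$phi_T, method = "isotropic",
                n_nodes = 1L))
  }
  nodes <- euler_quadrature(spec)
  projectors <- projection_operators(system)
  acc_S <- 0
  acc_T <- 0
  for (i in seq_len(nrow(nodes))) {
    om <- orientation(nodes$alpha[i], nodes$beta[i], nodes$gamma[i])
    if (isotropic) {
      y <- singlet_yield(system, fields, rates, orient = om)
    } else if (fields$B1_uT == 0) {
      H <- total_hamiltonian(system, fields, om, t = 0)
      y <- yield_liouville_solve(H, rates, projectors)
    } else {
      kbar <- max(rates$kS, rates$kT, (rates$kS + rates$kT) / 2)
      te <- if (is.null(t_end)) 10 / kbar else t_end
      st <- if (is.null(dt)) 1 / (40 * max(fields$nu_MHz, 1) * 1e6) else dt
      traj <- propagate_lab_frame(system, fields, rates, te, st, om,
                                  record_every = 1000L)
      y <- list(phi_S = attr(traj, "yield_S"), phi_T = attr(traj, "yield_T"))
    }
    acc_S <- acc_S + nodes$weight[i] * y$phi_S
    acc_T <- acc_T + nodes$weight[i] * y$phi_T
  }
  list(phi_S = acc_S, phi_T = acc_T, method = "quadrature",
       n_nodes = nrow(nodes))
}

#' Total product yields and fractions
#'
#' Scales the ensemble-averaged quantum yields by the number of radical pairs
#' in the experiment, `N = N_RPs * N_cells`, and forms the observable product
#' fractions, which are independent of `N` and equal the averaged quantum
#' yields when `phi_S + phi_T = 1`.
#'
#' @param phi_S,phi_T ensemble-averaged quantum yields (`phi_S + phi_T > 0`).
#' @param N radical-pair count scaling (> 0).
#' @return list with `total_S`, `total_T`, `fraction_S`, `fraction_T`.
#' @export
total_yields <- function(phi_S, phi_T, N = 1) {
  stopifnot(N > 0, phi_S + phi_T > 0)
  total_S <- N * phi_S
  total_T <- N * phi_T
  list(total_S = total_S, total_T = total_T,
       fraction_S = total_S / (total_S + total_T),
       fraction_T = total_T / (total_S + total_T))
}
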
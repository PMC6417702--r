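# Configuration parsing, built-in presets and the command-line interface.
#
# Config files are YAML with explicit unit suffixes (a_mT, B0_uT, nu_MHz,
# kS_per_s) so that the mT/uT/MHz mix of the problem domain can never be
# confused silently. Unknown keys are rejected with their location.

.allowed_keys <- list(
  top = c("system", "fields", "rates", "scan", "ensemble", "outputs", "seed"),
  system = c("g", "eta_mT", "r_nm", "nuclei"),
  nucleus = c("label", "radical", "spin", "a_mT"),
  fields = c("B0_uT", "B1_uT", "nu_MHz", "phi_rad", "polarization"),
  rates = c("kS_per_s", "kT_per_s"),
  scan = c("nu_min_MHz", "nu_max_MHz", "nu_step_MHz", "B1_uT"),
  ensemble = c("n_alpha", "n_beta", "n_gamma", "N"),
  outputs = c("dir", "prefix")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("config error at '", where, "': unknown key(s) ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  invisible(TRUE)
}

need_num <- function(x, where, min = -Inf) {
  if (is.null(x) || !is.numeric(x) || !all(is.finite(x))) {
    stop("config error at '", where, "': a finite number is required")
  }
  if (any(x < min)) {
    stop("config error at '", where, "': must be >= ", min)
  }
  x
}

#' Assemble a validated run configuration
#'
#' @param system a [spin_system()].
#' @param fields a [field_config()].
#' @param rates a [rate_set()].
#' @param ensemble an [ensemble_spec()].
#' @param scan list with `nu_min_MHz`, `nu_max_MHz`, `nu_step_MHz` and
#'   optionally a `B1_uT` vector for frequency-amplitude maps.
#' @param seed integer, reserved (all core computations are deterministic).
#' @return a `run_config` object.
#' @export
run_config <- function(system, fields, rates, ensemble = ensemble_spec(),
                       scan = list(nu_min_MHz = 0, nu_max_MHz = 50,
                                   nu_step_MHz = 0.1),
                       seed = 1L) {
  stopifnot(inherits(system, "spin_system"), inherits(fields, "field_config"),
            inherits(rates, "rate_set"), inherits(ensemble, "ensemble_spec"))
  structure(list(system = system, fields = fields, rates = rates,
                 ensemble = ensemble, scan = scan, seed = as.integer(seed)),
            class = "run_config")
}

config_from_list <- function(raw, where = "config") {
  check_keys(raw, .allowed_keys$top, where)
  if (is.null(raw$system)) stop("config error at '", where, "': 'system' is required")
  check_keys(raw$system, .allowed_keys$system, paste0(where, ".system"))
  nuclei <- lapply(seq_along(raw$system$nuclei), function(i) {
    nd <- raw$system$nuclei[[i]]
    loc <- sprintf("%s.system.nuclei[%d]", where, i)
    check_keys(nd, .allowed_keys$nucleus, loc)
    if (is.null(nd$a_mT)) {
      stop("config error at '", loc, "': nucleus '",
           if (is.null(nd$label)) i else nd$label,
           "' is missing its hyperfine coupling a_mT")
    }
    nucleus(label = if (is.null(nd$label)) paste0("n", i) else nd$label,
            radical = need_num(nd$radical, paste0(loc, ".radical"), min = 1),
            spin = need_num(nd$spin, paste0(loc, ".spin")),
            a_mT = need_num(nd$a_mT, paste0(loc, ".a_mT")))
  })
  sys <- spin_system(
    nuclei = nuclei,
    g = if (is.null(raw$system$g)) c(2, 2) else
      need_num(raw$system$g, paste0(where, ".system.g")),
    eta_mT = if (is.null(raw$system$eta_mT)) 0 else
      need_num(raw$system$eta_mT, paste0(where, ".system.eta_mT")),
    r_nm = if (is.null(raw$system$r_nm)) NULL else
      need_num(raw$system$r_nm, paste0(where, ".system.r_nm")))
  f <- raw$fields
  check_keys(f, .allowed_keys$fields, paste0(where, ".fields"))
  fields <- field_config(
    B0_uT = need_num(f$B0_uT, paste0(where, ".fields.B0_uT"), min = 0),
    B1_uT = if (is.null(f$B1_uT)) 0 else
      need_num(f$B1_uT, paste0(where, ".fields.B1_uT"), min = 0),
    nu_MHz = if (is.null(f$nu_MHz)) 0 else
      need_num(f$nu_MHz, paste0(where, ".fields.nu_MHz"), min = 0),
    phi_rad = if (is.null(f$phi_rad)) 0 else
      need_num(f$phi_rad, paste0(where, ".fields.phi_rad")),
    polarization = if (is.null(f$polarization)) "circular" else f$polarization)
  r <- raw$rates
  check_keys(r, .allowed_keys$rates, paste0(where, ".rates"))
  rates <- rate_set(
    kS = need_num(r$kS_per_s, paste0(where, ".rates.kS_per_s"), min = 0),
    kT = if (is.null(r$kT_per_s)) {
      need_num(r$kS_per_s, paste0(where, ".rates.kS_per_s"), min = 0)
    } else need_num(r$kT_per_s, paste0(where, ".rates.kT_per_s"), min = 0))
  ens <- raw$ensemble
  if (!is.null(ens)) check_keys(ens, .allowed_keys$ensemble, paste0(where, ".ensemble"))
  ensemble <- ensemble_spec(
    n_alpha = if (is.null(ens$n_alpha)) 8 else ens$n_alpha,
    n_beta = if (is.null(ens$n_beta)) 8 else ens$n_beta,
    n_gamma = if (is.null(ens$n_gamma)) 8 else ens$n_gamma,
    N = if (is.null(ens$N)) 1 else ens$N)
  scan <- raw$scan
  if (!is.null(scan)) check_keys(scan, .allowed_keys$scan, paste0(where, ".scan"))
  if (is.null(scan)) scan <- list()
  scan_full <- list(
    nu_min_MHz = if (is.null(scan$nu_min_MHz)) 0 else scan$nu_min_MHz,
    nu_max_MHz = if (is.null(scan$nu_max_MHz)) 50 else scan$nu_max_MHz,
    nu_step_MHz = if (is.null(scan$nu_step_MHz)) 0.1 else scan$nu_step_MHz)
  if (!is.null(scan$B1_uT)) scan_full$B1_uT <- scan$B1_uT
  scan <- scan_full
  run_config(sys, fields, rates, ensemble, scan,
             seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Load and validate a YAML run configuration
#'
#' All quantities carry explicit unit suffixes; unknown keys and malformed
#' values are rejected with the offending location.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config_from_list(yaml::read_yaml(path), where = basename(path))
}

config_to_list <- function(cfg) {
  sysl <- list(
    g = cfg$system$g,
    eta_mT = cfg$system$eta_mT,
    nuclei = lapply(cfg$system$nuclei, function(n) {
      list(label = n$label, radical = n$radical, spin = n$spin, a_mT = n$a_mT)
    }))
  if (!is.null(cfg$system$r_nm)) sysl$r_nm <- cfg$system$r_nm
  list(system = sysl,
       fields = list(B0_uT = cfg$fields$B0_uT, B1_uT = cfg$fields$B1_uT,
                     nu_MHz = cfg$fields$nu_MHz, phi_rad = cfg$fields$phi_rad,
                     polarization = cfg$fields$polarization),
       rates = list(kS_per_s = cfg$rates$kS, kT_per_s = cfg$rates$kT),
       scan = cfg$scan[!vapply(cfg$scan, is.null, logical(1))],
       ensemble = list(n_alpha = cfg$ensemble$n_alpha,
                       n_beta = cfg$ensemble$n_beta,
                       n_gamma = cfg$ensemble$n_gamma, N = cfg$ensemble$N),
       seed = cfg$seed)
}

#' Write a run configuration to YAML
#'
#' Round-trips through [load_config()] to an identical configuration.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
preset_dump <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' Built-in model presets
#'
#' `two_nucleus`: the generic radical pair with one spin-1/2 nucleus per
#' radical; the second nucleus' coupling is fixed at `a2 = 1.0 mT`, `a1` is
#' the tunable coupling (default 0.5 mT). Defaults `kS = kT = 1e6 s^-1`,
#' `B0 = B1 = 50 uT`. `fad_superoxide`: a flavin-semiquinone/superoxide pair
#' with the 8 strongest-coupled FAD nuclei (N5, N10 spin-1; H6, 3 x H8,
#' 2 x Hbeta spin-1/2) on radical 1 and a bare superoxide as radical 2
#' (Hilbert dimension 2304). FAD hyperfine values are not built in and must be
#' supplied from the literature via `fad_couplings_mT`.
#'
#' @param name "two_nucleus" or "fad_superoxide".
#' @param a1_mT tunable coupling of the first nucleus (two_nucleus preset).
#' @param kS_per_s,kT_per_s rate constants, s^-1.
#' @param B0_uT,B1_uT,nu_MHz field settings.
#' @param eta_mT exchange field equivalent, mT.
#' @param fad_couplings_mT named numeric of length 8 with names
#'   N5, N10, H6, H8a, H8b, H8c, Hb1, Hb2 (fad_superoxide preset; required).
#' @return a `run_config`.
#' @export
preset <- function(name = c("two_nucleus", "fad_superoxide"), a1_mT = 0.5,
                   kS_per_s = 1e6, kT_per_s = kS_per_s, B0_uT = 50,
                   B1_uT = 50, nu_MHz = 0, eta_mT = 0,
                   fad_couplings_mT = NULL) {
  name <- match.arg(name)
  if (name == "two_nucleus") {
    sys <- spin_system(
      nuclei = list(nucleus("n1", 1L, 0.5, a1_mT),
                    nucleus("n2", 2L, 0.5, 1.0)),
      eta_mT = eta_mT)
  } else {
    labs <- c("N5", "N10", "H6", "H8a", "H8b", "H8c", "Hb1", "Hb2")
    if (is.null(fad_couplings_mT)) {
      stop("the fad_superoxide preset has no built-in hyperfine couplings: ",
           "supply literature values as fad_couplings_mT = c(",
           paste(labs, collapse = ", "), ")")
    }
    if (!all(labs %in% names(fad_couplings_mT))) {
      stop("fad_couplings_mT must be named with: ", paste(labs, collapse = ", "))
    }
    spins <- c(N5 = 1, N10 = 1, H6 = 0.5, H8a = 0.5, H8b = 0.5, H8c = 0.5,
               Hb1 = 0.5, Hb2 = 0.5)
    sys <- spin_system(
      nuclei = lapply(labs, function(l) {
        nucleus(l, 1L, spins[[l]], fad_couplings_mT[[l]])
      }),
      eta_mT = eta_mT)
  }
  run_config(sys,
             field_config(B0_uT = B0_uT, B1_uT = B1_uT, nu_MHz = nu_MHz),
             rate_set(kS_per_s, kT_per_s))
}

# ---- command-line interface -------------------------------------------------

cli_parse_args <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- argv[i + 1]
      i <- i + 2
    }
  }
  opts
}

cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) return(default)
  as.numeric(strsplit(as.character(opts[[key]]), ",")[[1]])
}

cli_config <- function(opts) {
  if (!is.null(opts$config)) return(load_config(opts$config))
  name <- if (is.null(opts$preset)) "two_nucleus" else opts$preset
  preset(name,
         a1_mT = cli_num(opts, "a1", 0.5),
         kS_per_s = cli_num(opts, "kS", 1e6),
         kT_per_s = cli_num(opts, "kT", cli_num(opts, "kS", 1e6)),
         B0_uT = cli_num(opts, "B0", 50),
         B1_uT = cli_num(opts, "B1", 50),
         eta_mT = cli_num(opts, "eta", 0))
}

cli_nu_grid <- function(cfg, opts) {
  seq(cli_num(opts, "nu-min", cfg$scan$nu_min_MHz),
      cli_num(opts, "nu-max", cfg$scan$nu_max_MHz),
      by = cli_num(opts, "nu-step", cfg$scan$nu_step_MHz))
}

#' Command-line entry point
#'
#' Subcommands: `spectrum` (RF action spectrum), `map` (frequency-amplitude
#' map), `resonances` (catalog of the B1 = 0 Hamiltonian), `yield` (quantum
#' yields at one field setting), `workflow` (screening verdict), `preset-dump`
#' (write a preset as an editable YAML config). Common flags: `--preset`,
#' `--config`, `--a1`, `--kS`, `--kT`, `--B0`, `--B1`, `--eta`, `--nu-min`,
#' `--nu-max`, `--nu-step`, `--nu-rf`, `--tau0`, `--tauR`, `--out`. All runs
#' are deterministic.
#'
#' A thin executable wrapper is installed at `exec/rfspin`.
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return integer exit status, 0 on success.
#' @export
run_cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0) stop(
      "usage: rfspin <spectrum|map|resonances|yield|workflow|preset-dump> [--flags]")
    cmd <- argv[1]
    opts <- cli_parse_args(argv[-1])
    out <- opts$out
    params_of <- function(cfg) list(
      command = cmd,
      g = cfg$system$g, eta_mT = cfg$system$eta_mT,
      nuclei = vapply(cfg$system$nuclei, function(n)
        sprintf("%s(r%d,s=%g,a=%gmT)", n$label, n$radical, n$spin, n$a_mT), ""),
      B0_uT = cfg$fields$B0_uT, B1_uT = cfg$fields$B1_uT,
      kS_per_s = cfg$rates$kS, kT_per_s = cfg$rates$kT,
      package = as.character(utils::packageVersion("rfspin")))
    if (cmd == "spectrum") {
      cfg <- cli_config(opts)
      sp <- action_spectrum(cfg$system, cfg$rates, cfg$fields$B0_uT,
                            cfg$fields$B1_uT, cli_nu_grid(cfg, opts))
      if (is.null(out)) out <- "spectrum.tsv"
      write_run_table(sp, out, params_of(cfg))
      message("wrote ", out, " (", nrow(sp), " grid points)")
    } else if (cmd == "map") {
      cfg <- cli_config(opts)
      b1s <- cli_num(opts, "B1", c(10, 50, 100))
      mp <- field_frequency_map(cfg$system, cfg$rates, cfg$fields$B0_uT, b1s,
                                cli_nu_grid(cfg, opts))
      if (is.null(out)) out <- "map.tsv"
      write_run_table(mp, out, params_of(cfg))
      message("wrote ", out)
    } else if (cmd == "resonances") {
      cfg <- cli_config(opts)
      H0 <- total_hamiltonian(cfg$system, field_config(cfg$fields$B0_uT, 0, 0))
      rc <- resonance_catalog(H0)
      print(rc)
      if (!is.null(out)) {
        write_run_table(data.frame(freq_MHz = rc$freq_MHz), out, params_of(cfg))
        write_run_table(rc$histogram, sub("(\\.[^.]*)?$", "_hist\\1", out),
                        params_of(cfg))
        message("wrote ", out)
      }
    } else if (cmd == "yield") {
      cfg <- cli_config(opts)
      nu <- cli_num(opts, "nu-rf", cfg$fields$nu_MHz)
      y <- singlet_yield(cfg$system,
                         field_config(cfg$fields$B0_uT, cfg$fields$B1_uT, nu),
                         cfg$rates)
      print(y)
      if (!is.null(out)) {
        write_run_table(data.frame(phi_S = y$phi_S, phi_T = y$phi_T,
                                   solver = y$solver), out, params_of(cfg))
      }
    } else if (cmd == "workflow") {
      cfg <- cli_config(opts)
      tau0 <- cli_num(opts, "tau0")
      tauR <- cli_num(opts, "tauR")
      nu <- cli_num(opts, "nu-rf", cfg$fields$nu_MHz)
      if (is.null(tau0)) {
        rep <- workflow_report(cfg$system,
                               field_config(cfg$fields$B0_uT, cfg$fields$B1_uT, nu),
                               cfg$rates, tau_R = tauR)
      } else {
        H0 <- total_hamiltonian(cfg$system, field_config(cfg$fields$B0_uT, 0, 0))
        a_all <- vapply(cfg$system$nuclei, `[[`, numeric(1), "a_mT")
        rep <- rf_verdict(tau_0 = tau0, tau_RF = tau_rf(cfg$fields$B1_uT),
                          nu_rf_MHz = nu, resonances = resonance_catalog(H0),
                          tau_R = tauR, eta_mT = cfg$system$eta_mT,
                          a_max_mT = if (length(a_all)) max(abs(a_all)) else Inf)
      }
      print(rep)
      if (!is.null(out)) {
        write_run_table(
          data.frame(verdict = rep$verdict,
                     reasons = paste(rep$reasons, collapse = ";"),
                     tau_0_s = rep$timescales$tau_0,
                     tau_RF_s = rep$timescales$tau_RF,
                     nearest_resonance_MHz = rep$nearest_resonance_MHz),
          out, params_of(cfg))
      }
      if (rep$verdict == "excluded") message("RF effect excluded: ",
                                             paste(rep$reasons, collapse = ", "))
    } else if (cmd == "preset-dump") {
      cfg <- cli_config(opts)
      if (is.null(out)) out <- "config.yaml"
      preset_dump(cfg, out)
      message("wrote ", out)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("rfspin error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
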
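# Force field: harmonic bonds, weak homopolymeric 12-6 Lennard-Jones with a
# reduced scale for inserted beads, and Debye-Hueckel screened electrostatics.
# The LJ is evaluated by default in the "as printed" form
#   U = eps [ (sigma/r)^12 - (sigma/r)^6 ]
# (no conventional factor 4); `lj_prefactor_mode = "standard_4eps"` multiplies
# by 4.  Nonbonded terms are truncated and energy-shifted to zero at their
# cutoffs; directly bonded (1-2) pairs are excluded from nonbonded sums.

#' Force-field parameter set
#'
#' All defaults are the model's published constants: bond constant
#' Kb = 20000 kJ nm^-2 mol^-1, equilibrium bond length r0 = 0.38 nm,
#' sigma = 1.0 nm, eps = 0.001 kJ/mol for ordinary pairs and
#' eps_insert = 1e-5 kJ/mol for any pair involving an inserted glycine,
#' Kcoulomb = 138.94 kJ mol^-1 nm e^-2 and dielectric constant 80.
#' The inverse Debye length `kappa` (nm^-1) defaults to 0 (no screening);
#' use [kappa_from_salt()] for a salt concentration.  `b_kappa` is the
#' salt-dependent prefactor of the screened Coulomb term (default 1; supply a
#' number or compute one externally if a different convention is needed).
#'
#' @param kb bond constant, kJ nm^-2 mol^-1.
#' @param r0 equilibrium bond length, nm.
#' @param sigma LJ length scale, nm.
#' @param eps LJ energy scale for ordinary pairs, kJ/mol.
#' @param eps_insert LJ energy scale for pairs involving an inserted bead,
#'   kJ/mol (must not exceed `eps`).
#' @param dielectric relative dielectric constant (dimensionless).
#' @param kcoulomb electric conversion factor, kJ mol^-1 nm e^-2.
#' @param kappa inverse Debye screening length, nm^-1.
#' @param b_kappa salt-dependent coefficient multiplying the screened
#'   Coulomb term (dimensionless).
#' @param r_cut_lj LJ cutoff, nm.
#' @param r_cut_dh Debye-Hueckel cutoff, nm.
#' @param lj_prefactor_mode `"as_printed"` (prefactor eps) or
#'   `"standard_4eps"` (prefactor 4 eps).
#' @param charge_mode `"charged"` evaluates electrostatics; `"no_charge"`
#'   zeroes the Debye-Hueckel term entirely.
#' @return an object of class `cg_forcefield` (a named list).
#' @export
#' @examples
#' ff <- force_field(kappa = kappa_from_salt(0.01))
force_field <- function(kb = 20000, r0 = 0.38, sigma = 1.0,
                        eps = 0.001, eps_insert = 1e-5,
                        dielectric = 80, kcoulomb = 138.94,
                        kappa = 0, b_kappa = 1,
                        r_cut_lj = 3.0, r_cut_dh = 3.5,
                        lj_prefactor_mode = c("as_printed", "standard_4eps"),
                        charge_mode = c("charged", "no_charge")) {
  lj_prefactor_mode <- match.arg(lj_prefactor_mode)
  charge_mode <- match.arg(charge_mode)
  stopifnot(kb > 0, r0 > 0, sigma > 0, eps >= 0, eps_insert >= 0,
            eps_insert <= eps, dielectric > 0, kcoulomb > 0, kappa >= 0,
            b_kappa > 0, r_cut_lj > 0, r_cut_dh > 0)
  structure(list(kb = kb, r0 = r0, sigma = sigma, eps = eps,
                 eps_insert = eps_insert, dielectric = dielectric,
                 kcoulomb = kcoulomb, kappa = kappa, b_kappa = b_kappa,
                 r_cut_lj = r_cut_lj, r_cut_dh = r_cut_dh,
                 lj_prefactor_mode = lj_prefactor_mode,
                 charge_mode = charge_mode),
            class = "cg_forcefield")
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("cg_forcefield: Kb=", x$kb, " r0=", x$r0, " sigma=", x$sigma,
      " eps=", x$eps, " eps_insert=", x$eps_insert, "\n  kappa=", x$kappa,
      " 1/nm, dielectric=", x$dielectric, ", LJ mode=", x$lj_prefactor_mode,
      ", charge mode=", x$charge_mode, "\n", sep = "")
  invisible(x)
}

#' Inverse Debye screening length from salt concentration
#'
#' kappa = 3.2 sqrt(C_salt) nm^-1 with C_salt in mol/L (the usual aqueous
#' room-temperature approximation).
#'
#' @param c_salt salt concentration, mol/L.
#' @return kappa in nm^-1.
#' @export
#' @examples
#' kappa_from_salt(0.01)  # 0.32, the 10 mM condition
kappa_from_salt <- function(c_salt) {
  if (any(c_salt < 0)) stop("negative salt concentration")
  3.2 * sqrt(c_salt)
}

#' Harmonic bond energy and force
#'
#' U(r) = Kb (r - r0)^2; the returned force is the scalar radial force
#' -dU/dr (positive = repulsive).
#'
#' @param r bond length(s), nm.
#' @param kb,r0 bond constant and equilibrium length.
#' @return list with `energy` (kJ/mol) and `force` (kJ/mol/nm).
#' @export
#' @examples
#' bond_energy_force(0.39)$energy  # 2.0
bond_energy_force <- function(r, kb = 20000, r0 = 0.38) {
  stopifnot(all(r > 0))
  list(energy = kb * (r - r0)^2, force = -2 * kb * (r - r0))
}

#' Lennard-Jones pair energy and force
#'
#' In `"as_printed"` mode U(r) = eps ((sigma/r)^12 - (sigma/r)^6);
#' `"standard_4eps"` multiplies by 4.  When `r_cut` is finite the potential is
#' truncated and shifted so U(r_cut) = 0.
#'
#' @param r pair distance(s), nm.
#' @param pair_eps energy scale for this pair (eps or eps_insert), kJ/mol.
#' @param sigma LJ length scale, nm.
#' @param mode prefactor convention.
#' @param r_cut cutoff in nm, or `Inf` for no truncation.
#' @return list with `energy` and `force` (-dU/dr).
#' @export
#' @examples
#' lj_energy_force(2^(1/6), 0.001, r_cut = Inf)$energy  # -0.00025
lj_energy_force <- function(r, pair_eps, sigma = 1.0,
                            mode = c("as_printed", "standard_4eps"),
                            r_cut = 3.0) {
  mode <- match.arg(mode)
  if (any(r < 1e-6)) stop("overlapping beads: pair distance below 1e-6 nm")
  pref <- if (mode == "standard_4eps") 4 * pair_eps else pair_eps
  u <- function(rr) {
    s6 <- (sigma / rr)^6
    pref * (s6 * s6 - s6)
  }
  e <- u(r)
  shift <- if (is.finite(r_cut)) u(r_cut) else 0
  s6 <- (sigma / r)^6
  f <- pref * (12 * s6 * s6 - 6 * s6) / r
  out_e <- ifelse(r < r_cut, e - shift, 0)
  out_f <- ifelse(r < r_cut, f, 0)
  list(energy = out_e, force = out_f)
}

#' Debye-Hueckel pair energy and force
#'
#' U(r) = Kcoulomb B(kappa) q_i q_j exp(-kappa r) / (dielectric r), truncated
#' and shifted at `r_cut`.  Zero-charge pairs return exactly zero.
#'
#' @param r pair distance(s), nm.
#' @param qi,qj charges in elementary units.
#' @param kappa inverse screening length, nm^-1.
#' @param dielectric relative dielectric constant.
#' @param kcoulomb electric conversion factor.
#' @param b_kappa salt-dependent coefficient.
#' @param r_cut cutoff, nm (`Inf` for none).
#' @return list with `energy` and `force` (-dU/dr).
#' @export
#' @examples
#' dh_energy_force(1, 1, 1, kappa = 0, r_cut = Inf)$energy  # 138.94/80
dh_energy_force <- function(r, qi, qj, kappa = 0, dielectric = 80,
                            kcoulomb = 138.94, b_kappa = 1, r_cut = 3.5) {
  if (any(r < 1e-6)) stop("overlapping beads: pair distance below 1e-6 nm")
  qq <- qi * qj
  pref <- kcoulomb * b_kappa * qq / dielectric
  u <- function(rr) pref * exp(-kappa * rr) / rr
  shift <- if (is.finite(r_cut)) u(r_cut) else 0
  e <- ifelse(r < r_cut & qq != 0, u(r) - shift, 0)
  f <- ifelse(r < r_cut & qq != 0,
              pref * exp(-kappa * r) * (kappa * r + 1) / r^2, 0)
  list(energy = e, force = f)
}

#' Total potential energy and per-bead forces
#'
#' Sums bonds, LJ and Debye-Hueckel terms over a periodic orthorhombic box
#' with the minimum-image convention.  Directly bonded pairs are excluded from
#' the nonbonded terms.  `method = "cell"` uses a cell-list neighbour search;
#' `method = "brute"` is the O(N^2) reference path with identical cutoffs.
#'
#' @param topology a `cg_topology`.
#' @param coords N x 3 coordinate matrix, nm (any image; wrapped internally).
#' @param params a [force_field()].
#' @param method `"cell"` or `"brute"`.
#' @return list with `energy` (total, kJ/mol), `components` (named: bond, lj,
#'   dh) and `forces` (N x 3, kJ/mol/nm).
#' @export
total_energy_forces <- function(topology, coords, params = force_field(),
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(topology, "cg_topology"), inherits(params, "cg_forcefield"),
            is.matrix(coords), ncol(coords) == 3L,
            nrow(coords) == nrow(topology$beads))
  res <- cpp_energy_forces(coords, topology$box,
                           as.integer(topology$beads$charge),
                           topology$beads$is_insert,
                           topology$bonds,
                           ff_vector(params),
                           method == "brute")
  names(res$components) <- c("bond", "lj", "dh")
  res
}

# pack a cg_forcefield into the numeric vector the C++ layer consumes
ff_vector <- function(p) {
  c(kb = p$kb, r0 = p$r0, sigma = p$sigma, eps = p$eps,
    eps_insert = p$eps_insert, dielectric = p$dielectric,
    kcoulomb = p$kcoulomb, kappa = p$kappa, b_kappa = p$b_kappa,
    r_cut_lj = p$r_cut_lj, r_cut_dh = p$r_cut_dh,
    lj4 = as.numeric(p$lj_prefactor_mode == "standard_4eps"),
    no_charge = as.numeric(p$charge_mode == "no_charge"))
}

#' Compare analytic forces with a numerical gradient
#'
#' Central-difference check of the analytic forces of [total_energy_forces()];
#' the standard validation that the force routines are the exact gradient of
#' the energy.
#'
#' @param topology,coords,params as in [total_energy_forces()].
#' @param h finite-difference step, nm.
#' @param n_beads number of beads to probe (all by default).
#' @return maximum relative deviation |F_analytic + dU/dx| / max|F|.
#' @export
check_forces <- function(topology, coords, params = force_field(),
                         h = 1e-5, n_beads = NULL) {
  ref <- total_energy_forces(topology, coords, params)
  idx <- seq_len(nrow(coords))
  if (!is.null(n_beads)) idx <- idx[seq_len(min(n_beads, length(idx)))]
  fscale <- max(abs(ref$forces), 1e-12)
  worst <- 0
  for (i in idx) {
    for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + h
      xm <- coords; xm[i, d] <- xm[i, d] - h
      g <- (total_energy_forces(topology, xp, params)$energy -
            total_energy_forces(topology, xm, params)$energy) / (2 * h)
      worst <- max(worst, abs(ref$forces[i, d] + g) / fscale)
    }
  }
  worst
}
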
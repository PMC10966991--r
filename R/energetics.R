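# Differentiable potential energy: R surface over the compiled kernels.
# The kernel returns analytic first derivatives w.r.t. coordinates (forces)
# and w.r.t. every trainable parameter channel; this file maps the per-atom
# channels onto the 108-entry parameter vector.

KB <- 0.00831446261815324  # Boltzmann constant, kJ/mol/K

# Parameter-vector slot ranges (fixed flattening order, see ff_params).
PV_SLOTS <- list(charge_scale = 1:16, lj_sigma = 17:31, lj_epsilon = 32:46,
                 torsion_k = 47:79, scale_14 = 80:81, gb_radius = 82:87,
                 gb_obc = 88:99, gb_screen = 100:103, gb_global = 104:108)

# Internal: assemble the pieces the kernel needs from a mol_system.
kernel_args <- function(system) {
  empty_b <- list(i = integer(0), j = integer(0), k = numeric(0),
                  r0 = numeric(0))
  empty_a <- list(i = integer(0), j = integer(0), k = integer(0),
                  kf = numeric(0), theta0 = numeric(0))
  empty_t <- list(i = integer(0), j = integer(0), k = integer(0),
                  l = integer(0), n = numeric(0), kf = numeric(0),
                  phase = numeric(0), bin = integer(0))
  list(
    bonds = if (is.null(system$bonds)) empty_b else as.list(system$bonds),
    angles = if (is.null(system$angles)) empty_a else as.list(system$angles),
    torsions = if (is.null(system$torsions)) empty_t
               else as.list(system$torsions)
  )
}

#' Evaluate the full potential with forces and parameter gradients
#'
#' Computes the energy breakdown (bond, angle, torsion, LJ, Coulomb, GB polar,
#' GB surface), the forces, and optionally the gradient of the total energy
#' with respect to the 108 trainable parameters.
#'
#' @param system A `mol_system`.
#' @param coords Optional coordinates overriding `system$coords` (nm).
#' @param kappa Debye-Huckel screening parameter (1/nm), default 0.7.
#' @param gb Include the Generalized-Born solvation term (default TRUE).
#' @param sa Include the surface-area term (default TRUE).
#' @param want_pgrad Also return the 108-entry parameter gradient.
#' @return A list with `energies` (named vector), `total`, `forces`
#'   (N x 3, kJ/mol/nm) and, when requested, `pgrad` (length 108).
#' @export
eval_potential <- function(system, coords = NULL, kappa = 0.7, gb = TRUE,
                           sa = TRUE, want_pgrad = FALSE) {
  X <- if (is.null(coords)) system$coords else coords
  ka <- kernel_args(system)
  reg <- system$registry
  out <- cpp_eval_potential(
    X, system$atoms$charge, system$type_index, reg$atom_types$sigma,
    reg$atom_types$epsilon, system$pairflag,
    ka$bonds, ka$angles, ka$torsions, 33L,
    system$gb_rho, system$gb_screen, system$gb_alpha, system$gb_beta,
    system$gb_gamma, system$radius_class, system$elem_class,
    unname(reg$gb$globals), kappa,
    reg$scale_14[["coulomb_14"]], reg$scale_14[["lj_14"]],
    gb, sa, want_pgrad)
  res <- list(energies = out$energies, total = sum(out$energies),
              forces = out$F)
  if (want_pgrad) res$pgrad <- map_param_gradient(system, out)
  res
}

# Precompute the pieces that map per-atom derivative channels onto the
# 108-entry vector: the charge-scale Jacobian (depends on the scalings, not
# on coordinates) and the trainable-LJ type slots.
pgrad_mapper <- function(system) {
  list(Jq = system_charge_jacobian(system),
       lj_slots = match(setdiff(FF_ATOM_TYPES, "HO"), FF_ATOM_TYPES))
}

# Map the kernel's derivative channels onto the 108-entry vector.
map_param_gradient <- function(system, out, mapper = NULL) {
  if (is.null(mapper)) mapper <- pgrad_mapper(system)
  g <- numeric(108L)
  # charges: chain dE/dq through the charge-conserving rescaling
  g[PV_SLOTS$charge_scale] <- as.numeric(crossprod(mapper$Jq, out$dq))
  # per-type LJ channels (HO has no trainable entry)
  g[PV_SLOTS$lj_sigma] <- out$dsig[mapper$lj_slots]
  g[PV_SLOTS$lj_epsilon] <- out$deps[mapper$lj_slots]
  g[PV_SLOTS$torsion_k] <- out$dk
  g[PV_SLOTS$scale_14] <- c(out$dc14, out$dl14)
  g[PV_SLOTS$gb_radius] <- out$d_radii
  g[PV_SLOTS$gb_obc] <- out$d_obc
  g[PV_SLOTS$gb_screen] <- out$d_screen
  g[PV_SLOTS$gb_global] <- out$d_globals
  g
}

# Stacked Jacobian of all per-atom charges w.r.t. the 16 charge scalings,
# block-diagonal over residues.  Depends on the scalings, not on coordinates.
system_charge_jacobian <- function(system) {
  reg <- system$registry
  scales <- stats::setNames(reg$atom_types$charge_scale, reg$atom_types$type)
  n <- nrow(system$atoms)
  J <- matrix(0, n, 16L)
  for (ri in unique(system$atoms$residue_index)) {
    sel <- system$atoms$residue_index == ri
    tmpl <- list(atoms = data.frame(type = system$atoms$type[sel],
                                    charge = system$atoms$base_charge[sel]),
                 formal_charge = system$formal_charges[[as.character(ri)]])
    J[sel, ] <- charge_scale_jacobian(tmpl, scales)
  }
  J
}

#' Bonded energy (bonds, angles, proper torsions)
#'
#' Harmonic bonds `k (r - r0)^2`, harmonic angles `k (theta - theta0)^2` and
#' periodic torsions `k (1 + cos(n phi - delta))`.
#'
#' @inheritParams eval_potential
#' @return Named numeric vector with components `bond`, `angle`, `torsion`.
#' @export
bonded_energy <- function(system, coords = NULL) {
  e <- eval_potential(system, coords, gb = FALSE)$energies
  e[c("bond", "angle", "torsion")]
}

#' Lennard-Jones energy over non-excluded pairs
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]` with Lorentz-Berthelot combining;
#' 1-4 pairs are multiplied by the trainable `lj_14` scaling; no cutoff.
#'
#' @inheritParams eval_potential
#' @param lj_14_scale Optional override for the 1-4 LJ scaling.
#' @return Energy (kJ/mol).
#' @export
lennard_jones_energy <- function(system, coords = NULL, lj_14_scale = NULL) {
  if (!is.null(lj_14_scale)) {
    system$registry$scale_14[["lj_14"]] <- lj_14_scale
  }
  unname(eval_potential(system, coords, gb = FALSE)$energies["lj"])
}

#' Coulomb energy over non-excluded pairs
#'
#' `ke qi qj / r` with `ke = 138.935458 kJ mol^-1 nm e^-2`; 1-4 pairs are
#' multiplied by the trainable `coulomb_14` scaling.  The vacuum term is
#' unscreened; solvent screening lives in the GB term.
#'
#' @inheritParams eval_potential
#' @param coulomb_14_scale Optional override for the 1-4 Coulomb scaling.
#' @return Energy (kJ/mol).
#' @export
coulomb_energy <- function(system, coords = NULL, coulomb_14_scale = NULL) {
  if (!is.null(coulomb_14_scale)) {
    system$registry$scale_14[["coulomb_14"]] <- coulomb_14_scale
  }
  unname(eval_potential(system, coords, gb = FALSE)$energies["coulomb"])
}

#' Effective Born radii
#'
#' Pairwise HCT descreening with per-element screening factors, the smooth
#' neck correction within the neck cutoff, intrinsic radii reduced by the
#' offset, and the tanh(alpha psi - beta psi^2 + gamma psi^3) rescaling.
#'
#' @inheritParams eval_potential
#' @return Numeric vector of per-atom effective radii (nm).
#' @export
born_radii <- function(system, coords = NULL) {
  X <- if (is.null(coords)) system$coords else coords
  cpp_born_radii(X, system$gb_rho, system$gb_screen, system$gb_alpha,
                 system$gb_beta, system$gb_gamma,
                 unname(system$registry$gb$globals))
}

#' Generalized-Born polar energy for given Born radii
#'
#' `E = -1/2 sum_ij ke (1/eps_p - exp(-kappa f)/eps_w) qi qj / f` with
#' `f = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))` and the i = j diagonal
#' included with `f = Ri`.  Solute dielectric 1, solvent dielectric 78.5.
#'
#' @param system A `mol_system` (supplies charges and coordinates).
#' @param radii Per-atom effective Born radii (nm).
#' @param kappa Debye-Huckel screening parameter (1/nm).
#' @param coords Optional coordinate override.
#' @return Energy (kJ/mol).
#' @export
gb_energy <- function(system, radii, kappa = 0.7, coords = NULL) {
  if (any(radii <= 0)) stop("Born radii must be positive", call. = FALSE)
  X <- if (is.null(coords)) system$coords else coords
  q <- system$atoms$charge
  ke <- 138.935458
  n <- length(q)
  e <- sum(-0.5 * ke * (1 - exp(-kappa * radii) / 78.5) * q^2 / radii)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      r2 <- colSums((t(X[j, , drop = FALSE]) - X[i, ])^2)
      f <- sqrt(r2 + radii[i] * radii[j] * exp(-r2 / (4 * radii[i] * radii[j])))
      e <- e + sum(-ke * (1 - exp(-kappa * f) / 78.5) * q[i] * q[j] / f)
    }
  }
  e
}

#' ACE-style surface-area energy
#'
#' `factor * sum_i 4 pi (rho_i + probe)^2 (rho_tilde_i / R_i)^6`, where
#' `rho_tilde` is the offset-reduced intrinsic radius and `R` the effective
#' Born radius; buried atoms (large R) contribute vanishingly.
#'
#' @param system A `mol_system`.
#' @param radii Per-atom effective Born radii (nm).
#' @param probe_radius Solvent probe radius (nm); defaults to the registry
#'   value.
#' @param surface_area_factor Energy per area (kJ/mol/nm^2); defaults to the
#'   registry value.
#' @return Energy (kJ/mol).
#' @export
surface_area_energy <- function(system, radii, probe_radius = NULL,
                                surface_area_factor = NULL) {
  gl <- system$registry$gb$globals
  if (is.null(probe_radius)) probe_radius <- gl[["probe_radius"]]
  if (is.null(surface_area_factor))
    surface_area_factor <- gl[["sa_factor"]]
  rt <- system$gb_rho - gl[["offset"]]
  sum(surface_area_factor * 4 * pi * (system$gb_rho + probe_radius)^2 *
        (rt / radii)^6)
}

#' Total potential energy breakdown
#'
#' @param system A `mol_system`.
#' @param params Optional `param_vector` applied before evaluation.
#' @param coords Optional coordinate override (nm).
#' @param kappa Debye-Huckel screening (1/nm).
#' @param want_pgrad Also return the parameter gradient.
#' @return List with `energies`, `total`, `forces`, and optionally `pgrad`.
#' @export
total_potential <- function(system, params = NULL, coords = NULL,
                            kappa = 0.7, want_pgrad = FALSE) {
  if (!is.null(params)) system <- apply_parameter_vector(system, params)
  eval_potential(system, coords, kappa = kappa, want_pgrad = want_pgrad)
}
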
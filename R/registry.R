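# Trainable force-field registry: 16 atom types, 13 proper-torsion keys,
# Generalized-Born parameters and the two 1-4 scalings.  Flattening the
# trainable content gives exactly 108 scalars:
#   16 charge scalings + 15 LJ sigma + 15 LJ epsilon (HO fixed at zero)
#   + 33 torsion amplitudes + 2 1-4 scalings
#   + 6 GB radii + 12 GB alpha/beta/gamma + 4 GB screening + 5 GB globals.

# The 16 atom types in scope, in registry order.
FF_ATOM_TYPES <- c("CA", "CT", "C", "C8", "C9", "N", "N3", "O", "O2", "OH",
                   "H", "H1", "HA", "HC", "HO", "HP")

#' Build the default force-field registry
#'
#' Assembles the embedded Amber-style defaults for the 16 atom types in scope,
#' the 13 proper-torsion keys (33 trainable amplitudes), the two 1-4
#' interaction scalings and the Generalized-Born (GBNeck2-style) parameter set,
#' together with the non-trainable content (bond/angle constants, residue
#' templates).  The hydroxyl hydrogen HO has its Lennard-Jones sigma and
#' epsilon fixed at zero and non-trainable, which is why the per-type
#' non-bonded block holds 46 rather than 48 trainable values.
#'
#' @return An object of class `ff_registry`: a list with elements
#'   `atom_types` (tibble: type, sigma nm, epsilon kJ/mol, charge_scale,
#'   element, mass amu), `torsion_types` (list of 13 keys with periodic
#'   terms), `scale_14` (coulomb_14, lj_14), `gb` (radii, obc coefficients,
#'   screening factors, globals), `bond_params`, `angle_params` and
#'   `residues` (templates with base partial charges and ideal internal
#'   coordinates).
#' @export
ff_registry <- function() {
  atom_types <- tibble::tibble(
    type = FF_ATOM_TYPES,
    element = c("C", "C", "C", "C", "C", "N", "N", "O", "O", "O",
                "H", "H", "H", "H", "H", "H"),
    mass = c(12.011, 12.011, 12.011, 12.011, 12.011, 14.007, 14.007,
             15.999, 15.999, 15.999,
             1.008, 1.008, 1.008, 1.008, 1.008, 1.008),
    sigma = c(0.339967, 0.339967, 0.339967, 0.339967, 0.339967,
              0.325000, 0.325000, 0.295992, 0.295992, 0.306647,
              0.106908, 0.247135, 0.259964, 0.264953, 0.000000, 0.195998),
    epsilon = c(0.359824, 0.457730, 0.359824, 0.457730, 0.457730,
                0.711280, 0.711280, 0.878640, 0.878640, 0.880314,
                0.065689, 0.065689, 0.062760, 0.065689, 0.000000, 0.065689),
    charge_scale = rep(1.0, 16L)
  )

  torsion_types <- list(
    list(key = "C-N-CT-C",   pattern = c("C", "N", "CT", "C"),
         terms = data.frame(n = 1:4, k = c(0.75, 1.50, 1.80, 0.40),
                            phase = c(0, pi, 0, pi))),
    list(key = "N-CT-C-N",   pattern = c("N", "CT", "C", "N"),
         terms = data.frame(n = 1:4, k = c(1.90, 2.50, 0.60, 0.30),
                            phase = c(0, pi, 0, pi))),
    list(key = "C-N-CT-CT",  pattern = c("C", "N", "CT", "CT"),
         terms = data.frame(n = 1:3, k = c(0.80, 1.20, 0.50),
                            phase = c(0, pi, 0))),
    list(key = "CT-CT-C-N",  pattern = c("CT", "CT", "C", "N"),
         terms = data.frame(n = 1:3, k = c(0.90, 1.00, 0.40),
                            phase = c(0, pi, 0))),
    list(key = "CT-C-N-CT",  pattern = c("CT", "C", "N", "CT"),
         terms = data.frame(n = 1:3, k = c(1.20, 10.46, 0.30),
                            phase = c(0, pi, 0))),
    list(key = "H-N-CT-X",   pattern = c("H", "N", "CT", "X"),
         terms = data.frame(n = 2:3, k = c(0.80, 0.65), phase = c(pi, 0))),
    list(key = "X-CT-C-O",   pattern = c("X", "CT", "C", "O"),
         terms = data.frame(n = 2:3, k = c(0.35, 0.80), phase = c(pi, 0))),
    list(key = "O-C-N-X",    pattern = c("O", "C", "N", "X"),
         terms = data.frame(n = c(2L, 1L), k = c(10.46, 0.90),
                            phase = c(pi, 0))),
    list(key = "X-CT-CT-X",  pattern = c("X", "CT", "CT", "X"),
         terms = data.frame(n = c(3L, 2L), k = c(0.6508, 0.20),
                            phase = c(0, pi))),
    list(key = "N-CT-CT-X",  pattern = c("N", "CT", "CT", "X"),
         terms = data.frame(n = c(3L, 1L), k = c(0.70, 0.40),
                            phase = c(0, 0))),
    list(key = "C-N-CT-H1",  pattern = c("C", "N", "CT", "H1"),
         terms = data.frame(n = c(3L, 1L), k = c(0.45, 0.20),
                            phase = c(0, 0))),
    list(key = "X-C-N-X",    pattern = c("X", "C", "N", "X"),
         terms = data.frame(n = c(2L, 1L), k = c(10.46, 0.50),
                            phase = c(pi, 0))),
    list(key = "X-CT-N-X",   pattern = c("X", "CT", "N", "X"),
         terms = data.frame(n = c(3L, 2L), k = c(0.40, 0.30),
                            phase = c(0, pi)))
  )

  # Generalized-Born parameter block (GBNeck2-style defaults).
  # Radius classes: H, HN (H bonded to N), C, N, O (hydroxyl), OC (carbonyl /
  # carboxylate oxygen).  obc rows and screening are keyed by element class.
  gb <- list(
    radii = c(H = 0.120, HN = 0.130, C = 0.170, N = 0.155,
              O = 0.152, OC = 0.140),
    obc = matrix(c(0.788440, 0.798699, 0.437334,
                   0.733756, 0.506378, 0.205844,
                   0.503364, 0.316828, 0.192915,
                   0.867814, 0.876635, 0.387882),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("H", "C", "N", "O"),
                                 c("alpha", "beta", "gamma"))),
    screen = c(H = 1.425952, C = 1.058554, N = 0.733599, O = 1.061039),
    globals = c(neck_cutoff = 0.68, neck_scale = 0.826836,
                offset = 0.0195141, probe_radius = 0.14,
                sa_factor = 28.3919551)
  )

  # Harmonic bond constants, E = k (r - r0)^2, k in kJ/mol/nm^2, r0 in nm.
  bond_params <- tibble::tibble(
    t1 = c("N",  "N3", "CT", "CT", "CT", "CT", "CT", "CT", "CT", "C",
           "C",  "C",  "CT", "OH"),
    t2 = c("H",  "H",  "N",  "N3", "H1", "HP", "HC", "CT", "C",  "O",
           "O2", "N",  "OH", "HO"),
    k  = c(181586, 181586, 141001, 153553, 142256, 142256, 142256,
           129704, 132633, 238488, 274470, 205016, 133888, 231375),
    r0 = c(0.1010, 0.1010, 0.1449, 0.1471, 0.1090, 0.1090, 0.1090,
           0.1526, 0.1522, 0.1229, 0.1250, 0.1335, 0.1410, 0.0960)
  )

  # Harmonic angle constants, E = k (theta - theta0)^2, k in kJ/mol/rad^2.
  # Specific triples first; fall back to a default keyed on the central type.
  angle_params <- list(
    specific = tibble::tibble(
      t1 = c("N", "CT", "N",  "CT", "CT", "O",  "O",  "C",  "C",  "CT"),
      tc = c("CT", "C", "CT", "C",  "C",  "C",  "C",  "N",  "N",  "OH"),
      t2 = c("C", "N",  "CT", "O",  "O2", "N",  "O2", "CT", "H",  "HO"),
      k  = c(263.6, 292.9, 334.7, 334.7, 292.9, 334.7, 334.7, 209.2,
             209.2, 230.1),
      theta0 = c(110.4, 116.6, 110.5, 120.8, 117.0, 122.9, 126.0,
                 121.7, 119.5, 108.5) * pi / 180
    ),
    default = tibble::tibble(
      tc = c("CT", "C", "N", "N3", "OH"),
      k  = c(209.2, 292.9, 209.2, 209.2, 230.1),
      theta0 = c(109.47, 120.0, 118.0, 109.47, 108.5) * pi / 180
    )
  )

  reg <- list(
    atom_types = atom_types,
    torsion_types = torsion_types,
    scale_14 = c(coulomb_14 = 1 / 1.2, lj_14 = 0.5),
    gb = gb,
    bond_params = bond_params,
    angle_params = angle_params,
    residues = residue_templates()
  )
  class(reg) <- "ff_registry"
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  at <- reg$atom_types
  stopifnot(identical(at$type, FF_ATOM_TYPES),
            all(at$sigma >= 0), all(at$epsilon >= 0),
            all(at$charge_scale > 0))
  if (at$sigma[at$type == "HO"] != 0 || at$epsilon[at$type == "HO"] != 0)
    stop("HO Lennard-Jones parameters must be fixed at zero", call. = FALSE)
  n_amp <- sum(vapply(reg$torsion_types, function(t) nrow(t$terms), 1L))
  if (n_amp != 33L)
    stop("torsion registry must carry exactly 33 trainable amplitudes, got ",
         n_amp, call. = FALSE)
  stopifnot(all(reg$gb$radii > 0),
            reg$gb$globals[["probe_radius"]] >= 0,
            length(reg$gb$radii) == 6L, length(reg$gb$obc) == 12L,
            length(reg$gb$screen) == 4L, length(reg$gb$globals) == 5L)
  for (rt in reg$residues) {
    if (abs(sum(rt$atoms$charge) - rt$formal_charge) > 1e-6)
      stop("template ", rt$name, " charges do not sum to its formal charge",
           call. = FALSE)
  }
  invisible(reg)
}

#' Flatten a registry into the 108-entry trainable parameter vector
#'
#' The flattening order is fixed: 16 charge scalings, 15 LJ sigma, 15 LJ
#' epsilon (type HO excluded from both LJ blocks), 33 torsion amplitudes in
#' key order, the Coulomb and LJ 1-4 scalings, 6 GB radii, 12 GB
#' alpha/beta/gamma coefficients, 4 GB screening factors and the 5 GB globals.
#'
#' @param registry An `ff_registry`.
#' @return A numeric vector of class `param_vector`, length 108, with
#'   attributes `labels` (category per entry), `names` (human-readable entry
#'   names) and `hydrogen` (TRUE for entries belonging to atom types whose
#'   name begins with H).
#' @export
ff_params <- function(registry) {
  at <- registry$atom_types
  lj_types <- setdiff(at$type, "HO")
  idx_lj <- match(lj_types, at$type)

  vals <- c(at$charge_scale,
            at$sigma[idx_lj],
            at$epsilon[idx_lj])
  labels <- c(rep("charge_scale", 16L), rep("lj_sigma", 15L),
              rep("lj_epsilon", 15L))
  nms <- c(paste0("charge_scale.", at$type),
           paste0("lj_sigma.", lj_types),
           paste0("lj_epsilon.", lj_types))
  hyd <- c(startsWith(at$type, "H"),
           startsWith(lj_types, "H"),
           startsWith(lj_types, "H"))

  for (tt in registry$torsion_types) {
    vals <- c(vals, tt$terms$k)
    labels <- c(labels, rep("torsion_k", nrow(tt$terms)))
    nms <- c(nms, paste0("torsion_k.", tt$key, ".n", tt$terms$n))
    hyd <- c(hyd, rep(FALSE, nrow(tt$terms)))
  }

  vals <- c(vals, registry$scale_14, registry$gb$radii,
            as.vector(t(registry$gb$obc)), registry$gb$screen,
            registry$gb$globals)
  labels <- c(labels, rep("scale_14", 2L), rep("gb_radius", 6L),
              rep("gb_obc", 12L), rep("gb_screen", 4L), rep("gb_global", 5L))
  nms <- c(nms, "scale_14.coulomb", "scale_14.lj",
           paste0("gb_radius.", names(registry$gb$radii)),
           paste0("gb_obc.", rep(rownames(registry$gb$obc), each = 3L), ".",
                  rep(colnames(registry$gb$obc), 4L)),
           paste0("gb_screen.", names(registry$gb$screen)),
           paste0("gb_global.", names(registry$gb$globals)))
  hyd <- c(hyd, rep(FALSE, 2L + 6L + 12L + 4L + 5L))

  structure(as.numeric(vals), labels = labels, names = nms, hydrogen = hyd,
            class = "param_vector")
}

#' Write a parameter vector back into a registry
#'
#' Inverse of [ff_params()]: `set_ff_params(reg, ff_params(reg))` returns an
#' identical registry, and flatten-apply-flatten is the identity.
#'
#' @param registry An `ff_registry`.
#' @param params A `param_vector` of length 108 in registry order.
#' @return The updated `ff_registry`.
#' @export
set_ff_params <- function(registry, params) {
  if (length(params) != 108L)
    stop("parameter vector must have length 108, got ", length(params),
         call. = FALSE)
  ref <- ff_params(registry)
  if (!is.null(names(params)) && !identical(names(params), names(ref)))
    stop("parameter vector labels do not match this registry", call. = FALSE)
  v <- as.numeric(params)
  at <- registry$atom_types
  lj_types <- setdiff(at$type, "HO")
  registry$atom_types$charge_scale <- v[1:16]
  registry$atom_types$sigma[match(lj_types, at$type)] <- v[17:31]
  registry$atom_types$epsilon[match(lj_types, at$type)] <- v[32:46]
  i <- 47L
  for (j in seq_along(registry$torsion_types)) {
    nk <- nrow(registry$torsion_types[[j]]$terms)
    registry$torsion_types[[j]]$terms$k <- v[i:(i + nk - 1L)]
    i <- i + nk
  }
  registry$scale_14[] <- v[80:81]
  registry$gb$radii[] <- v[82:87]
  registry$gb$obc[] <- matrix(v[88:99], nrow = 4, byrow = TRUE)
  registry$gb$screen[] <- v[100:103]
  registry$gb$globals[] <- v[104:108]
  registry
}

#' @export
print.param_vector <- function(x, ...) {
  tab <- table(attr(x, "labels"))
  cat("<param_vector> 108 trainable force-field parameters\n")
  for (nm in names(tab)) cat(sprintf("  %-13s %3d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Rescale the partial charges of one residue template
#'
#' Each atom's base charge is multiplied by its atom type's charge-scaling
#' value; the resulting drift in total residue charge is then removed by
#' subtracting from each atom an offset proportional to its share of the sum
#' of absolute scaled charges, so the residue's formal charge is conserved
#' exactly.
#'
#' @param template A residue template (element of `registry$residues`), or any
#'   list with `atoms` (data frame with `type`, `charge`) and `formal_charge`.
#' @param charge_scales Named numeric vector of per-type multipliers; every
#'   atom type present in the template must be named.
#' @return Numeric vector of final per-atom charges (e), summing to the
#'   template's formal charge.
#' @export
rescale_residue_charges <- function(template, charge_scales) {
  tys <- template$atoms$type
  miss <- setdiff(tys, names(charge_scales))
  if (length(miss))
    stop("no charge scale supplied for type(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  qp <- template$atoms$charge * charge_scales[tys]
  A <- sum(abs(qp))
  delta <- sum(qp) - template$formal_charge
  if (A == 0) {
    if (abs(delta) > 1e-12)
      stop("degenerate residue: all scaled charges zero but total charge ",
           "differs from the formal charge", call. = FALSE)
    return(as.numeric(qp))
  }
  as.numeric(qp - delta * abs(qp) / A)
}

# Jacobian of the final charges of one template w.r.t. the 16 charge scales.
# Returns n_atoms x 16 matrix in registry atom-type order.
charge_scale_jacobian <- function(template, charge_scales) {
  tys <- template$atoms$type
  q0 <- template$atoms$charge
  s <- charge_scales[tys]
  qp <- q0 * s
  A <- sum(abs(qp))
  delta <- sum(qp) - template$formal_charge
  n <- length(q0)
  J <- matrix(0, n, length(FF_ATOM_TYPES),
              dimnames = list(NULL, FF_ATOM_TYPES))
  if (A == 0) return(J)
  sg <- sign(qp)
  for (u in unique(tys)) {
    sel <- tys == u                      # atoms whose own scale is s_u
    dqp <- ifelse(sel, q0, 0)            # d qp_i / d s_u
    dA <- sum(sg[sel] * q0[sel])         # d A / d s_u
    dDelta <- sum(q0[sel])               # d delta / d s_u
    # q''_i = qp_i - delta * |qp_i| / A
    J[, u] <- dqp - dDelta * abs(qp) / A -
      delta * (sg * dqp * A - abs(qp) * dA) / A^2
  }
  J
}

#' Per-atom charges for a whole system under the current charge scalings
#'
#' Applies [rescale_residue_charges()] residue by residue.
#'
#' @param system A `mol_system` (see [build_system()]).
#' @param registry The `ff_registry` the system was built from.
#' @return Numeric vector of per-atom charges (e).
#' @export
system_charges <- function(system, registry) {
  scales <- stats::setNames(registry$atom_types$charge_scale,
                            registry$atom_types$type)
  q <- numeric(nrow(system$atoms))
  for (ri in unique(system$atoms$residue_index)) {
    sel <- system$atoms$residue_index == ri
    tmpl <- list(atoms = data.frame(type = system$atoms$type[sel],
                                    charge = system$atoms$base_charge[sel]),
                 formal_charge = system$formal_charges[[as.character(ri)]])
    q[sel] <- rescale_residue_charges(tmpl, scales)
  }
  q
}

#' Apply a parameter vector to a built system
#'
#' Recomputes everything in a `mol_system` that depends on the trainable
#' parameters: per-atom charges (via the charge-conserving rescaling),
#' per-atom LJ sigma/epsilon, per-term torsion amplitudes, the 1-4 scalings
#' and the per-atom GB parameters.  Non-trainable content (bonds, angles,
#' topology) is untouched.
#'
#' @param system A `mol_system` built with [build_system()].
#' @param params A `param_vector` (length 108).
#' @return The updated `mol_system`.
#' @export
apply_parameter_vector <- function(system, params) {
  reg <- set_ff_params(system$registry, params)
  refresh_system_parameters(system, reg)
}
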
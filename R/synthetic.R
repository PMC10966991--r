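# Synthetic fixtures: toy chains, analytic systems, self-generated reference
# statistics and aggregation fixtures.  Everything is generated in code and
# deterministic per seed, so no external downloads or binary fixtures are
# needed anywhere in the package.

#' Specification for a toy peptide chain
#'
#' @param n_residues Number of residues (>= 1).
#' @param geometry "extended" (phi = -135, psi = 135), "helical"
#'   (phi = -57, psi = -47) or "custom" (supply `phi`/`psi` in degrees).
#' @param sequence Optional residue-name vector (ALA/GLY/SER core names);
#'   default polyalanine.
#' @param seed Seed for the coordinate noise.
#' @param noise_amplitude Gaussian coordinate noise (nm); default 0.
#' @param phi,psi Backbone dihedrals in degrees for `geometry = "custom"`.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_residues, geometry = c("extended", "helical",
                                              "custom"),
                     sequence = NULL, seed = 1L, noise_amplitude = 0,
                     phi = NULL, psi = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 1, noise_amplitude >= 0)
  ang <- switch(geometry,
                extended = c(-135, 135),
                helical = c(-57, -47),
                custom = c(phi, psi))
  if (is.null(sequence)) sequence <- rep("ALA", n_residues)
  stopifnot(length(sequence) == n_residues)
  list(n_residues = as.integer(n_residues), geometry = geometry,
       sequence = sequence, seed = as.integer(seed),
       noise_amplitude = noise_amplitude, phi = ang[1], psi = ang[2])
}

#' Build a toy peptide chain as PDB text and a molecular system
#'
#' Generates an idealised (optionally noised) zwitterionic peptide from the
#' embedded templates, writes it as PDB text and builds the corresponding
#' `mol_system`.  Deterministic per seed.
#'
#' @param spec A `toy_spec`.
#' @param registry An `ff_registry`.
#' @param path Optional path to write the PDB file.
#' @return List with `system` (a `mol_system`), `pdb` (character vector of
#'   PDB lines) and `path` (if written).
#' @export
make_toy_chain <- function(spec, registry = ff_registry(), path = NULL) {
  seqn <- spec$sequence
  n <- length(seqn)
  if (n < 2)
    stop("toy chains need at least 2 residues (zwitterionic termini)",
         call. = FALSE)
  nm <- seqn
  nm[1] <- paste0("N", nm[1])
  nm[n] <- paste0("C", nm[n])
  ch <- build_ideal_coords(nm, phi = spec$phi * pi / 180,
                           psi = spec$psi * pi / 180,
                           templates = registry$residues)
  coords <- ch$coords
  if (spec$noise_amplitude > 0) {
    set.seed(spec$seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                           spec$noise_amplitude),
                              ncol = 3)
  }
  sys <- build_system(ch$atoms, coords, registry)
  tmp <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  write_pdb(sys, tmp)
  pdb_lines <- readLines(tmp)
  if (is.null(path)) unlink(tmp)
  list(system = sys, pdb = pdb_lines, path = if (!is.null(path)) path)
}

#' Reference distance statistics from a fast forward simulation
#'
#' Runs a plain (non-differentiable) simulation of the system under a stated
#' parameter vector and returns its distance statistics.  At desk scale this
#' stands in for the explicit-solvent reference trajectories: training then
#' matches the distance distributions of a different Hamiltonian, which
#' preserves the structure of the training problem and makes
#' parameter-recovery experiments closed-loop.
#'
#' @param system A `mol_system`.
#' @param params The parameter vector defining the reference Hamiltonian.
#' @param config A `sim_config`.
#' @param coords Optional starting coordinates (default: minimised system
#'   coordinates).
#' @param minimize_first Energy-minimise before simulating (default TRUE).
#' @return A `distance_stats` object.
#' @export
make_reference_stats <- function(system, params, config, coords = NULL,
                                 minimize_first = TRUE) {
  eng <- system_engine(system, params, kappa = config$kappa)
  if (is.null(coords)) coords <- eng$coords
  if (minimize_first) coords <- minimize(eng, coords = coords)$coords
  sim <- simulate_with_checkpoints(eng, config, coords = coords)
  simulation_statistics(sim, length(eng$ca_indices))
}

#' Rigid multi-peptide fixture for contact and oligomer tests
#'
#' Places rigid copies of a small idealised peptide at controlled
#' separations along a line (or at supplied centres).
#'
#' @param separation Centre-to-centre separation (nm) between consecutive
#'   copies.
#' @param n_peptides Number of copies.
#' @param box Optional cubic box length (nm), stored with the output.
#' @param centres Optional n x 3 matrix of copy centres overriding the
#'   linear placement.
#' @param n_residues Residues per peptide (default 2).
#' @return List with `coords` (stacked), `groups` (atom-index list),
#'   `box`, and `peptide` (the single-copy system).
#' @export
make_dimer_fixture <- function(separation, n_peptides = 2L, box = NULL,
                               centres = NULL, n_residues = 2L) {
  stopifnot(separation > 0, n_peptides >= 1)
  toy <- make_toy_chain(toy_spec(n_residues, "extended"))
  base <- toy$system$coords
  base <- sweep(base, 2, colMeans(base))
  ext <- max(dist(base))
  if (is.null(centres)) {
    centres <- cbind((seq_len(n_peptides) - 1) * separation, 0, 0)
  }
  if (n_peptides > 1) {
    dmin <- min(dist(centres))
    if (dmin < 1e-6 || (is.null(box) && dmin + 1e-9 < 1e-3))
      stop("overlapping peptide copies at requested separation",
           call. = FALSE)
  }
  na <- nrow(base)
  coords <- do.call(rbind, lapply(seq_len(n_peptides), function(i) {
    sweep(base, 2, -as.numeric(centres[i, ]))
  }))
  groups <- lapply(seq_len(n_peptides), function(i) (i - 1L) * na + seq_len(na))
  list(coords = coords, groups = groups, box = box, peptide = toy$system,
       extent = ext)
}
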
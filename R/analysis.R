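# Trajectory-analysis operators: radius of gyration, windowed RMSD with
# Kabsch superposition, ligand side-chain contact fractions and oligomer
# clustering by connected components.

#' Mass-weighted radius of gyration
#'
#' @param frame N x 3 coordinate matrix (nm).
#' @param masses Per-atom masses (amu); default equal masses.
#' @return Radius of gyration (nm).
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  stopifnot(n >= 1)
  if (is.null(masses)) masses <- rep(1, n)
  M <- sum(masses)
  if (M <= 0) stop("total mass must be positive", call. = FALSE)
  com <- colSums(frame * masses) / M
  sqrt(sum(masses * rowSums((frame - rep(com, each = n))^2)) / M)
}

# Kabsch least-squares rotation of P onto Q (both centred); returns rotated P.
kabsch_fit <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  P %*% (s$u %*% D %*% t(s$v))
}

# best-fit RMSD between two selections after Kabsch superposition
fit_rmsd <- function(P, Q) {
  Pr <- kabsch_fit(P, Q)
  Qc <- sweep(Q, 2, colMeans(Q))
  sqrt(mean(rowSums((Pr - Qc)^2)))
}

#' Window-smoothed best-fit RMSD to a reference frame
#'
#' Per frame, the Calpha (or supplied selection) coordinates are superposed
#' on the reference with the Kabsch rotation and the RMSD computed; the
#' returned series is the mean over a window extending `window` frames
#' either side of each frame, truncated at the trajectory edges.
#'
#' @param trajectory List of N x 3 coordinate matrices (nm).
#' @param reference Reference N x 3 matrix (same selection).
#' @param window Half-width in frames (default 10); 0 gives the plain
#'   per-frame RMSD.
#' @param sel Optional row selection (e.g. Calpha indices) applied to every
#'   frame and the reference.
#' @return Tibble with columns `frame`, `rmsd`, `rmsd_smooth` (nm).
#' @export
windowed_rmsd <- function(trajectory, reference, window = 10L, sel = NULL) {
  if (length(trajectory) < 1) stop("empty trajectory", call. = FALSE)
  if (!is.null(sel)) {
    trajectory <- lapply(trajectory, function(f) f[sel, , drop = FALSE])
    reference <- reference[sel, , drop = FALSE]
  }
  raw <- vapply(trajectory, fit_rmsd, 0, Q = reference)
  nfr <- length(raw)
  sm <- vapply(seq_len(nfr), function(t) {
    mean(raw[max(1, t - window):min(nfr, t + window)])
  }, 0)
  tibble::tibble(frame = seq_len(nfr), rmsd = raw, rmsd_smooth = sm)
}

# minimum-image displacement for a cubic box (box = NULL: plain Euclidean)
min_image_dist2 <- function(A, B, box = NULL) {
  # returns matrix of squared distances between rows of A and rows of B
  out <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) d <- d - box * round(d / box)
    out <- out + d * d
  }
  out
}

#' Fraction of frames in which a ligand contacts each residue side chain
#'
#' A contact is any frame in which the minimum distance between any ligand
#' atom and any heavy atom of the residue's side chain (the Calpha for
#' glycine) is strictly less than the cutoff.
#'
#' @param trajectory List of full-coordinate frames (nm).
#' @param ligand_atoms Integer indices of the ligand atoms.
#' @param residue_sets List (per residue) of integer side-chain heavy-atom
#'   indices (CA for glycine).
#' @param cutoff Contact cutoff (nm); default 0.6 (6 Angstrom).
#' @param box Optional cubic box length (nm) for minimum-image distances.
#' @return Tibble with columns `residue` (0-based) and `contact_fraction`.
#' @export
ligand_contact_fraction <- function(trajectory, ligand_atoms, residue_sets,
                                    cutoff = 0.6, box = NULL) {
  if (length(ligand_atoms) == 0) stop("empty ligand atom set", call. = FALSE)
  nfr <- length(trajectory)
  hits <- numeric(length(residue_sets))
  for (f in trajectory) {
    L <- f[ligand_atoms, , drop = FALSE]
    for (ri in seq_along(residue_sets)) {
      R <- f[residue_sets[[ri]], , drop = FALSE]
      if (min(min_image_dist2(L, R, box)) < cutoff^2)
        hits[ri] <- hits[ri] + 1
    }
  }
  tibble::tibble(residue = seq_along(residue_sets) - 1L,
                 contact_fraction = hits / nfr)
}

#' Oligomer sizes by single-linkage peptide clustering
#'
#' Peptides are nodes; an edge joins two peptides when any inter-peptide
#' atom pair is closer than the cutoff.  Connected components define
#' oligomers; sizes are returned largest first.
#'
#' @param frame Full coordinate matrix (nm).
#' @param groups List of disjoint integer atom-index vectors, one per
#'   peptide.
#' @param cutoff Contact cutoff (nm); default 0.4 (4 Angstrom).
#' @param box Optional cubic box length (nm).
#' @return List with `sizes` (decreasing component sizes) and `largest`.
#' @export
oligomer_sizes <- function(frame, groups, cutoff = 0.4, box = NULL) {
  np <- length(groups)
  stopifnot(np >= 1)
  if (anyDuplicated(unlist(groups)))
    stop("peptide atom groups overlap", call. = FALSE)
  edges <- integer(0)
  if (np > 1) {
    for (a in seq_len(np - 1)) {
      A <- frame[groups[[a]], , drop = FALSE]
      for (b in (a + 1):np) {
        B <- frame[groups[[b]], , drop = FALSE]
        if (min(min_image_dist2(A, B, box)) < cutoff^2)
          edges <- c(edges, a, b)
      }
    }
  }
  gr <- igraph::make_graph(edges, n = np, directed = FALSE)
  comp <- igraph::components(gr)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  list(sizes = sizes, largest = sizes[1])
}

#' Read a multi-model PDB trajectory
#'
#' @param path Path written by [write_pdb()] (or any multi-MODEL PDB).
#' @return List of N x 3 coordinate matrices (nm).
#' @export
read_pdb_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(f) {
    matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  })
}
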
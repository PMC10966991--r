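# Topology: building a molecular system from residue templates or a PDB file,
# including the bond graph, exclusion (1-2, 1-3) and 1-4 pair tables, torsion
# enumeration against the 13-key registry and per-atom GB class assignment.
#
# Atom indices are 1-based (R convention); residue indices are 0-based and
# contiguous.  PDB serial numbers are never trusted.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

# Place atom D at bond length r from C, angle theta (D-C-B) and dihedral chi
# (D-C-B-A), angles in radians.  Natural extension reference frame.
place_atom <- function(C, B, A, r, theta, chi) {
  bc <- C - B; bc <- bc / vnorm(bc)
  n <- vcross(B - A, bc)
  nn <- vnorm(n)
  if (nn < 1e-12) n <- vcross(c(1, 0, 0), bc) else n <- n / nn
  if (vnorm(n) < 1e-12) n <- vcross(c(0, 1, 0), bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  C + r * (d[1] * bc + d[2] * m + d[3] * n)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Resolve a residue name from a PDB or sequence to a template name, applying
# terminal variants at the chain ends.
resolve_template_name <- function(resnm, first, last, templates) {
  if (resnm %in% names(templates)) {
    nm <- resnm
  } else {
    nm <- resnm
  }
  if (first && !startsWith(nm, "N") && paste0("N", nm) %in% names(templates))
    nm <- paste0("N", nm)
  if (last && !startsWith(nm, "C") && paste0("C", nm) %in% names(templates))
    nm <- paste0("C", nm)
  if (!nm %in% names(templates))
    stop("no residue template for '", resnm, "'", call. = FALSE)
  nm
}

# Build idealised coordinates for a chain of template residues with the given
# backbone dihedrals (radians, recycled).  Returns list(atoms, coords) with
# atoms in template order.
build_ideal_coords <- function(res_names, phi = -2.356, psi = 2.356,
                               templates = residue_templates()) {
  nres <- length(res_names)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  atoms <- list(); coords <- list()
  pos <- list()  # named coordinates per residue
  for (i in seq_len(nres)) {
    tmpl <- templates[[res_names[i]]]
    cur <- list()
    if (i == 1L) {
      cur[["N"]] <- c(0, 0, 0)
      cur[["CA"]] <- c(0.1449, 0, 0)
      th <- 110.4 * pi / 180
      cur[["C"]] <- cur[["CA"]] + 0.1522 * c(-cos(th), sin(th), 0)
    }
    for (k in seq_len(nrow(tmpl$zmat))) {
      z <- tmpl$zmat[k, ]
      if (!is.null(cur[[z$atom]])) next
      ref <- function(nm) {
        if (startsWith(nm, "-")) pos[[i - 1L]][[substring(nm, 2)]]
        else cur[[nm]]
      }
      p1 <- ref(z$p1); p2 <- ref(z$p2); p3 <- ref(z$p3)
      if (is.null(p1) || is.null(p2) || is.null(p3)) {
        if (i == 1L && z$atom %in% c("N", "CA", "C")) next
        stop("unresolvable reference for atom ", z$atom, " of residue ", i)
      }
      chi <- z$chi * pi / 180 +
        switch(z$sym, phi = phi[i], psi = psi[i],
               psi_prev = psi[max(i - 1L, 1L)], 0)
      cur[[z$atom]] <- place_atom(p1, p2, p3, z$r, z$theta * pi / 180, chi)
    }
    pos[[i]] <- cur
    atoms[[i]] <- cbind(tmpl$atoms,
                        residue_index = i - 1L,
                        residue_name = tmpl$name)
    coords[[i]] <- do.call(rbind, cur[tmpl$atoms$name])
  }
  list(atoms = do.call(rbind, atoms), coords = do.call(rbind, coords))
}

#' Load a PDB file into atom records and coordinates
#'
#' Reads a PDB file (standard amino-acid residues covered by the embedded
#' templates), converts coordinates from Angstrom to nm, renumbers residues
#' contiguously from 0 and completes hydrogens that are missing from the file
#' using idealised template geometry.  Missing heavy atoms and unknown
#' residue names (including HETATM ligands without a template) are errors.
#'
#' @param path Path to a PDB file.
#' @param templates Residue template set (default: embedded templates).
#' @return A list with `atoms` (tibble: name, type, charge (base), residue
#'   index/name) and `coords` (N x 3 matrix, nm), in template atom order.
#' @export
load_pdb <- function(path, templates = residue_templates()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  het <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
  if (nrow(het) > 0)
    stop("no template for HETATM residue(s): ",
         paste(unique(het$resid), collapse = ", "), call. = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  rid <- paste(at$chain, at$resno, sep = ":")
  urid <- unique(rid)
  nres <- length(urid)

  atoms <- list(); coords <- list()
  placed <- list()
  for (i in seq_len(nres)) {
    sel <- rid == urid[i]
    resnm <- unique(at$resid[sel])[1]
    tnm <- resolve_template_name(resnm, i == 1L, i == nres, templates)
    tmpl <- templates[[tnm]]
    have <- at[sel, ]
    cur <- list()
    for (k in seq_len(nrow(have))) {
      nm <- trimws(have$elety[k])
      cur[[nm]] <- c(have$x[k], have$y[k], have$z[k]) / 10  # Angstrom -> nm
    }
    extra <- setdiff(names(cur), tmpl$atoms$name)
    if (length(extra))
      stop("atom(s) ", paste(extra, collapse = ", "), " of residue ", resnm,
           " (index ", i - 1L, ") not in template ", tnm, call. = FALSE)
    missing <- setdiff(tmpl$atoms$name, names(cur))
    heavy <- tmpl$atoms$name[!startsWith(tmpl$atoms$type, "H")]
    if (any(missing %in% heavy))
      stop("missing heavy atom(s) ",
           paste(intersect(missing, heavy), collapse = ", "),
           " in residue ", resnm, " (index ", i - 1L, ")", call. = FALSE)
    if (length(missing)) {
      # backbone dihedrals from the actual coordinates for placement
      phi_i <- psi_i <- psi_prev <- 0
      prev <- if (i > 1L) placed[[i - 1L]] else NULL
      if (!is.null(prev) && !is.null(prev[["C"]]))
        phi_i <- dihedral_angle(prev[["C"]], cur[["N"]], cur[["CA"]],
                                cur[["C"]])
      if (!is.null(cur[["O"]]))
        psi_i <- dihedral_angle(cur[["N"]], cur[["CA"]], cur[["C"]],
                                cur[["O"]]) - pi
      for (k in seq_len(nrow(tmpl$zmat))) {
        z <- tmpl$zmat[k, ]
        if (!z$atom %in% missing || !is.null(cur[[z$atom]])) next
        ref <- function(nm) {
          if (startsWith(nm, "-")) prev[[substring(nm, 2)]] else cur[[nm]]
        }
        p1 <- ref(z$p1); p2 <- ref(z$p2); p3 <- ref(z$p3)
        if (is.null(p1) || is.null(p2) || is.null(p3))
          stop("cannot place missing atom ", z$atom, " of residue ", resnm,
               call. = FALSE)
        chi <- z$chi * pi / 180 +
          switch(z$sym, phi = phi_i, psi = psi_i, psi_prev = psi_prev, 0)
        cur[[z$atom]] <- place_atom(p1, p2, p3, z$r, z$theta * pi / 180, chi)
      }
    }
    placed[[i]] <- cur
    atoms[[i]] <- cbind(tmpl$atoms, residue_index = i - 1L,
                        residue_name = tmpl$name)
    coords[[i]] <- do.call(rbind, cur[tmpl$atoms$name])
  }
  list(atoms = tibble::as_tibble(do.call(rbind, atoms)),
       coords = do.call(rbind, coords))
}

# breadth-first bond-graph distances from one atom, capped at maxd
bond_bfs <- function(adj, start, maxd = 3L) {
  dist <- rep(NA_integer_, length(adj))
  dist[start] <- 0L
  frontier <- start
  for (d in seq_len(maxd)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

match_torsion_key <- function(types, torsion_types) {
  pat_match <- function(pat, tys) {
    all(pat == "X" | pat == tys)
  }
  nwild <- vapply(torsion_types, function(t) sum(t$pattern == "X"), 1L)
  ord <- order(nwild, seq_along(torsion_types))
  for (j in ord) {
    pat <- torsion_types[[j]]$pattern
    if (pat_match(pat, types) || pat_match(pat, rev(types))) return(j)
  }
  0L
}

#' Build a molecular system from atom records and a registry
#'
#' Instantiates bonded terms from the residue templates and the registry's
#' bond/angle/torsion tables, derives exclusions (pairs within 2 bonds) and
#' 1-4 pairs (exactly 3 bonds apart) by breadth-first search over the bond
#' graph, assigns per-atom GB radius and element classes, and computes
#' charges with the charge-conserving rescaling.
#'
#' @param atoms Atom records as returned by [load_pdb()] (columns name, type,
#'   charge, residue_index, residue_name).
#' @param coords N x 3 coordinate matrix (nm).
#' @param registry An `ff_registry`.
#' @return An object of class `mol_system`.
#' @export
build_system <- function(atoms, coords, registry = ff_registry()) {
  atoms <- tibble::as_tibble(atoms)
  names(atoms)[names(atoms) == "charge"] <- "base_charge"
  n <- nrow(atoms)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  at_reg <- registry$atom_types
  ti <- match(atoms$type, at_reg$type)
  if (anyNA(ti))
    stop("unknown atom type(s): ",
         paste(unique(atoms$type[is.na(ti)]), collapse = ", "), call. = FALSE)
  atoms$element <- at_reg$element[ti]
  atoms$mass <- at_reg$mass[ti]

  # bond list: template bonds plus backbone links C(i)-N(i+1)
  templates <- registry$residues
  bonds_ij <- list()
  rids <- unique(atoms$residue_index)
  for (ri in rids) {
    sel <- which(atoms$residue_index == ri)
    tmpl <- templates[[atoms$residue_name[sel[1]]]]
    if (is.null(tmpl))
      stop("no template for residue ", atoms$residue_name[sel[1]],
           call. = FALSE)
    loc <- stats::setNames(sel, atoms$name[sel])
    for (b in tmpl$bonds) bonds_ij[[length(bonds_ij) + 1L]] <- unname(loc[b])
    if (ri > min(rids)) {
      prev <- which(atoms$residue_index == ri - 1L)
      ci <- prev[atoms$name[prev] == "C"]
      ni <- sel[atoms$name[sel] == "N"]
      if (length(ci) == 1L && length(ni) == 1L)
        bonds_ij[[length(bonds_ij) + 1L]] <- c(ci, ni)
      else
        warning("disconnected residue chain at residue index ", ri)
    }
  }
  bmat <- do.call(rbind, bonds_ij)
  if (any(is.na(bmat))) stop("template bond references missing atom")

  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(bmat))) {
    i <- bmat[k, 1]; j <- bmat[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }

  # bond parameters
  bp <- registry$bond_params
  bkey <- paste(pmin(bp$t1, bp$t2), pmax(bp$t1, bp$t2))
  qkey <- paste(pmin(atoms$type[bmat[, 1]], atoms$type[bmat[, 2]]),
                pmax(atoms$type[bmat[, 1]], atoms$type[bmat[, 2]]))
  bi <- match(qkey, bkey)
  if (anyNA(bi))
    stop("no bond parameters for type pair(s): ",
         paste(unique(qkey[is.na(bi)]), collapse = ", "), call. = FALSE)
  bonds <- tibble::tibble(i = bmat[, 1], j = bmat[, 2],
                          k = bp$k[bi], r0 = bp$r0[bi])

  # angles: all i-j-k paths
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (c_ in seq_len(ncol(cmb)))
      ang[[length(ang) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
  }
  amat <- do.call(rbind, ang)
  ap <- registry$angle_params
  akey_spec <- paste(pmin(ap$specific$t1, ap$specific$t2), ap$specific$tc,
                     pmax(ap$specific$t1, ap$specific$t2))
  aq <- paste(pmin(atoms$type[amat[, 1]], atoms$type[amat[, 3]]),
              atoms$type[amat[, 2]],
              pmax(atoms$type[amat[, 1]], atoms$type[amat[, 3]]))
  ai <- match(aq, akey_spec)
  di <- match(atoms$type[amat[, 2]], ap$default$tc)
  akf <- ifelse(is.na(ai), ap$default$k[di], ap$specific$k[ai])
  ath <- ifelse(is.na(ai), ap$default$theta0[di], ap$specific$theta0[ai])
  if (anyNA(akf))
    stop("no angle parameters for central type(s): ",
         paste(unique(atoms$type[amat[, 2]][is.na(akf)]), collapse = ", "),
         call. = FALSE)
  angles <- tibble::tibble(i = amat[, 1], j = amat[, 2], k = amat[, 3],
                           kf = akf, theta0 = ath)

  # torsions: all a-b-c-d paths over central bonds, matched to the 13 keys
  tor <- list()
  for (k in seq_len(nrow(bmat))) {
    b <- bmat[k, 1]; c_ <- bmat[k, 2]
    for (a in setdiff(adj[[b]], c_))
      for (d in setdiff(adj[[c_]], c(b, a)))
        tor[[length(tor) + 1L]] <- c(a, b, c_, d)
  }
  tq <- do.call(rbind, tor)
  # torsion bin bookkeeping: global slot index for each trainable amplitude
  nterms <- vapply(registry$torsion_types, function(t) nrow(t$terms), 1L)
  bin0 <- cumsum(c(0L, nterms))[seq_along(nterms)]
  trows <- list()
  for (krow in seq_len(nrow(tq))) {
    quad <- tq[krow, ]
    tys <- atoms$type[quad]
    key <- match_torsion_key(tys, registry$torsion_types)
    if (key == 0L) next
    terms <- registry$torsion_types[[key]]$terms
    trows[[length(trows) + 1L]] <- tibble::tibble(
      i = quad[[1]], j = quad[[2]], k = quad[[3]], l = quad[[4]],
      n = terms$n, kf = terms$k, phase = terms$phase,
      bin = bin0[key] + seq_len(nrow(terms)))
  }
  torsions <- do.call(rbind, trows)

  # exclusions (<=2 bonds) and 1-4 pairs (exactly 3 bonds)
  excl <- list(); p14 <- list()
  pairflag <- matrix(1L, n, n)
  diag(pairflag) <- 0L
  for (i in seq_len(n)) {
    d <- bond_bfs(adj, i, 3L)
    e <- which(!is.na(d) & d >= 1L & d <= 2L & seq_len(n) > i)
    f <- which(!is.na(d) & d == 3L & seq_len(n) > i)
    if (length(e)) excl[[length(excl) + 1L]] <- cbind(i, e)
    if (length(f)) p14[[length(p14) + 1L]] <- cbind(i, f)
    pairflag[i, e] <- 0L; pairflag[e, i] <- 0L
    pairflag[i, f] <- 2L; pairflag[f, i] <- 2L
  }
  exclusions <- do.call(rbind, excl)
  pairs_14 <- do.call(rbind, p14)

  # per-atom GB classes: radius class (H, HN, C, N, O, OC) and element class
  elem_class <- match(atoms$element, c("H", "C", "N", "O"))
  radius_class <- character(n)
  for (i in seq_len(n)) {
    radius_class[i] <- switch(
      atoms$element[i],
      H = if (any(atoms$element[adj[[i]]] == "N")) "HN" else "H",
      C = "C", N = "N",
      O = if (atoms$type[i] == "OH") "O" else "OC")
  }
  radius_class <- match(radius_class, names(registry$gb$radii))

  ca_indices <- vapply(rids, function(ri) {
    w <- which(atoms$residue_index == ri & atoms$name == "CA")
    if (length(w) != 1L) NA_integer_ else w
  }, 1L)

  formal_charges <- stats::setNames(
    lapply(rids, function(ri) {
      templates[[atoms$residue_name[atoms$residue_index == ri][1]]]$formal_charge
    }), as.character(rids))

  sys <- list(atoms = atoms, coords = coords, bonds = bonds, angles = angles,
              torsions = torsions, exclusions = exclusions,
              pairs_14 = pairs_14, pairflag = pairflag, adj = adj,
              ca_indices = ca_indices, formal_charges = formal_charges,
              elem_class = elem_class, radius_class = radius_class,
              registry = registry)
  class(sys) <- "mol_system"
  refresh_system_parameters(sys, registry)
}

# Recompute the parameter-dependent per-atom/per-term fields of a system from
# a registry (possibly carrying updated trainable values).
refresh_system_parameters <- function(system, registry) {
  at_reg <- registry$atom_types
  ti <- match(system$atoms$type, at_reg$type)
  system$sigma_i <- at_reg$sigma[ti]
  system$eps_i <- at_reg$epsilon[ti]
  system$type_index <- ti
  system$atoms$charge <- system_charges(system, registry)
  if (!is.null(system$torsions)) {
    flat_k <- unlist(lapply(registry$torsion_types, function(t) t$terms$k))
    system$torsions$kf <- flat_k[system$torsions$bin]
  }
  system$gb_rho <- unname(registry$gb$radii[system$radius_class])
  system$gb_screen <- unname(registry$gb$screen[system$elem_class])
  system$gb_alpha <- unname(registry$gb$obc[system$elem_class, "alpha"])
  system$gb_beta <- unname(registry$gb$obc[system$elem_class, "beta"])
  system$gb_gamma <- unname(registry$gb$obc[system$elem_class, "gamma"])
  system$registry <- registry
  system
}

#' @export
print.mol_system <- function(x, ...) {
  cat("<mol_system> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_index)), " residues, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      length(unique(x$torsions$bin)), " torsion keys in use\n", sep = "")
  invisible(x)
}

#' Write coordinates (or a trajectory) as a PDB file
#'
#' Writes one MODEL block per frame; the result round-trips through
#' [load_pdb()] and standard structure viewers.
#'
#' @param system A `mol_system`.
#' @param path Output path.
#' @param frames A single N x 3 matrix or a list of them (nm; written in
#'   Angstrom).  Defaults to the system's coordinates.
#' @export
write_pdb <- function(system, path, frames = NULL) {
  if (is.null(frames)) frames <- list(system$coords)
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  a <- system$atoms
  multi <- length(frames) > 1L
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    x <- frames[[f]] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      substr(sub("^[NC](ALA|GLY|SER)$", "\\1", a$residue_name), 1, 3),
      a$residue_index + 1L, x[, 1], x[, 2], x[, 3], a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
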
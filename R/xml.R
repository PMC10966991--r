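# Force-field XML export and import.  The dialect is self-contained:
# AtomTypes, Residues (base and final charges), HarmonicBondForce,
# HarmonicAngleForce, PeriodicTorsionForce, NonbondedForce (with the two 1-4
# scalings) and a GBParameters block.  Numbers are written with 17
# significant digits so export -> import round-trips the parameter vector
# exactly.  Harmonic constants follow this package's k (x - x0)^2 convention
# and are written as 2k in the XML's 0.5 k (x - x0)^2 convention.

fmt <- function(x) sprintf("%.17g", x)

#' Export a force-field registry as XML
#'
#' @param registry An `ff_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_forcefield_xml <- function(registry, path) {
  doc <- xml2::xml_new_root("ForceField", version = "1")
  at <- registry$atom_types
  nd <- xml2::xml_add_child(doc, "AtomTypes")
  for (k in seq_len(nrow(at))) {
    xml2::xml_add_child(nd, "Type", name = at$type[k],
                        element = at$element[k], mass = fmt(at$mass[k]))
  }
  nd <- xml2::xml_add_child(doc, "Residues")
  scales <- stats::setNames(at$charge_scale, at$type)
  for (tmpl in registry$residues) {
    rn <- xml2::xml_add_child(nd, "Residue", name = tmpl$name,
                              formal_charge = as.character(tmpl$formal_charge))
    final_q <- rescale_residue_charges(tmpl, scales)
    for (k in seq_len(nrow(tmpl$atoms))) {
      xml2::xml_add_child(rn, "Atom", name = tmpl$atoms$name[k],
                          type = tmpl$atoms$type[k],
                          charge = fmt(tmpl$atoms$charge[k]),
                          final_charge = fmt(final_q[k]))
    }
    for (b in tmpl$bonds)
      xml2::xml_add_child(rn, "Bond", from = b[1], to = b[2])
  }
  nd <- xml2::xml_add_child(doc, "HarmonicBondForce")
  bp <- registry$bond_params
  for (k in seq_len(nrow(bp)))
    xml2::xml_add_child(nd, "Bond", type1 = bp$t1[k], type2 = bp$t2[k],
                        length = fmt(bp$r0[k]), k = fmt(2 * bp$k[k]))
  nd <- xml2::xml_add_child(doc, "HarmonicAngleForce")
  sp <- registry$angle_params$specific
  for (k in seq_len(nrow(sp)))
    xml2::xml_add_child(nd, "Angle", type1 = sp$t1[k], typec = sp$tc[k],
                        type2 = sp$t2[k], angle = fmt(sp$theta0[k]),
                        k = fmt(2 * sp$k[k]))
  dp <- registry$angle_params$default
  for (k in seq_len(nrow(dp)))
    xml2::xml_add_child(nd, "AngleDefault", typec = dp$tc[k],
                        angle = fmt(dp$theta0[k]), k = fmt(2 * dp$k[k]))
  nd <- xml2::xml_add_child(doc, "PeriodicTorsionForce")
  for (tt in registry$torsion_types) {
    pn <- xml2::xml_add_child(nd, "Proper", key = tt$key,
                              type1 = tt$pattern[1], type2 = tt$pattern[2],
                              type3 = tt$pattern[3], type4 = tt$pattern[4])
    for (k in seq_len(nrow(tt$terms)))
      xml2::xml_add_child(pn, "Term",
                          periodicity = as.character(tt$terms$n[k]),
                          k = fmt(tt$terms$k[k]),
                          phase = fmt(tt$terms$phase[k]))
  }
  nd <- xml2::xml_add_child(
    doc, "NonbondedForce",
    coulomb14scale = fmt(registry$scale_14[["coulomb_14"]]),
    lj14scale = fmt(registry$scale_14[["lj_14"]]))
  for (k in seq_len(nrow(at)))
    xml2::xml_add_child(nd, "Atom", type = at$type[k],
                        sigma = fmt(at$sigma[k]),
                        epsilon = fmt(at$epsilon[k]),
                        charge_scale = fmt(at$charge_scale[k]))
  gb <- registry$gb
  nd <- xml2::xml_add_child(doc, "GBParameters")
  for (k in seq_along(gb$radii))
    xml2::xml_add_child(nd, "Radius", class = names(gb$radii)[k],
                        value = fmt(gb$radii[k]))
  for (r in rownames(gb$obc))
    xml2::xml_add_child(nd, "OBC", class = r,
                        alpha = fmt(gb$obc[r, "alpha"]),
                        beta = fmt(gb$obc[r, "beta"]),
                        gamma = fmt(gb$obc[r, "gamma"]))
  for (k in seq_along(gb$screen))
    xml2::xml_add_child(nd, "Screen", class = names(gb$screen)[k],
                        value = fmt(gb$screen[k]))
  gl <- xml2::xml_add_child(nd, "Globals")
  for (k in seq_along(gb$globals))
    xml2::xml_attr(gl, names(gb$globals)[k]) <- fmt(gb$globals[k])
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a force-field registry from XML
#'
#' Inverse of [export_forcefield_xml()]; export followed by import yields an
#' identical parameter vector.  Residue ideal internal coordinates (used
#' only for geometry building) are reattached from the embedded templates by
#' residue name.
#'
#' @param path Path to an XML file written by [export_forcefield_xml()].
#' @return An `ff_registry`.
#' @export
read_forcefield_xml <- function(path) {
  doc <- xml2::read_xml(path)
  reg <- ff_registry()
  num <- function(nodes, attr) as.numeric(xml2::xml_attr(nodes, attr))
  chr <- function(nodes, attr) xml2::xml_attr(nodes, attr)

  nb <- xml2::xml_find_all(doc, "./NonbondedForce/Atom")
  ti <- match(chr(nb, "type"), reg$atom_types$type)
  reg$atom_types$sigma[ti] <- num(nb, "sigma")
  reg$atom_types$epsilon[ti] <- num(nb, "epsilon")
  reg$atom_types$charge_scale[ti] <- num(nb, "charge_scale")
  nf <- xml2::xml_find_first(doc, "./NonbondedForce")
  reg$scale_14[["coulomb_14"]] <- as.numeric(xml2::xml_attr(nf, "coulomb14scale"))
  reg$scale_14[["lj_14"]] <- as.numeric(xml2::xml_attr(nf, "lj14scale"))

  props <- xml2::xml_find_all(doc, "./PeriodicTorsionForce/Proper")
  reg$torsion_types <- lapply(props, function(p) {
    terms <- xml2::xml_find_all(p, "./Term")
    list(key = xml2::xml_attr(p, "key"),
         pattern = vapply(paste0("type", 1:4),
                          function(a) xml2::xml_attr(p, a), ""),
         terms = data.frame(n = as.integer(num(terms, "periodicity")),
                            k = num(terms, "k"),
                            phase = num(terms, "phase")))
  })

  bn <- xml2::xml_find_all(doc, "./HarmonicBondForce/Bond")
  reg$bond_params <- tibble::tibble(t1 = chr(bn, "type1"),
                                    t2 = chr(bn, "type2"),
                                    k = num(bn, "k") / 2,
                                    r0 = num(bn, "length"))
  an <- xml2::xml_find_all(doc, "./HarmonicAngleForce/Angle")
  ad <- xml2::xml_find_all(doc, "./HarmonicAngleForce/AngleDefault")
  reg$angle_params <- list(
    specific = tibble::tibble(t1 = chr(an, "type1"), tc = chr(an, "typec"),
                              t2 = chr(an, "type2"), k = num(an, "k") / 2,
                              theta0 = num(an, "angle")),
    default = tibble::tibble(tc = chr(ad, "typec"), k = num(ad, "k") / 2,
                             theta0 = num(ad, "angle")))

  rad <- xml2::xml_find_all(doc, "./GBParameters/Radius")
  reg$gb$radii <- stats::setNames(num(rad, "value"), chr(rad, "class"))
  obc <- xml2::xml_find_all(doc, "./GBParameters/OBC")
  m <- matrix(c(num(obc, "alpha"), num(obc, "beta"), num(obc, "gamma")),
              ncol = 3, dimnames = list(chr(obc, "class"),
                                        c("alpha", "beta", "gamma")))
  reg$gb$obc <- m[c("H", "C", "N", "O"), ]
  sc <- xml2::xml_find_all(doc, "./GBParameters/Screen")
  reg$gb$screen <- stats::setNames(num(sc, "value"), chr(sc, "class"))
  gl <- xml2::xml_find_first(doc, "./GBParameters/Globals")
  for (nm in names(reg$gb$globals))
    reg$gb$globals[[nm]] <- as.numeric(xml2::xml_attr(gl, nm))

  emb <- residue_templates()
  res <- xml2::xml_find_all(doc, "./Residues/Residue")
  reg$residues <- stats::setNames(lapply(res, function(r) {
    nmr <- xml2::xml_attr(r, "name")
    atoms <- xml2::xml_find_all(r, "./Atom")
    bonds <- xml2::xml_find_all(r, "./Bond")
    list(name = nmr,
         formal_charge = as.integer(xml2::xml_attr(r, "formal_charge")),
         atoms = tibble::tibble(name = chr(atoms, "name"),
                                type = chr(atoms, "type"),
                                charge = num(atoms, "charge")),
         bonds = lapply(bonds, function(b) c(xml2::xml_attr(b, "from"),
                                             xml2::xml_attr(b, "to"))),
         zmat = if (!is.null(emb[[nmr]])) emb[[nmr]]$zmat)
  }), vapply(res, function(r) xml2::xml_attr(r, "name"), ""))
  validate_registry(reg)
  reg
}
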
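# Residue templates: atom names, atom types, base partial charges and ideal
# internal coordinates (Z-matrix style) used both to build toy chains and to
# complete hydrogens missing from input PDB files.
#
# Templates cover ALA, GLY and SER plus N-terminal (protonated amine, +1) and
# C-terminal (carboxylate, -1) variants generated programmatically.  The same
# atom type carries different base charges in different residues; charge
# scaling acts on these base values residue by residue.

# zmat columns: atom, p1 (bonded parent), p2 (angle ref), p3 (dihedral ref),
# r (nm), theta (deg), chi (deg), sym ("" | phi | psi | psi_prev).
# References prefixed "-" point at the previous residue.  The dihedral of the
# placed atom D is dihedral(D, p1, p2, p3) = chi + value(sym).
zrow <- function(atom, p1, p2, p3, r, theta, chi, sym = "") {
  data.frame(atom = atom, p1 = p1, p2 = p2, p3 = p3, r = r,
             theta = theta, chi = chi, sym = sym, stringsAsFactors = FALSE)
}

backbone_zmat <- function() {
  rbind(
    zrow("N",  "-C", "-CA", "-N", 0.1335, 116.6, 0,   "psi_prev"),
    zrow("CA", "N",  "-C",  "-CA", 0.1449, 121.7, 180, ""),
    zrow("C",  "CA", "N",   "-C",  0.1522, 110.4, 0,   "phi"),
    zrow("O",  "C",  "CA",  "N",   0.1229, 120.8, 180, "psi"),
    zrow("H",  "N",  "CA",  "C",   0.1010, 118.0, 180, "phi")
  )
}

residue_templates <- function() {
  ala <- list(
    name = "ALA", formal_charge = 0L,
    atoms = tibble::tibble(
      name = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
      type = c("N", "H", "CT", "H1", "CT", "HC", "HC", "HC", "C", "O"),
      charge = c(-0.4157, 0.2719, 0.0337, 0.0823, -0.1825,
                 0.0603, 0.0603, 0.0603, 0.5973, -0.5679)),
    bonds = list(c("N", "H"), c("N", "CA"), c("CA", "HA"), c("CA", "CB"),
                 c("CB", "HB1"), c("CB", "HB2"), c("CB", "HB3"),
                 c("CA", "C"), c("C", "O")),
    zmat = rbind(backbone_zmat(),
                 zrow("CB",  "CA", "N", "C", 0.1526, 110.5, 122.5),
                 zrow("HA",  "CA", "N", "C", 0.1090, 109.0, -119),
                 zrow("HB1", "CB", "CA", "N", 0.1090, 109.5, 60),
                 zrow("HB2", "CB", "CA", "N", 0.1090, 109.5, 180),
                 zrow("HB3", "CB", "CA", "N", 0.1090, 109.5, 300))
  )
  gly <- list(
    name = "GLY", formal_charge = 0L,
    atoms = tibble::tibble(
      name = c("N", "H", "CA", "HA2", "HA3", "C", "O"),
      type = c("N", "H", "CT", "H1", "H1", "C", "O"),
      charge = c(-0.4157, 0.2719, -0.0252, 0.0698, 0.0698,
                 0.5973, -0.5679)),
    bonds = list(c("N", "H"), c("N", "CA"), c("CA", "HA2"), c("CA", "HA3"),
                 c("CA", "C"), c("C", "O")),
    zmat = rbind(backbone_zmat(),
                 zrow("HA2", "CA", "N", "C", 0.1090, 109.0, 119),
                 zrow("HA3", "CA", "N", "C", 0.1090, 109.0, -119))
  )
  ser <- list(
    name = "SER", formal_charge = 0L,
    atoms = tibble::tibble(
      name = c("N", "H", "CA", "HA", "CB", "HB2", "HB3", "OG", "HG",
               "C", "O"),
      type = c("N", "H", "CT", "H1", "CT", "H1", "H1", "OH", "HO",
               "C", "O"),
      charge = c(-0.4157, 0.2719, -0.0249, 0.0843, 0.2117,
                 0.0352, 0.0352, -0.6546, 0.4275, 0.5973, -0.5679)),
    bonds = list(c("N", "H"), c("N", "CA"), c("CA", "HA"), c("CA", "CB"),
                 c("CB", "HB2"), c("CB", "HB3"), c("CB", "OG"),
                 c("OG", "HG"), c("CA", "C"), c("C", "O")),
    zmat = rbind(backbone_zmat(),
                 zrow("CB",  "CA", "N", "C", 0.1526, 110.5, 122.5),
                 zrow("HA",  "CA", "N", "C", 0.1090, 109.0, -119),
                 zrow("OG",  "CB", "CA", "N", 0.1410, 110.5, 180),
                 zrow("HB2", "CB", "CA", "N", 0.1090, 109.5, 60),
                 zrow("HB3", "CB", "CA", "N", 0.1090, 109.5, 300),
                 zrow("HG",  "OG", "CB", "CA", 0.0960, 108.5, 180))
  )
  base <- list(ALA = ala, GLY = gly, SER = ser)
  out <- base
  for (nm in names(base)) {
    out[[paste0("N", nm)]] <- nterminal_variant(base[[nm]])
    out[[paste0("C", nm)]] <- cterminal_variant(base[[nm]])
  }
  out
}

# Protonated N-terminal variant: NH3+ (type N3, three type-H hydrogens),
# alpha hydrogens become HP (H on C adjacent to a charged nitrogen).  The
# nitrogen's base charge absorbs the +1 formal charge exactly.
nterminal_variant <- function(tmpl) {
  a <- tmpl$atoms
  hrow <- which(a$name == "H")
  a$type[a$name == "N"] <- "N3"
  a$type[a$name %in% c("HA", "HA2", "HA3")] <- "HP"
  h3 <- tibble::tibble(name = c("H1", "H2", "H3"), type = "H", charge = 0.26)
  a <- rbind(a[seq_len(hrow - 1L), ], h3, a[-seq_len(hrow), ])
  nrow_ <- which(a$name == "N")
  a$charge[nrow_] <- 0
  a$charge[nrow_] <- 1 - sum(a$charge)
  bonds <- Filter(function(b) !identical(sort(b), sort(c("N", "H"))),
                  tmpl$bonds)
  bonds <- c(list(c("N", "H1"), c("N", "H2"), c("N", "H3")), bonds)
  zm <- tmpl$zmat[!tmpl$zmat$atom %in% "H", ]
  zm <- rbind(zm,
              zrow("H1", "N", "CA", "C", 0.1010, 109.47, 60),
              zrow("H2", "N", "CA", "C", 0.1010, 109.47, 180),
              zrow("H3", "N", "CA", "C", 0.1010, 109.47, 300))
  list(name = paste0("N", tmpl$name), formal_charge = 1L, atoms = a,
       bonds = bonds, zmat = zm)
}

# Deprotonated C-terminal variant: carboxylate with O/OXT of type O2; the
# alpha carbon's base charge absorbs the -1 formal charge exactly.
cterminal_variant <- function(tmpl) {
  a <- tmpl$atoms
  a$type[a$name == "O"] <- "O2"
  a$charge[a$name == "O"] <- -0.7555
  a$charge[a$name == "C"] <- 0.5366
  a <- rbind(a, tibble::tibble(name = "OXT", type = "O2", charge = -0.7555))
  carow <- which(a$name == "CA")
  a$charge[carow] <- 0
  a$charge[carow] <- -1 - sum(a$charge)
  bonds <- c(tmpl$bonds, list(c("C", "OXT")))
  zm <- rbind(tmpl$zmat,
              zrow("OXT", "C", "CA", "N", 0.1250, 117.0, 0, "psi"))
  zm$r[zm$atom == "O"] <- 0.1250
  list(name = paste0("C", tmpl$name), formal_charge = -1L, atoms = a,
       bonds = bonds, zmat = zm)
}
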
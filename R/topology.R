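# Covalent topology and ideal internal coordinates for the 20 standard amino
# acids: heavy-atom z-matrices for the torsion-driven builder, heavy-atom bond
# lists, proton inventories (IUPAC/BMRB names) with their parent heavy atoms,
# and the sp2 flags that drive planar hydrogen placement.
#
# Dihedral column: "x1".."x4" are sidechain chi torsions, optionally with a
# branch offset ("x1-122"); plain numbers are fixed (ring / sp2) torsions.

.topo_env <- new.env(parent = emptyenv())

zrow <- function(name, parent, bref, aref, r, theta, dih) {
  data.frame(name = name, parent = parent, bref = bref, aref = aref,
             r = r, theta = theta, dih = dih, stringsAsFactors = FALSE)
}

# The CB improper torsion (C-N-CA-CB = -122.5) gives L-amino acids under
# the CORN rule; HA then completes the CA tetrahedron automatically.
sidechain_zmat <- function(resname) {
  cb <- zrow("CB", "CA", "N", "C", 1.53, 110.5, "-122.5")
  sc <- switch(resname,
    ALA = cb,
    ARG = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 114.1, "x1"),
      zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, "x2"),
      zrow("NE",  "CD", "CG", "CB", 1.46, 112.0, "x3"),
      zrow("CZ",  "NE", "CD", "CG", 1.33, 124.2, "x4"),
      zrow("NH1", "CZ", "NE", "CD", 1.33, 120.0, "0"),
      zrow("NH2", "CZ", "NE", "CD", 1.33, 120.0, "180")),
    ASN = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 112.6, "x1"),
      zrow("OD1", "CG", "CB", "CA", 1.23, 120.8, "x2"),
      zrow("ND2", "CG", "CB", "CA", 1.33, 116.4, "x2+180")),
    ASP = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 112.6, "x1"),
      zrow("OD1", "CG", "CB", "CA", 1.25, 118.4, "x2"),
      zrow("OD2", "CG", "CB", "CA", 1.25, 118.4, "x2+180")),
    CYS = rbind(cb,
      zrow("SG",  "CB", "CA", "N",  1.81, 113.8, "x1")),
    GLN = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 114.1, "x1"),
      zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, "x2"),
      zrow("OE1", "CD", "CG", "CB", 1.23, 120.8, "x3"),
      zrow("NE2", "CD", "CG", "CB", 1.33, 116.4, "x3+180")),
    GLU = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 114.1, "x1"),
      zrow("CD",  "CG", "CB", "CA", 1.52, 112.6, "x2"),
      zrow("OE1", "CD", "CG", "CB", 1.25, 118.4, "x3"),
      zrow("OE2", "CD", "CG", "CB", 1.25, 118.4, "x3+180")),
    GLY = NULL,
    HIS = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.50, 113.8, "x1"),
      zrow("ND1", "CG", "CB", "CA", 1.38, 122.7, "x2"),
      zrow("CD2", "CG", "CB", "CA", 1.36, 129.7, "x2+180"),
      zrow("CE1", "ND1", "CG", "CB", 1.32, 109.0, "180"),
      zrow("NE2", "CD2", "CG", "CB", 1.37, 107.0, "180")),
    ILE = rbind(cb,
      zrow("CG1", "CB", "CA", "N",  1.53, 110.4, "x1"),
      zrow("CG2", "CB", "CA", "N",  1.53, 110.5, "x1-122"),
      zrow("CD1", "CG1", "CB", "CA", 1.52, 113.8, "x2")),
    LEU = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.53, 116.3, "x1"),
      zrow("CD1", "CG", "CB", "CA", 1.52, 110.7, "x2"),
      zrow("CD2", "CG", "CB", "CA", 1.52, 110.7, "x2+122")),
    LYS = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 114.1, "x1"),
      zrow("CD",  "CG", "CB", "CA", 1.52, 111.3, "x2"),
      zrow("CE",  "CD", "CG", "CB", 1.52, 111.3, "x3"),
      zrow("NZ",  "CE", "CD", "CG", 1.49, 112.0, "x4")),
    MET = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.52, 114.1, "x1"),
      zrow("SD",  "CG", "CB", "CA", 1.81, 112.7, "x2"),
      zrow("CE",  "SD", "CG", "CB", 1.79, 100.8, "x3")),
    PHE = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.51, 113.8, "x1"),
      zrow("CD1", "CG", "CB", "CA", 1.39, 120.7, "x2"),
      zrow("CD2", "CG", "CB", "CA", 1.39, 120.7, "x2+180"),
      zrow("CE1", "CD1", "CG", "CB", 1.39, 120.7, "180"),
      zrow("CE2", "CD2", "CG", "CB", 1.39, 120.7, "180"),
      zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, "0")),
    PRO = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.50, 104.5, "x1"),
      zrow("CD",  "CG", "CB", "CA", 1.51, 105.5, "x2")),
    SER = rbind(cb,
      zrow("OG",  "CB", "CA", "N",  1.42, 110.8, "x1")),
    THR = rbind(cb,
      zrow("OG1", "CB", "CA", "N",  1.43, 109.6, "x1"),
      zrow("CG2", "CB", "CA", "N",  1.53, 110.5, "x1-122")),
    TRP = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.50, 113.6, "x1"),
      zrow("CD1", "CG", "CB", "CA", 1.37, 126.9, "x2"),
      zrow("CD2", "CG", "CB", "CA", 1.43, 126.6, "x2+180"),
      zrow("NE1", "CD1", "CG", "CB", 1.38, 110.2, "180"),
      zrow("CE2", "CD2", "CG", "CB", 1.41, 107.2, "180"),
      zrow("CE3", "CD2", "CG", "CB", 1.40, 133.9, "0"),
      zrow("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, "180"),
      zrow("CZ3", "CE3", "CD2", "CG", 1.39, 118.6, "180"),
      zrow("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, "0")),
    TYR = rbind(cb,
      zrow("CG",  "CB", "CA", "N",  1.51, 113.8, "x1"),
      zrow("CD1", "CG", "CB", "CA", 1.39, 120.7, "x2"),
      zrow("CD2", "CG", "CB", "CA", 1.39, 120.7, "x2+180"),
      zrow("CE1", "CD1", "CG", "CB", 1.39, 120.7, "180"),
      zrow("CE2", "CD2", "CG", "CB", 1.39, 120.7, "180"),
      zrow("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, "0"),
      zrow("OH",  "CZ", "CE1", "CD1", 1.38, 119.9, "180")),
    VAL = rbind(cb,
      zrow("CG1", "CB", "CA", "N",  1.53, 110.5, "x1"),
      zrow("CG2", "CB", "CA", "N",  1.53, 110.5, "x1-122")),
    data_error(sprintf("unknown residue type: %s", resname),
               class = "rpfdp_unknown_residue"))
  sc
}

# Extra ring-closure bonds not implied by the z-matrix parent links.
ring_closure_bonds <- function(resname) {
  switch(resname,
    HIS = matrix(c("CE1", "NE2"), ncol = 2, byrow = TRUE),
    PHE = matrix(c("CE2", "CZ"), ncol = 2, byrow = TRUE),
    TYR = matrix(c("CE2", "CZ"), ncol = 2, byrow = TRUE),
    TRP = matrix(c("NE1", "CE2", "CD2", "CE2", "CZ3", "CH2"),
                 ncol = 2, byrow = TRUE),
    PRO = matrix(c("CD", "N"), ncol = 2, byrow = TRUE),
    NULL)
}

proton_table <- function(resname) {
  p <- function(name, parent) data.frame(name = name, parent = parent,
                                         stringsAsFactors = FALSE)
  bb <- if (resname == "PRO") NULL else p("H", "N")
  ha <- if (resname == "GLY") p(c("HA2", "HA3"), "CA") else p("HA", "CA")
  hb2 <- p(c("HB2", "HB3"), "CB")
  sc <- switch(resname,
    ALA = p(c("HB1", "HB2", "HB3"), "CB"),
    ARG = rbind(hb2, p(c("HG2", "HG3"), "CG"), p(c("HD2", "HD3"), "CD"),
                p("HE", "NE"), p(c("HH11", "HH12"), "NH1"),
                p(c("HH21", "HH22"), "NH2")),
    ASN = rbind(hb2, p(c("HD21", "HD22"), "ND2")),
    ASP = hb2,
    CYS = rbind(hb2, p("HG", "SG")),
    GLN = rbind(hb2, p(c("HG2", "HG3"), "CG"), p(c("HE21", "HE22"), "NE2")),
    GLU = rbind(hb2, p(c("HG2", "HG3"), "CG")),
    GLY = NULL,
    HIS = rbind(hb2, p("HD1", "ND1"), p("HD2", "CD2"), p("HE1", "CE1"),
                p("HE2", "NE2")),
    ILE = rbind(p("HB", "CB"), p(c("HG12", "HG13"), "CG1"),
                p(c("HG21", "HG22", "HG23"), "CG2"),
                p(c("HD11", "HD12", "HD13"), "CD1")),
    LEU = rbind(hb2, p("HG", "CG"), p(c("HD11", "HD12", "HD13"), "CD1"),
                p(c("HD21", "HD22", "HD23"), "CD2")),
    LYS = rbind(hb2, p(c("HG2", "HG3"), "CG"), p(c("HD2", "HD3"), "CD"),
                p(c("HE2", "HE3"), "CE"), p(c("HZ1", "HZ2", "HZ3"), "NZ")),
    MET = rbind(hb2, p(c("HG2", "HG3"), "CG"),
                p(c("HE1", "HE2", "HE3"), "CE")),
    PHE = rbind(hb2, p("HD1", "CD1"), p("HD2", "CD2"), p("HE1", "CE1"),
                p("HE2", "CE2"), p("HZ", "CZ")),
    PRO = rbind(hb2, p(c("HG2", "HG3"), "CG"), p(c("HD2", "HD3"), "CD")),
    SER = rbind(hb2, p("HG", "OG")),
    THR = rbind(p("HB", "CB"), p("HG1", "OG1"),
                p(c("HG21", "HG22", "HG23"), "CG2")),
    TRP = rbind(hb2, p("HD1", "CD1"), p("HE1", "NE1"), p("HE3", "CE3"),
                p("HZ2", "CZ2"), p("HZ3", "CZ3"), p("HH2", "CH2")),
    TYR = rbind(hb2, p("HD1", "CD1"), p("HD2", "CD2"), p("HE1", "CE1"),
                p("HE2", "CE2"), p("HH", "OH")),
    VAL = rbind(p("HB", "CB"), p(c("HG11", "HG12", "HG13"), "CG1"),
                p(c("HG21", "HG22", "HG23"), "CG2")),
    data_error(sprintf("unknown residue type: %s", resname),
               class = "rpfdp_unknown_residue"))
  rbind(bb, ha, sc)
}

# Heavy atoms whose attached protons are placed with planar (sp2) geometry.
sp2_parents <- function(resname) {
  base <- "N"  # backbone amide
  extra <- switch(resname,
    ARG = c("NE", "NH1", "NH2"),
    ASN = "ND2",
    GLN = "NE2",
    HIS = c("ND1", "CD2", "CE1", "NE2"),
    PHE = c("CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD1", "NE1", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CD1", "CD2", "CE1", "CE2"),
    character(0))
  c(base, extra)
}

# Full per-residue topology entry, cached.
residue_topology <- function(resname) {
  if (!is.null(.topo_env[[resname]])) return(.topo_env[[resname]])
  check_resname(resname)
  z <- sidechain_zmat(resname)
  heavy <- c("N", "CA", "C", "O", if (!is.null(z)) z$name)
  bonds <- rbind(matrix(c("N", "CA", "CA", "C", "C", "O"), ncol = 2,
                        byrow = TRUE),
                 if (!is.null(z)) cbind(z$parent, z$name),
                 ring_closure_bonds(resname))
  pt <- proton_table(resname)
  entry <- list(resname = resname, heavy = heavy, bonds = bonds,
                zmat = z, protons = pt, sp2 = sp2_parents(resname))
  .topo_env[[resname]] <- entry
  entry
}

# Heavy-atom adjacency (within one residue) as a named list.
heavy_neighbors <- function(topo) {
  nb <- setNames(vector("list", length(topo$heavy)), topo$heavy)
  for (k in seq_len(nrow(topo$bonds))) {
    a <- topo$bonds[k, 1]; b <- topo$bonds[k, 2]
    if (a %in% topo$heavy && b %in% topo$heavy) {
      nb[[a]] <- union(nb[[a]], b)
      nb[[b]] <- union(nb[[b]], a)
    }
  }
  nb
}

# Number of chi torsions a residue's z-matrix consumes.
n_chi <- function(resname) {
  z <- residue_topology(resname)$zmat
  if (is.null(z)) return(0L)
  hits <- regmatches(z$dih, regexpr("x[0-9]", z$dih))
  if (length(hits) == 0L) return(0L)
  max(as.integer(substring(hits, 2)))
}

# Element of an atom from its (normalized) name.
atom_element <- function(name) {
  ifelse(grepl("^[0-9]*H", name), "H", substring(sub("^[0-9]+", "", name), 1, 1))
}
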
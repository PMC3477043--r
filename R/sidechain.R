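# Idealised side-chain geometry templates.
#
# Each template row places one side-chain atom by NeRF construction from
# three previously placed atoms: torsion ref1-ref2-ref3-atom, angle
# ref2-ref3-atom, distance ref3-atom.  Torsions are either an offset added
# to chi1 (for gamma atoms, torsion N-CA-CB-gamma) or a fixed value for
# more distal atoms (only chi1 is treated as a degree of freedom; distal
# torsions sit at canonical staggered/planar values).  Bond lengths and
# angles follow standard protein stereochemistry dictionaries.

sidechain_templates <- function() {
  t <- function(atom, refs, dist, angle, tor, chi = FALSE) {
    list(atom = atom, refs = refs, dist = dist, angle = angle,
         tor = tor, chi = chi)
  }
  list(
    GLY = list(),
    ALA = list(),
    SER = list(t("OG", c("N", "CA", "CB"), 1.417, 110.8, 0, TRUE)),
    CYS = list(t("SG", c("N", "CA", "CB"), 1.808, 113.8, 0, TRUE)),
    THR = list(t("OG1", c("N", "CA", "CB"), 1.433, 109.5, 0, TRUE),
               t("CG2", c("N", "CA", "CB"), 1.521, 110.5, -120, TRUE)),
    VAL = list(t("CG1", c("N", "CA", "CB"), 1.527, 110.7, 0, TRUE),
               t("CG2", c("N", "CA", "CB"), 1.527, 110.4, 122.3, TRUE)),
    ILE = list(t("CG1", c("N", "CA", "CB"), 1.530, 110.4, 0, TRUE),
               t("CG2", c("N", "CA", "CB"), 1.530, 110.5, -122.3, TRUE),
               t("CD1", c("CA", "CB", "CG1"), 1.513, 113.8, 180)),
    LEU = list(t("CG", c("N", "CA", "CB"), 1.530, 116.3, 0, TRUE),
               t("CD1", c("CA", "CB", "CG"), 1.521, 110.7, 180),
               t("CD2", c("CA", "CB", "CG"), 1.521, 110.4, -60)),
    ASP = list(t("CG", c("N", "CA", "CB"), 1.516, 112.6, 0, TRUE),
               t("OD1", c("CA", "CB", "CG"), 1.249, 118.4, 0),
               t("OD2", c("CA", "CB", "CG"), 1.249, 118.4, 180)),
    ASN = list(t("CG", c("N", "CA", "CB"), 1.516, 112.6, 0, TRUE),
               t("OD1", c("CA", "CB", "CG"), 1.231, 120.8, 0),
               t("ND2", c("CA", "CB", "CG"), 1.328, 116.4, 180)),
    GLU = list(t("CG", c("N", "CA", "CB"), 1.520, 114.1, 0, TRUE),
               t("CD", c("CA", "CB", "CG"), 1.516, 112.6, 180),
               t("OE1", c("CB", "CG", "CD"), 1.249, 118.4, 0),
               t("OE2", c("CB", "CG", "CD"), 1.249, 118.4, 180)),
    GLN = list(t("CG", c("N", "CA", "CB"), 1.520, 114.1, 0, TRUE),
               t("CD", c("CA", "CB", "CG"), 1.516, 112.6, 180),
               t("OE1", c("CB", "CG", "CD"), 1.231, 120.8, 0),
               t("NE2", c("CB", "CG", "CD"), 1.328, 116.4, 180)),
    MET = list(t("CG", c("N", "CA", "CB"), 1.520, 114.1, 0, TRUE),
               t("SD", c("CA", "CB", "CG"), 1.803, 112.7, 180),
               t("CE", c("CB", "CG", "SD"), 1.791, 100.9, 180)),
    LYS = list(t("CG", c("N", "CA", "CB"), 1.520, 114.1, 0, TRUE),
               t("CD", c("CA", "CB", "CG"), 1.520, 111.3, 180),
               t("CE", c("CB", "CG", "CD"), 1.520, 111.3, 180),
               t("NZ", c("CG", "CD", "CE"), 1.489, 111.9, 180)),
    ARG = list(t("CG", c("N", "CA", "CB"), 1.520, 114.1, 0, TRUE),
               t("CD", c("CA", "CB", "CG"), 1.520, 111.3, 180),
               t("NE", c("CB", "CG", "CD"), 1.461, 112.0, 180),
               t("CZ", c("CG", "CD", "NE"), 1.329, 124.2, 180),
               t("NH1", c("CD", "NE", "CZ"), 1.326, 120.3, 0),
               t("NH2", c("CD", "NE", "CZ"), 1.326, 119.8, 180)),
    PHE = list(t("CG", c("N", "CA", "CB"), 1.502, 113.8, 0, TRUE),
               t("CD1", c("CA", "CB", "CG"), 1.384, 120.8, 90),
               t("CD2", c("CA", "CB", "CG"), 1.384, 120.8, -90),
               t("CE1", c("CB", "CG", "CD1"), 1.382, 121.0, 180),
               t("CE2", c("CB", "CG", "CD2"), 1.382, 121.0, 180),
               t("CZ", c("CG", "CD1", "CE1"), 1.382, 120.1, 0)),
    TYR = list(t("CG", c("N", "CA", "CB"), 1.502, 113.8, 0, TRUE),
               t("CD1", c("CA", "CB", "CG"), 1.384, 120.8, 90),
               t("CD2", c("CA", "CB", "CG"), 1.384, 120.8, -90),
               t("CE1", c("CB", "CG", "CD1"), 1.382, 121.0, 180),
               t("CE2", c("CB", "CG", "CD2"), 1.382, 121.0, 180),
               t("CZ", c("CG", "CD1", "CE1"), 1.382, 120.1, 0),
               t("OH", c("CD1", "CE1", "CZ"), 1.376, 119.9, 180)),
    HIS = list(t("CG", c("N", "CA", "CB"), 1.497, 113.8, 0, TRUE),
               t("ND1", c("CA", "CB", "CG"), 1.371, 122.7, 90),
               t("CD2", c("CA", "CB", "CG"), 1.356, 131.1, -90),
               t("CE1", c("CB", "CG", "ND1"), 1.319, 109.3, 180),
               t("NE2", c("CB", "CG", "CD2"), 1.374, 107.2, 180))
  )
}

# atom defining chi1 (torsion N-CA-CB-<atom>); NULL when chi1 undefined
chi1_atom <- function(resid) {
  switch(resid,
         SER = "OG", THR = "OG1", VAL = "CG1", ILE = "CG1", CYS = "SG",
         LEU = , ASP = , ASN = , GLU = , GLN = , MET = , LYS = , ARG = ,
         PHE = , TYR = , HIS = , TRP = "CG",
         NULL)
}

aa_three <- function(x) {
  x <- toupper(x)
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  if (nchar(x) == 1L) {
    if (!x %in% names(map)) stop("unknown residue code: ", x, call. = FALSE)
    unname(map[[x]])
  } else {
    if (!x %in% map) stop("unknown residue code: ", x, call. = FALSE)
    x
  }
}
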
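# Amino-acid chemistry tables: residue naming, ideal side-chain internal
# geometry (z-matrix rows built on the N/CA/C backbone frame), rotatable chi
# counts, partial charges, hydrogen-bond donor/acceptor roles and per-residue
# reference energies.  Heavy atoms only throughout.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- setNames(names(AA3), AA3)

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes
#' @return character vector of converted codes
#' @export
aa_three <- function(x) unname(AA3[toupper(x)])

#' @rdname aa_three
#' @export
aa_one <- function(x) unname(AA1[toupper(x)])

# number of rotatable side-chain dihedrals sampled by the rotamer moves
N_CHI <- c(A = 0L, G = 0L, S = 1L, C = 1L, T = 1L, V = 1L, L = 2L, I = 2L,
           M = 3L, P = 0L, F = 2L, Y = 2L, W = 2L, D = 2L, N = 2L, E = 3L,
           Q = 3L, K = 4L, R = 4L, H = 2L)

# z-matrix row: atom placed from parents a-b-c at distance d (A), angle
# b-c-atom (deg) and dihedral a-b-c-atom; chi > 0 means the dihedral is
# chi_k + off, chi == 0 means the dihedral is the fixed value off.
zrow <- function(atom, a, b, c, d, ang, chi, off) {
  data.frame(atom = atom, a = a, b = b, c = c, d = d, ang = ang,
             chi = chi, off = off, stringsAsFactors = FALSE)
}

# CB placement: improper dihedral C-N-CA-CB; sign fixed for L-chirality
# (validated against deposited protein structures in the test suite).
CB_ROW <- zrow("CB", "C", "N", "CA", 1.530, 110.5, 0L, 122.6)

SIDECHAIN_Z <- list(
  A = NULL,
  G = NULL,
  S = zrow("OG", "N", "CA", "CB", 1.417, 110.8, 1L, 0),
  C = zrow("SG", "N", "CA", "CB", 1.808, 113.8, 1L, 0),
  T = rbind(zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 1L, 0),
            zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, 120)),
  V = rbind(zrow("CG1", "N", "CA", "CB", 1.527, 110.7, 1L, 0),
            zrow("CG2", "N", "CA", "CB", 1.527, 110.4, 1L, -122.5)),
  L = rbind(zrow("CG", "N", "CA", "CB", 1.530, 116.3, 1L, 0),
            zrow("CD1", "CA", "CB", "CG", 1.524, 110.7, 2L, 0),
            zrow("CD2", "CA", "CB", "CG", 1.525, 110.4, 2L, -122.4)),
  I = rbind(zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 1L, 0),
            zrow("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, 122.3),
            zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
  M = rbind(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
            zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
            zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 3L, 0)),
  P = rbind(zrow("CG", "N", "CA", "CB", 1.495, 104.5, 1L, 0),
            zrow("CD", "CA", "CB", "CG", 1.507, 105.5, 2L, 0)),
  F = rbind(zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
            zrow("CD1", "CA", "CB", "CG", 1.390, 120.8, 2L, 0),
            zrow("CD2", "CA", "CB", "CG", 1.390, 120.8, 2L, 180),
            zrow("CE1", "CB", "CG", "CD1", 1.390, 121.0, 0L, 180),
            zrow("CE2", "CB", "CG", "CD2", 1.390, 121.0, 0L, 180),
            zrow("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0L, 0)),
  Y = rbind(zrow("CG", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
            zrow("CD1", "CA", "CB", "CG", 1.390, 120.8, 2L, 0),
            zrow("CD2", "CA", "CB", "CG", 1.390, 120.8, 2L, 180),
            zrow("CE1", "CB", "CG", "CD1", 1.390, 121.0, 0L, 180),
            zrow("CE2", "CB", "CG", "CD2", 1.390, 121.0, 0L, 180),
            zrow("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0L, 0),
            zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 0L, 180)),
  W = rbind(zrow("CG", "N", "CA", "CB", 1.498, 113.6, 1L, 0),
            zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
            zrow("CD2", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
            zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0L, 180),
            zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0L, 180),
            zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0L, 0),
            zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0L, 180),
            zrow("CZ3", "CE2", "CD2", "CE3", 1.382, 118.7, 0L, 0),
            zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0L, 0)),
  D = rbind(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
            zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
            zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
  N = rbind(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
            zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
            zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
  E = rbind(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
            zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
            zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
            zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
  Q = rbind(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
            zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
            zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
            zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
  K = rbind(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
            zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
            zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 3L, 0),
            zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 4L, 0)),
  R = rbind(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
            zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
            zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 3L, 0),
            zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
            zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0L, 0),
            zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0L, 180)),
  H = rbind(zrow("CG", "N", "CA", "CB", 1.492, 113.7, 1L, 0),
            zrow("ND1", "CA", "CB", "CG", 1.380, 122.8, 2L, 0),
            zrow("CD2", "CA", "CB", "CG", 1.354, 131.0, 2L, 180),
            zrow("CE1", "CB", "CG", "ND1", 1.326, 109.2, 0L, 180),
            zrow("NE2", "CB", "CG", "CD2", 1.373, 107.2, 0L, 180))
)

# side-chain heavy-atom names in build order (CB first where present)
# the two proline ring puckers as (chi1, chi2) pairs; the ring is closed
# approximately and the pro_close term penalizes the residual CD-N gap
PRO_PUCKERS <- list(c(30, -35), c(-30, 35))

sidechain_atoms <- function(aa) {
  if (aa %in% c("G")) return(character(0))
  z <- SIDECHAIN_Z[[aa]]
  c("CB", if (!is.null(z)) z$atom)
}

# partial charges by (aa, atom); backbone common to all residues
BACKBONE_CHARGE <- c(N = -0.47, CA = 0.07, C = 0.51, O = -0.51)
SIDECHAIN_CHARGE <- list(
  K = c(NZ = 0.80),
  R = c(CZ = 0.40, NH1 = 0.30, NH2 = 0.30),
  D = c(CG = 0.20, OD1 = -0.60, OD2 = -0.60),
  E = c(CD = 0.20, OE1 = -0.60, OE2 = -0.60),
  N = c(CG = 0.30, OD1 = -0.55, ND2 = 0.25),
  Q = c(CD = 0.30, OE1 = -0.55, NE2 = 0.25),
  S = c(OG = -0.35),
  T = c(OG1 = -0.35),
  Y = c(OH = -0.35),
  H = c(ND1 = -0.25, NE2 = -0.25, CE1 = 0.50),
  W = c(NE1 = -0.10),
  C = c(SG = -0.15),
  M = c(SD = -0.15)
)

atom_charge <- function(aa, atom) {
  q <- unname(BACKBONE_CHARGE[atom])
  q[is.na(q)] <- 0
  for (i in seq_along(aa)) {
    sc <- SIDECHAIN_CHARGE[[aa[i]]]
    if (!is.null(sc) && atom[i] %in% names(sc)) q[i] <- sc[[atom[i]]]
  }
  q
}

# hydrogen-bond roles: donor/acceptor heavy atoms and their bonded base atom
SC_DONORS <- list(
  S = c(OG = "CB"), T = c(OG1 = "CB"), Y = c(OH = "CZ"),
  K = c(NZ = "CE"), R = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  N = c(ND2 = "CG"), Q = c(NE2 = "CD"),
  H = c(ND1 = "CG", NE2 = "CD2"), W = c(NE1 = "CD1")
)
SC_ACCEPTORS <- list(
  D = c(OD1 = "CG", OD2 = "CG"), E = c(OE1 = "CD", OE2 = "CD"),
  N = c(OD1 = "CG"), Q = c(OE1 = "CD"),
  S = c(OG = "CB"), T = c(OG1 = "CB"), Y = c(OH = "CZ"),
  H = c(ND1 = "CG", NE2 = "CD2")
)

# per-residue reference energies (constant chemical-potential-like offsets)
REF_ENERGY <- c(A = 0.77, C = 1.50, D = -1.55, E = -1.72, F = 0.68, G = 0.80,
                H = -0.30, I = 1.12, K = -1.20, L = 1.00, M = 0.19, N = -1.63,
                P = -0.10, Q = -1.26, R = 0.44, S = 0.16, T = 0.36, V = 0.87,
                W = 0.91, Y = 0.51)

atom_element <- function(name) substr(toupper(name), 1, 1)

is_backbone_atom <- function(name) name %in% c("N", "CA", "C", "O", "OXT")

#' Wimley-White interface hydropathy scale
#'
#' The packaged water-to-interface transfer free energies (kcal/mol) used for
#' all positional hydropathy features and comparisons.  Negative values mark
#' hydrophobic residues.
#'
#' @return named numeric vector over the 20 one-letter amino-acid codes
#' @export
#' @examples
#' hydropathy_scale()[c("L", "S")]
hydropathy_scale <- function() {
  tab <- sys_table("wimley_white_interface.tsv")
  setNames(tab$ww_interface, tab$aa)
}

atom_param_table <- function() {
  tab <- sys_table("atom_params.tsv")
  as.data.frame(tab)
}
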
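# Internal chemistry tables used by the atomic descriptor, the solvent
# accessibility routine and the synthetic-structure generator. Values are
# standard textbook constants; the bonded-hydrogen and ring assignments are
# deliberately coarse heavy-atom heuristics (documented in the vignette).

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

CHARGED_AA <- c("D", "E", "H", "K", "R")

# Tien et al. theoretical maximum accessible surface area (A^2), used to
# turn absolute residue SASA into relative accessibility.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)

# Side-chain heavy-atom element composition (beyond backbone N, CA, C, O).
SIDECHAIN_ELEMENTS <- list(
  A = "C",
  R = c("C", "C", "C", "N", "C", "N", "N"),
  N = c("C", "C", "O", "N"),
  D = c("C", "C", "O", "O"),
  C = c("C", "S"),
  Q = c("C", "C", "C", "O", "N"),
  E = c("C", "C", "C", "O", "O"),
  G = character(0),
  H = c("C", "C", "N", "C", "C", "N"),
  I = c("C", "C", "C", "C"),
  L = c("C", "C", "C", "C"),
  K = c("C", "C", "C", "C", "N"),
  M = c("C", "C", "S", "C"),
  F = c("C", "C", "C", "C", "C", "C", "C"),
  P = c("C", "C", "C"),
  S = c("C", "O"),
  T = c("C", "O", "C"),
  W = c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
  Y = c("C", "C", "C", "C", "C", "C", "C", "O"),
  V = c("C", "C", "C")
)

RING_AA <- c("H", "F", "W", "Y", "P")

ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971)
ELEMENT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, SE = 1.90)
DEFAULT_MASS <- 20.0
DEFAULT_VDW <- 1.80

element_mass <- function(el) {
  m <- ELEMENT_MASS[el]
  m[is.na(m)] <- DEFAULT_MASS
  unname(m)
}

element_vdw <- function(el) {
  r <- ELEMENT_VDW[el]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

# Coarse bonded-hydrogen estimate per heavy atom. Backbone: amide N carries
# one H, CA one, carbonyl C and O none. Side chain: generic sp3 carbon 2,
# nitrogen 1, hydroxyl/thiol O/S 1, everything else 0.
bonded_hydrogens <- function(element, is_sidechain) {
  h <- numeric(length(element))
  bb <- !is_sidechain
  h[bb & element == "N"] <- 1
  h[bb & element == "C"] <- 0   # CA handled below via name-free rule
  sc <- is_sidechain
  h[sc & element == "C"] <- 2
  h[sc & element == "N"] <- 1
  h[sc & element == "O"] <- 1
  h[sc & element == "S"] <- 1
  h
}

# Ring membership: side-chain atoms of ring-bearing residues, minus the
# beta carbon (first side-chain atom); proline's three side-chain carbons
# all belong to the pyrrolidine ring.
ring_membership <- function(aa, is_sidechain) {
  if (!(aa %in% RING_AA)) return(rep(FALSE, length(is_sidechain)))
  flag <- is_sidechain
  if (aa != "P") {
    first_sc <- which(is_sidechain)[1]
    if (!is.na(first_sc)) flag[first_sc] <- FALSE
  }
  flag
}

aa_three_to_one <- function(resid) {
  m <- match(resid, AA3)
  out <- names(AA3)[m]
  out[is.na(out)] <- "X"
  out
}

max_asa_for <- function(aa) {
  v <- MAX_ASA[aa]
  v[is.na(v)] <- mean(MAX_ASA)
  unname(v)
}
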
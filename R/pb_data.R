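#' Protein Blocks reference dihedral table
#'
#' The 16 Protein Blocks (PBs) form a structural alphabet of pentapeptide
#' backbone conformations (de Brevern, Etchebest & Hazout 2000, Proteins
#' 41:271-287).  Each block is defined by eight reference dihedral angles
#' spanning the pentapeptide centred at residue i, in the order
#' psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2).
#' Block \code{m} is the core alpha-helix conformation and \code{d} the core
#' beta-strand.
#'
#' @return 16 x 8 numeric matrix, rownames \code{a}..\code{p}, angles in
#'   degrees in (-180, 180].
#' @export
pb_reference_angles <- function() {
  m <- matrix(c(
     41.14,   75.53,  13.92,  -99.80, 131.88,  -96.27, 122.40,  -99.20,
    108.24,  -90.12, 119.54,  -92.21, -18.06, -128.93, 147.04,  -99.90,
    -11.61, -105.66,  94.81, -106.09, 133.56, -106.93, 135.97, -100.63,
    141.98, -112.79, 132.20, -114.79, 140.11, -111.05, 139.54, -103.16,
    133.25, -112.37, 137.64, -108.13, 133.00,  -87.30, 120.54,   77.40,
    116.40, -105.53, 129.32,  -96.68, 140.72,  -74.19, -26.65,  -94.51,
      0.40,  -81.83,   4.91, -100.59,  85.50,  -71.65, 130.78,   84.98,
    119.14, -102.58, 130.83,  -67.91, 121.55,   76.25,  -2.95,  -90.88,
    130.68,  -56.92, 119.26,   77.85,  10.42,  -99.43, 141.40,  -98.01,
    114.32, -121.47, 118.14,   82.88,-150.05,  -83.81,  23.35,  -85.82,
    117.16,  -95.41, 140.40,  -59.35, -29.23,  -72.39, -25.08,  -76.16,
    139.20,  -55.96, -32.70,  -68.51, -26.09,  -74.44, -22.60,  -71.74,
    -39.62,  -64.73, -39.52,  -65.54, -38.88,  -66.89, -37.76,  -70.19,
    -35.34,  -65.03, -38.12,  -66.34, -29.51,  -89.10,  -2.91,   77.90,
    -45.29,  -67.44, -27.72,  -87.27,   5.13,   77.49,  30.71,  -93.23,
    -27.09,  -86.14,   0.30,   59.85,  21.51,  -96.30, 132.67,  -92.91),
    nrow = 16, byrow = TRUE,
    dimnames = list(letters[1:16],
                    c("psi_m2", "phi_m1", "psi_m1", "phi0",
                      "psi0", "phi_p1", "psi_p1", "phi_p2")))
  m
}

#' Protein Blocks alphabet
#'
#' @return character vector \code{a}..\code{p} (16 letters); the undefined
#'   marker is \code{"Z"}.
#' @export
pb_alphabet <- function() letters[1:16]

#' Background frequencies of the 16 Protein Blocks
#'
#' Approximate observed frequencies of the blocks over a representative set of
#' globular protein structures (de Brevern et al. 2000), normalized to sum to
#' one.  Helix core \code{m} and strand core \code{d} dominate.
#'
#' @return named numeric vector of length 16 summing to 1.
#' @export
pb_background <- function() {
  f <- c(a = 3.88, b = 4.46, c = 8.10, d = 18.85, e = 2.48, f = 6.68,
         g = 1.06, h = 2.39, i = 1.88, j = 0.84, k = 5.57, l = 5.45,
         m = 32.17, n = 1.74, o = 2.77, p = 1.86)
  f / sum(f)
}

#' Amino-acid alphabet used throughout the package
#'
#' @return the 20 standard one-letter codes in alphabetical order.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' Marginal frequencies of the BLOSUM62 substitution model (Henikoff &
#' Henikoff 1992), normalized; used as the amino-acid null model in column
#' scoring and as the composition assigned to unknown ('X') residues.
#'
#' @return named numeric vector over [aa_alphabet()] summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  f / sum(f)
}

# one-to-three / three-to-one residue code tables (standard amino acids)
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))
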
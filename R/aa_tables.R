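#' @keywords internal
#' @noRd
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

#' @noRd
AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Van der Waals radii (Angstrom) by element, NACCESS-compatible values.
#' @noRd
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80,
               SE = 1.90, H = 1.20, D = 1.20)

#' @noRd
VDW_DEFAULT <- 1.80

# Theoretical maximum solvent accessibility per residue type (Angstrom^2),
# Tien et al. 2013 theoretical values; used to normalise relative exposure.
#' @noRd
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174, X = 200
)

# Chou-Fasman conformational propensities (helix, sheet, turn) used as the
# fallback peptide secondary-structure prior when no external prediction is
# supplied. Rows are normalised to probabilities at lookup time.
#' @noRd
CHOU_FASMAN <- matrix(c(
  # Pa,  Pb,  Pt
  1.42, 0.83, 0.66,  # A
  0.98, 0.93, 0.95,  # R
  0.67, 0.89, 1.56,  # N
  1.01, 0.54, 1.46,  # D
  0.70, 1.19, 1.19,  # C
  1.51, 0.37, 0.74,  # E
  1.11, 1.10, 0.98,  # Q
  0.57, 0.75, 1.56,  # G
  1.00, 0.87, 0.95,  # H
  1.08, 1.60, 0.47,  # I
  1.21, 1.30, 0.59,  # L
  1.16, 0.74, 1.01,  # K
  1.45, 1.05, 0.60,  # M
  1.13, 1.38, 0.60,  # F
  0.57, 0.55, 1.52,  # P
  0.77, 0.75, 1.43,  # S
  0.83, 1.19, 0.96,  # T
  1.08, 1.37, 0.96,  # W
  0.69, 1.47, 1.14,  # Y
  1.06, 1.70, 0.50   # V
), ncol = 3, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("H", "E", "C")))

#' @noRd
aa_three_to_one <- function(resnames) {
  out <- unname(AA3TO1[resnames])
  out[is.na(out)] <- "X"
  out
}

#' @noRd
element_radius <- function(elements, warn = TRUE) {
  r <- unname(VDW_RADII[toupper(elements)])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (warn) {
      warning(sprintf("unknown element(s) %s: using default radius %.2f A",
                      paste(unique(elements[unknown]), collapse = ", "),
                      VDW_DEFAULT), call. = FALSE)
    }
    r[unknown] <- VDW_DEFAULT
  }
  r
}
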
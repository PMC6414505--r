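#' Interface residues between two chains
#'
#' A residue of one chain belongs to the interface iff any of its heavy atoms
#' lies within `cutoff` of any heavy atom of the other chain. Hydrogens are
#' excluded at parse time, so the test is over heavy atoms by construction.
#'
#' @param structure a [pb_structure()].
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return list with elements `a` and `b`, the two [residue_site()]s.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  ca <- get_chain(structure, chain_a)
  cb <- get_chain(structure, chain_b)
  pairs <- .contact_pairs_cpp(as.matrix(ca$atoms[, c("x", "y", "z")]),
                              as.integer(ca$atoms$pos),
                              as.matrix(cb$atoms[, c("x", "y", "z")]),
                              as.integer(cb$atoms$pos), cutoff)
  list(a = residue_site(ca, unique(pairs[, 1])),
       b = residue_site(cb, unique(pairs[, 2])))
}

#' Assign 3-state secondary structure from C-alpha geometry
#'
#' Distance-based assignment in the spirit of P-SEA: a residue window is
#' helical when its i/i+2, i/i+3 and i/i+4 C-alpha distances match ideal
#' alpha-helix geometry, and strand-like when the i/i+2 and i/i+3 distances
#' match extended-sheet geometry. Residues not matching either pattern, or
#' lacking C-alpha coordinates, are coil.
#'
#' @param chain a [pb_chain()].
#' @return character scalar of `H`/`E`/`C`, one letter per residue.
#' @export
assign_secondary_structure <- function(chain) {
  n <- chain$length
  ss <- rep("C", n)
  if (n < 5) return(paste(ss, collapse = ""))
  ca <- chain$ca
  d <- function(i, j) sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
  i <- seq_len(n - 4)
  d13 <- d(i, i + 2); d14 <- d(i, i + 3); d15 <- d(i, i + 4)
  helix_start <- !is.na(d13) & !is.na(d14) & !is.na(d15) &
    d13 >= 4.6 & d13 <= 6.4 & d14 >= 4.3 & d14 <= 6.1 & d15 >= 5.2 & d15 <= 7.2
  for (k in which(helix_start)) ss[(k + 1):(k + 3)] <- "H"
  j <- seq_len(n - 3)
  e13 <- d(j, j + 2)
  e14 <- d(j, j + 3)
  strand_start <- !is.na(e13) & !is.na(e14) &
    e13 >= 6.0 & e13 <= 7.3 & e14 >= 9.0 & e14 <= 11.0
  for (k in which(strand_start)) {
    idx <- (k + 1):(k + 2)
    ss[idx][ss[idx] == "C"] <- "E"
  }
  paste(ss, collapse = "")
}
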
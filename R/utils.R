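#' Evaluate an expression with a local, restorable RNG state
#' @noRd
with_rng <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' @noRd
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

#' Mean cross-pair Euclidean distance between two coordinate sets
#' @noRd
mean_cross_distance <- function(a, b) {
  # ||a_i - b_j||: expand via the Gram trick, clamped for numerical safety
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(d2, 0)))
}

#' @noRd
min_cross_distance <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}
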
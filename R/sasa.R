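#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-residue SASA for all (or a subset of) chains with the
#' Shrake-Rupley rolling-probe algorithm on heavy atoms, using
#' NACCESS-compatible van der Waals radii and a deterministic spherical point
#' lattice.
#'
#' @param structure a [pb_structure()].
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atomic sphere; more points give
#'   a finer (and slower) estimate.
#' @param chains optional character vector restricting the computation to a
#'   subset of chains; all other chains are removed before the calculation
#'   (i.e. the subset is treated as an isolated molecule).
#' @param lattice_frame optional frame (`list(center, rotation)`) in which to
#'   orient the point lattice; by default the principal-axis frame of the
#'   selected atoms, which makes the result invariant under rigid-body motion
#'   of the input. Pass a common frame when differencing SASA values across
#'   chain subsets so the lattice discretisation cancels (see
#'   [buried_surface()]).
#' @return named list, `chain_id -> numeric vector` of per-residue SASA in
#'   square Angstrom.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                         chains = NULL, lattice_frame = NULL) {
  sel <- if (is.null(chains)) names(structure$chains) else chains
  missing <- setdiff(sel, names(structure$chains))
  if (length(missing))
    stop(sprintf("chain '%s' not found in structure '%s'", missing[1], structure$id))
  coords <- list(); cid <- character(0); pos <- integer(0); elem <- character(0)
  for (id in sel) {
    a <- structure$chains[[id]]$atoms
    coords[[id]] <- as.matrix(a[, c("x", "y", "z")])
    cid <- c(cid, rep(id, nrow(a)))
    pos <- c(pos, a$pos)
    elem <- c(elem, a$element)
  }
  xyz <- do.call(rbind, coords)
  if (is.null(lattice_frame)) lattice_frame <- principal_frame(xyz)
  xyz <- sweep(xyz, 2, lattice_frame$center) %*% lattice_frame$rotation
  areas <- .sasa_atoms_cpp(xyz, element_radius(elem), probe_radius,
                           as.integer(n_points))
  out <- list()
  for (id in sel) {
    ch <- structure$chains[[id]]
    v <- numeric(ch$length)
    agg <- tapply(areas[cid == id], pos[cid == id], sum)
    v[as.integer(names(agg))] <- as.numeric(agg)
    out[[id]] <- v
  }
  out
}

# Rotate coordinates into a deterministic molecule-fixed (principal-axis)
# frame so the point-lattice SASA is exactly invariant under rigid-body
# motion of the input. Axis signs are fixed by the third central moment
# (generically non-zero), falling back to a largest-component rule.
#' @noRd
principal_frame <- function(xyz) {
  center <- colMeans(xyz)
  X <- sweep(xyz, 2, center)
  if (nrow(xyz) < 3) return(list(center = center, rotation = diag(3)))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:3) {
    s <- sum((X %*% V[, j])^3)
    if (abs(s) > 1e-8) {
      if (s < 0) V[, j] <- -V[, j]
    } else {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = center, rotation = V)
}

#' @noRd
structure_frame <- function(structure, chains) {
  xyz <- do.call(rbind, lapply(chains, function(id)
    as.matrix(structure$chains[[id]]$atoms[, c("x", "y", "z")])))
  principal_frame(xyz)
}

#' Buried (shared) surface area between two chains
#'
#' The surface lost on complex formation:
#' `SASA(a alone) + SASA(b alone) - SASA(a+b together)`, reported as the full
#' difference (not halved).
#'
#' @param structure a [pb_structure()] containing both chains.
#' @param chain_a,chain_b chain identifiers.
#' @param n_points sphere points per atom, see [compute_sasa()].
#' @return buried surface area in square Angstrom.
#' @export
buried_surface <- function(structure, chain_a, chain_b, n_points = 960) {
  fr <- structure_frame(structure, c(chain_a, chain_b))
  sa <- sum(unlist(compute_sasa(structure, chains = chain_a,
                                n_points = n_points, lattice_frame = fr)))
  sb <- sum(unlist(compute_sasa(structure, chains = chain_b,
                                n_points = n_points, lattice_frame = fr)))
  sab <- sum(unlist(compute_sasa(structure, chains = c(chain_a, chain_b),
                                 n_points = n_points, lattice_frame = fr)))
  sa + sb - sab
}

#' Fraction of a peptide's surface buried by the rest of the structure
#'
#' @param structure a [pb_structure()].
#' @param peptide_chain peptide chain identifier.
#' @param n_points sphere points per atom, see [compute_sasa()].
#' @return burial fraction in `[0, 1]`:
#'   `1 - SASA(peptide in complex) / SASA(peptide alone)`.
#' @export
peptide_burial_fraction <- function(structure, peptide_chain, n_points = 960) {
  fr <- structure_frame(structure, names(structure$chains))
  alone <- sum(unlist(compute_sasa(structure, chains = peptide_chain,
                                   n_points = n_points, lattice_frame = fr)))
  if (alone <= 0) stop("peptide has zero isolated surface; burial undefined")
  complexed <- sum(compute_sasa(structure, n_points = n_points,
                                lattice_frame = fr)[[peptide_chain]])
  min(max(1 - complexed / alone, 0), 1)
}

#' Mean relative solvent exposure of a residue site
#'
#' Each residue's SASA is divided by the theoretical maximum for its residue
#' type (Tien et al. scale shipped with the package), clamped to `[0, 1]`,
#' and averaged over the site.
#'
#' @param chain a [pb_chain()].
#' @param site a [residue_site()] on that chain.
#' @param sasa numeric vector of per-residue SASA for the chain (one entry
#'   per residue), e.g. one element of [compute_sasa()] output.
#' @return mean relative exposure in `[0, 1]`.
#' @export
relative_exposure <- function(chain, site, sasa) {
  if (!length(site$members)) stop("relative exposure undefined for an empty site")
  aa <- aa_three_to_one(chain$resnames[site$members])
  ref <- MAX_SASA[aa]
  ref[is.na(ref)] <- MAX_SASA[["X"]]
  mean(pmin(pmax(sasa[site$members] / ref, 0), 1))
}
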
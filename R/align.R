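#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, the length-dependent distance scale of
#' the TM-score. By default the value is clamped from below at 0.5 A, where
#' the cube-root formula loses validity for short chains.
#'
#' @param l normalization length (residues).
#' @param clamp clamp the result from below at 0.5 A (default). With
#'   `clamp = FALSE` the raw formula value is returned (valid for `l > 15`).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l, clamp = TRUE) {
  raw <- ifelse(l > 15, 1.24 * (l - 15)^(1 / 3) - 1.8, NA_real_)
  if (!clamp) return(raw)
  out <- pmax(raw, 0.5)
  out[is.na(out)] <- 0.5
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `coords_a` onto
#' `coords_b`; reflections are excluded.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices of paired points.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3 vector) and `rmsd`, such that
#'   `coords_a %*% t(rotation) + translation` best matches `coords_b`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3)
    stop("superposition requires equal-length n x 3 coordinate sets")
  n <- nrow(coords_a)
  if (n < 3) stop("superposition requires at least 3 point pairs")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  s <- svd(crossprod(A, B))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (collinear) geometry: superposition underdetermined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.vector(cb - R %*% ca)
  fit <- A %*% t(R)
  list(rotation = R, translation = trans,
       rmsd = sqrt(mean(rowSums((fit - B)^2))))
}

#' TM-score of a residue mapping
#'
#' `TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` over the mapped residue
#' pairs. With `optimize = TRUE` (default) the score is maximised over rigid
#' superpositions of the mapped pairs (fragment-seeded iterative search);
#' with `optimize = FALSE` the coordinates are scored as given.
#'
#' @param mapping 2-column matrix of (target_position, template_position)
#'   residue index pairs.
#' @param target_coords,template_coords per-residue C-alpha coordinate
#'   matrices of the two chains.
#' @param normalization_length chain length used for normalization and d0.
#' @param optimize maximise over superpositions of the mapped pairs.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(mapping, target_coords, template_coords,
                     normalization_length, optimize = TRUE) {
  mapping <- matrix(as.integer(mapping), ncol = 2)
  if (!nrow(mapping)) stop("TM-score undefined for an empty mapping")
  a <- as.matrix(target_coords)[mapping[, 1], , drop = FALSE]
  b <- as.matrix(template_coords)[mapping[, 2], , drop = FALSE]
  d0 <- tm_d0(normalization_length)
  if (optimize) {
    return(.tm_search_cpp(a, b, d0, normalization_length)$tm)
  }
  d2 <- rowSums((a - b)^2)
  sum(1 / (1 + d2 / d0^2)) / normalization_length
}

#' Align a target chain to a template chain
#'
#' Heuristic TM-align-style search: gapless diagonal seed fragments are
#' superposed and iteratively refined by dynamic-programming alignment under
#' the current superposition; the mapping with the highest target-normalized
#' TM-score is kept, then both TM-score normalizations are computed by full
#' superposition search over the final mapping. Deterministic; seed ties are
#' broken by the earliest seed.
#'
#' @param target_chain a [pb_chain()] (or any list with elements `ca` and
#'   `length`).
#' @param template_chain same as `target_chain`.
#' @return an alignment of class `pb_alignment`: `mapping` (2-column matrix
#'   of 1-based residue positions, strictly increasing in both columns),
#'   `rotation`, `translation` (target onto template frame), `rmsd`,
#'   `tm_target` and `tm_template`; or `NULL` when no alignment of at least 3
#'   residues exists.
#' @export
align_structures <- function(target_chain, template_chain) {
  ta <- chain_ca(target_chain); tb <- chain_ca(template_chain)
  if (nrow(ta$ca) < 5 || nrow(tb$ca) < 5)
    stop("alignment requires at least 5 residues with C-alpha coordinates")
  la <- ta$n_total; lb <- tb$n_total
  res <- .align_pair_cpp(ta$ca, tb$ca, tm_d0(la), tm_d0(lb), -0.6)
  if (res$n == 0) return(NULL)
  mapping <- cbind(target = ta$idx[res$mi + 1L], template = tb$idx[res$mj + 1L])
  base::structure(list(mapping = mapping,
                       rotation = res$rotation,
                       translation = as.vector(res$translation),
                       rmsd = res$rmsd,
                       tm_target = res$tm_target,
                       tm_template = res$tm_template),
                  class = "pb_alignment")
}

#' @export
print.pb_alignment <- function(x, ...) {
  cat(sprintf("<pb_alignment> %d pairs, TM(target) %.3f, TM(template) %.3f, RMSD %.2f A\n",
              nrow(x$mapping), x$tm_target, x$tm_template, x$rmsd))
  invisible(x)
}

# residues with finite C-alpha, remembering original positions
#' @noRd
chain_ca <- function(chain) {
  ca <- chain$ca
  ok <- which(is.finite(ca[, 1]) & is.finite(ca[, 2]) & is.finite(ca[, 3]))
  if (!length(ok)) stop("chain has no C-alpha coordinates")
  n_total <- if (!is.null(chain$length)) chain$length else nrow(ca)
  list(ca = ca[ok, , drop = FALSE], idx = ok, n_total = n_total)
}

#' Transfer a template's interface onto the target through an alignment
#'
#' Template receptor interface positions that are present in the alignment
#' mapping are converted to the equivalent target positions; unmapped
#' interface residues are dropped.
#'
#' @param alignment a `pb_alignment` between the target and the template's
#'   receptor chain.
#' @param template_entry a `pb_template`.
#' @param target_chain the target [pb_chain()].
#' @return a candidate site of class `pb_candidate`: `source_id`,
#'   `alignment`, `site` (a [residue_site()] on the target),
#'   `interface_vector` (logical over target residues) and
#'   `aligned_interface_count`; or `NULL` when no interface residue maps.
#' @export
transfer_interface <- function(alignment, template_entry, target_chain) {
  hit <- match(template_entry$receptor_interface, alignment$mapping[, 2])
  tpos <- alignment$mapping[hit[!is.na(hit)], 1]
  if (!length(tpos)) return(NULL)
  site <- residue_site(target_chain, tpos)
  vec <- rep(FALSE, target_chain$length)
  vec[site$members] <- TRUE
  base::structure(list(source_id = template_entry$source_id,
                       alignment = alignment,
                       site = site,
                       interface_vector = vec,
                       aligned_interface_count = length(site$members)),
                  class = "pb_candidate")
}

#' Scan a template library with a target chain
#'
#' Aligns the target to the receptor chain of every entry and keeps, in
#' library order, one candidate site per entry whose target-normalized
#' TM-score passes the significance gate.
#'
#' @param target_chain the target [pb_chain()].
#' @param library a `pb_library`.
#' @param tm_cutoff minimum target-normalized TM-score (0.5 marks a
#'   significant structural match).
#' @return list of `pb_candidate` objects, each carrying `template_index`
#'   (position of its entry in the library).
#' @export
scan_library <- function(target_chain, library, tm_cutoff = 0.5) {
  stopifnot(length(library$entries) >= 1)
  out <- list()
  for (i in seq_along(library$entries)) {
    e <- library$entries[[i]]
    aln <- tryCatch(align_structures(target_chain, e$receptor),
                    error = function(err) NULL)
    if (is.null(aln) || aln$tm_target < tm_cutoff) next
    cand <- transfer_interface(aln, e, target_chain)
    if (is.null(cand)) next
    cand$template_index <- i
    out[[length(out) + 1]] <- cand
  }
  out
}
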
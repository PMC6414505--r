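#' Generate a synthetic chain with ideal backbone geometry
#'
#' Builds a chain of C-alpha plus pseudo side-chain heavy atoms on an idealised
#' backbone: alpha-helix (1.5 A rise, 100 degrees per residue, 2.3 A radius),
#' zig-zag extended strand (3.8 A C-alpha spacing), a two-strand hairpin, or
#' a three-helix bundle. Optional Gaussian coordinate noise emulates
#' structural divergence between homologous folds. Generation is
#' seed-deterministic; the caller's RNG state is left untouched.
#'
#' @param topology one of `"HELIX"`, `"STRAND"`, `"HAIRPIN"`, `"HELIX_BUNDLE"`.
#' @param n_residues number of residues (>= 3).
#' @param sequence optional one-letter sequence of length `n_residues`;
#'   drawn uniformly over the 20 amino acids when `NULL`.
#' @param noise_sigma standard deviation (Angstrom) of i.i.d. Gaussian noise
#'   added to every coordinate.
#' @param seed integer seed for sequence sampling and noise.
#' @param chain_id chain identifier.
#' @return a [pb_chain()].
#' @export
make_chain <- function(topology = c("HELIX", "STRAND", "HAIRPIN", "HELIX_BUNDLE"),
                       n_residues, sequence = NULL, noise_sigma = 0,
                       seed = 1, chain_id = "A") {
  topology <- match.arg(topology)
  stopifnot(n_residues >= 3, noise_sigma >= 0)
  n <- as.integer(n_residues)

  ca <- switch(topology,
    HELIX = helix_ca(n),
    STRAND = strand_ca(n),
    HAIRPIN = hairpin_ca(n),
    HELIX_BUNDLE = bundle_ca(n))

  # pseudo side chain: CB and CG offset from C-alpha away from the local
  # backbone direction, giving residues a realistic outward reach
  off <- cbeta_offsets(ca)
  cb <- ca + off
  cg <- ca + off * (2.9 / 1.5)

  with_rng(seed, {
    if (is.null(sequence)) {
      sequence <- paste(sample(AA1, n, replace = TRUE), collapse = "")
    }
    if (noise_sigma > 0) {
      ca <- ca + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
      cb <- cb + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
      cg <- cg + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
    }
  })
  stopifnot(nchar(sequence) == n)
  resnames <- unname(AA1TO3[strsplit(sequence, "")[[1]]])
  resnames[is.na(resnames)] <- "UNK"

  atoms <- data.frame(
    pos = rep(seq_len(n), each = 3),
    atom = rep(c("CA", "CB", "CG"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1], cg[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2], cg[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3], cg[, 3])),
    stringsAsFactors = FALSE)
  pb_chain(chain_id, resnames, ca, atoms)
}

helix_ca <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  k <- seq_len(n) - 1
  th <- twist * pi / 180 * k
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

strand_ca <- function(n) {
  # zig-zag with ~3.8 A consecutive and ~6.7 A i,i+2 distances
  k <- seq_len(n) - 1
  cbind(3.35 * k, 1.79 * (k %% 2), 0)
}

hairpin_ca <- function(n) {
  n1 <- ceiling(n / 2)
  s1 <- strand_ca(n1)
  s2 <- strand_ca(n - n1)
  # antiparallel return strand offset in y
  s2 <- cbind(max(s1[, 1]) - s2[, 1], s2[, 2] + 4.8, s2[, 3] + 1.0)
  rbind(s1, s2)
}

bundle_ca <- function(n) {
  n3 <- n %/% 3
  seg <- c(n3, n3, n - 2 * n3)
  offs <- list(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0))
  out <- NULL
  for (s in 1:3) {
    h <- helix_ca(seg[s])
    if (s %% 2 == 0) h[, 3] <- max(h[, 3]) - h[, 3]  # antiparallel
    h <- sweep(h, 2, unlist(offs[s]), "+")
    out <- rbind(out, h)
  }
  out
}

cbeta_offsets <- function(ca) {
  n <- nrow(ca)
  off <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    nb <- colMeans(ca[c(lo, hi), , drop = FALSE])
    v <- ca[i, ] - nb
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) v <- c(0, 0, 1) else v <- v / nv
    off[i, ] <- 1.5 * v
  }
  off
}

#' Assemble a two-chain complex with a known true interface
#'
#' Places the peptide chain next to the receptor along a given direction so
#' that the closest heavy-atom distance between the chains equals
#' `contact_offset`, then records the receptor residues within the standard
#' 6 A heavy-atom contact of the peptide as the true binding site.
#'
#' @param receptor a [pb_chain()] (used as chain A).
#' @param peptide a [pb_chain()] (used as chain B).
#' @param contact_offset desired closest heavy-atom distance in Angstrom;
#'   must be >= 1.5 to avoid steric overlap.
#' @param direction 3-vector along which the peptide is displaced.
#' @param id structure identifier.
#' @return list with `structure` (a [pb_structure()]), `receptor_chain`,
#'   `peptide_chain`, and `true_site` (a [residue_site()] on the receptor).
#' @export
make_complex <- function(receptor, peptide, contact_offset = 3.0,
                         direction = c(0, -1, 0), id = "synthetic_complex") {
  if (contact_offset < 1.5)
    stop("contact_offset below 1.5 A would create steric overlap")
  dirv <- direction / sqrt(sum(direction^2))
  ra <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  pa <- as.matrix(peptide$atoms[, c("x", "y", "z")])
  # start from aligned centroids, push the peptide out along `direction`
  shift0 <- colMeans(ra) - colMeans(pa)
  pa0 <- sweep(pa, 2, shift0, "+")
  f <- function(t) min_cross_distance(ra, sweep(pa0, 2, t * dirv, "+")) -
    contact_offset
  tmax <- 10
  while (f(tmax) < 0 && tmax < 1e4) tmax <- tmax * 2
  t_star <- stats::uniroot(f, c(0, tmax), tol = 1e-4)$root
  shift <- shift0 + t_star * dirv

  pep <- shift_chain(peptide, shift, chain_id = "B")
  rec <- relabel_chain(receptor, "A")
  str <- pb_structure(id, list(rec, pep), method = "XRAY", resolution = 1.5)
  iface <- interface_residues(str, "A", "B", cutoff = 6.0)
  list(structure = str, receptor_chain = "A", peptide_chain = "B",
       true_site = iface$a)
}

#' @noRd
shift_chain <- function(chain, shift, chain_id = chain$chain_id) {
  atoms <- chain$atoms
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  pb_chain(chain_id, chain$resnames, sweep(chain$ca, 2, shift, "+"), atoms)
}

#' @noRd
relabel_chain <- function(chain, chain_id) {
  pb_chain(chain_id, chain$resnames, chain$ca, chain$atoms)
}

#' Add Gaussian coordinate noise to a chain
#' @param chain a [pb_chain()].
#' @param sigma noise standard deviation in Angstrom.
#' @param seed integer seed.
#' @return a perturbed [pb_chain()].
#' @export
perturb_chain <- function(chain, sigma, seed = 1) {
  if (sigma <= 0) return(chain)
  with_rng(seed, {
    ca <- chain$ca + matrix(stats::rnorm(3 * chain$length, sd = sigma),
                            chain$length, 3)
    atoms <- chain$atoms
    na <- nrow(atoms)
    noise <- matrix(stats::rnorm(3 * na, sd = sigma), na, 3)
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
    # keep CA rows of the atom table and the ca matrix coherent
    is_ca <- atoms$atom == "CA"
    ca[atoms$pos[is_ca], ] <- as.matrix(atoms[is_ca, c("x", "y", "z")])
    pb_chain(chain$chain_id, chain$resnames, ca, atoms)
  })
}

#' Build a template library with one planted true template among decoys
#'
#' The planted entry is a noise-perturbed copy of the target complex (the
#' receptor with its peptide and true interface), which should pass the
#' TM-score gate whenever `noise_sigma` is small (<= 1 A). Decoys are
#' unrelated synthetic folds paired with small partners; optionally,
#' `n_shifted` additional decoys are structural homologs of the target whose
#' partner binds elsewhere, providing negatives that pass the TM gate (used
#' to train the ranking forest).
#'
#' @param target output of [make_complex()].
#' @param n_decoys number of unrelated decoy templates.
#' @param noise_sigma coordinate noise (Angstrom) applied to the planted copy.
#' @param seed integer seed.
#' @param n_shifted number of wrong-site homolog decoys.
#' @return list with `library` (a template library) and `planted_id` (the
#'   source id of the planted entry).
#' @export
make_planted_library <- function(target, n_decoys = 20, noise_sigma = 0.5,
                                 seed = 1, n_shifted = 0) {
  entries <- list()

  rec <- get_chain(target$structure, target$receptor_chain)
  pep <- get_chain(target$structure, target$peptide_chain)
  planted_struct <- pb_structure("planted", list(
    relabel_chain(perturb_chain(rec, noise_sigma, seed = seed * 1000L + 1L), "A"),
    relabel_chain(perturb_chain(pep, noise_sigma, seed = seed * 1000L + 2L), "B")))
  planted <- template_entry_from_pair(planted_struct, "A", "B")
  if (is.null(planted)) stop("planted template lost its interface; lower noise_sigma")
  entries[["planted"]] <- planted

  topo <- c("HAIRPIN", "STRAND", "HELIX")
  lens <- with_rng(seed * 1000L + 3L, sample(30:70, n_decoys, replace = TRUE))
  for (k in seq_len(n_decoys)) {
    dseed <- seed * 1000L + 10L + k
    drec <- make_chain(topo[(k %% 3) + 1], lens[k], seed = dseed)
    dpep <- make_chain("HELIX", 8 + (k %% 5), seed = dseed + 500L)
    cx <- make_complex(drec, dpep, id = sprintf("decoy%02d", k))
    e <- template_entry_from_pair(cx$structure, "A", "B")
    if (!is.null(e)) {
      e$source_id <- sprintf("decoy%02d_A_B", k)
      entries[[e$source_id]] <- e
    }
  }

  # homologous receptors with the partner bound at a different face: pass the
  # TM gate but suggest the wrong site
  dirs <- list(c(0, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(n_shifted)) {
    hseed <- seed * 1000L + 600L + k
    hrec <- perturb_chain(rec, max(noise_sigma, 0.3), seed = hseed)
    hpep <- make_chain("HELIX", pep$length, seed = hseed + 50L)
    cx <- make_complex(hrec, hpep,
                       direction = unlist(dirs[(k - 1) %% length(dirs) + 1]),
                       id = sprintf("shifted%02d", k))
    e <- template_entry_from_pair(cx$structure, "A", "B")
    if (!is.null(e)) {
      e$source_id <- sprintf("shifted%02d_A_B", k)
      entries[[e$source_id]] <- e
    }
  }

  lib <- new_template_library(unname(entries),
                              meta = list(contact_cutoff = 6.0,
                                          min_receptor_len = 25L,
                                          source = "synthetic planted library",
                                          seed = seed,
                                          noise_sigma = noise_sigma))
  lib$entries[[1]]$source_id <- "planted_A_B"
  list(library = lib, planted_id = "planted_A_B")
}

#' Generate a labelled synthetic training set for the ranking forest
#'
#' Builds `n_targets` synthetic receptor-peptide complexes, each with its own
#' planted template library (true copy plus unrelated and wrong-site decoys),
#' scans each target against its library, computes candidate features and
#' labels candidates against the known true site.
#'
#' @param n_targets number of synthetic targets.
#' @param seed integer seed.
#' @param n_decoys unrelated decoys per target library.
#' @param n_shifted wrong-site homolog decoys per target library (these
#'   provide the negative examples that pass the TM gate).
#' @param label_threshold fraction of suggested residues that must be correct
#'   for a positive label, see [label_candidate()].
#' @return data frame of feature columns plus `label`, `group_id` and
#'   `template_source`, suitable for [train_ranker()].
#' @export
make_training_set <- function(n_targets = 8, seed = 1, n_decoys = 6,
                              n_shifted = 5, label_threshold = 0.8) {
  rows <- list()
  for (t in seq_len(n_targets)) {
    tseed <- seed * 10000L + t * 37L
    rec_len <- 50 + (t %% 4) * 6
    pep_len <- 7 + (t %% 5) * 2
    rec <- make_chain("HELIX_BUNDLE", rec_len, seed = tseed)
    pep <- make_chain("HELIX", pep_len, seed = tseed + 1L)
    cx <- make_complex(rec, pep, id = sprintf("train%02d", t))
    pl <- make_planted_library(cx, n_decoys = n_decoys, noise_sigma = 0.5,
                               seed = tseed + 2L, n_shifted = n_shifted)
    chain <- get_chain(cx$structure, "A")
    aux <- list(target_ss = assign_secondary_structure(chain),
                target_sasa = compute_sasa(pb_structure("t", list(chain)))[["A"]])
    cands <- scan_library(chain, pl$library)
    for (cand in cands) {
      fv <- compute_features(chain, pep$sequence, cand,
                             pl$library$entries[[cand$template_index]], aux)
      rows[[length(rows) + 1]] <- data.frame(
        t(fv),
        label = label_candidate(cand$site, cx$true_site, label_threshold),
        group_id = sprintf("train%02d", t),
        template_source = cand$source_id,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
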
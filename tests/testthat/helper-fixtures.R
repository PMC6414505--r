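# Shared fixtures and independent oracles used across test files.

# memoised heavy fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small labelled training set and ranker shared by pipeline tests
shared_training_set <- function() {
  cached("training_set", make_training_set(n_targets = 6, seed = 42))
}

shared_model <- function() {
  cached("model", train_ranker(shared_training_set(), seed = 7))
}

# one-chain structure from explicit atoms (all carbon), one atom per residue
# unless pos is given
atoms_structure <- function(xyz, pos = seq_len(nrow(xyz)), atom = "CA",
                            resnames = NULL, chain_id = "A", id = "fix") {
  xyz <- matrix(xyz, ncol = 3)
  n <- max(pos)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  ca <- matrix(NA_real_, n, 3)
  is_ca <- atom == "CA"
  if (length(atom) == 1) is_ca <- rep(is_ca, nrow(xyz))
  ca[pos[is_ca], ] <- xyz[is_ca, , drop = FALSE]
  atoms <- data.frame(pos = pos, atom = if (length(atom) == 1)
    rep(atom, nrow(xyz)) else atom,
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  pb_structure(id, list(pb_chain(chain_id, resnames, ca, atoms)))
}

# Monte-Carlo SASA estimator: random (not lattice) surface points per atom.
# Independent of the package implementation.
mc_sasa <- function(xyz, radii, probe = 1.4, n_points = 4000, seed = 99) {
  set.seed(seed)
  n <- nrow(xyz)
  rs <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rs[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, xyz[j, ], "-")^2)
      free <- free & d2 >= rs[j]^2
    }
    total <- total + 4 * pi * rs[i]^2 * mean(free)
  }
  total
}

# random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# rmsd of b vs a under rotation R with optimal translation (centroid match)
rmsd_under_rotation <- function(a, b, R) {
  ar <- a %*% t(R)
  ar <- sweep(ar, 2, colMeans(ar))
  bc <- sweep(b, 2, colMeans(b))
  sqrt(mean(rowSums((ar - bc)^2)))
}

# brute-force average-linkage (UPGMA) agglomeration on a distance matrix:
# recomputes every cluster-pair mean distance at each step. Returns merge
# heights and a function giving the partition below a cutoff.
brute_average_linkage <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list(clusters)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- mean(dm[clusters[[i]], clusters[[j]]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestd)
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights,
       cut = function(h) {
    k <- sum(heights <= h)
    partitions[[k + 1]]
  })
}

# canonical form of a partition (set of sorted member vectors) for comparison
canon_partition <- function(groups) {
  out <- lapply(groups, function(g) sort(as.integer(g)))
  out[order(vapply(out, `[`, integer(1), 1))]
}

# residue-site object from explicit coordinates
mk_site <- function(coords) {
  coords <- matrix(coords, ncol = 3)
  structure(list(chain_id = "A", members = seq_len(nrow(coords)),
                 coords = coords), class = "pb_site")
}

# simple candidate-like site list at given centers for clustering tests
sites_at <- function(centers, chain_len = 80) {
  chain <- make_chain("HELIX", chain_len, seed = 3)
  lapply(centers, function(cn) {
    members <- cn + 0:2
    site <- residue_site(chain, members)
    vec <- rep(FALSE, chain$length)
    vec[members] <- TRUE
    structure(list(source_id = paste0("s", cn), site = site,
                   interface_vector = vec,
                   aligned_interface_count = length(members)),
              class = "pb_candidate")
  })
}
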
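test_that("site distance is the mean over all cross pairs", {
  a <- mk_site(c(0, 0, 0))
  expect_identical(site_distance(a, a), 0)
  b <- mk_site(c(3, 4, 0))
  expect_identical(site_distance(a, b), 5)
  expect_identical(site_distance(b, a), 5)
  two <- mk_site(rbind(c(0, 0, 0), c(2, 0, 0)))
  one <- mk_site(c(1, 0, 0))
  expect_equal(site_distance(two, one), 1, tolerance = 1e-12)
  expect_error(site_distance(a, mk_site(matrix(0, 0, 3))), "empty")
})

test_that("elbow cutoff sits below the largest merge-height jump", {
  cut1 <- elbow_cutoff(c(1.0, 1.1, 1.2, 9.0))
  expect_gt(cut1, 1.2)
  expect_lte(cut1, 9.0)
  # uniform gaps: ties break to the lowest qualifying height
  cut2 <- elbow_cutoff(c(1, 2, 3, 4))
  expect_gte(cut2, 1)
  expect_lt(cut2, 2)
  # single merge: cutoff lies above it (one cluster)
  expect_gt(elbow_cutoff(3.2), 3.2)
})

test_that("cluster_sites separates planted groups and ranks by best member", {
  sites <- sites_at(c(5, 6, 60, 61))
  probs <- c(0.3, 0.9, 0.7, 0.2)
  clusters <- cluster_sites(sites, probs)
  expect_length(clusters, 2)
  expect_setequal(clusters[[1]]$members, c(1, 2))
  expect_setequal(clusters[[2]]$members, c(3, 4))
  expect_equal(clusters[[1]]$cluster_score, 0.9)
  expect_equal(clusters[[2]]$cluster_score, 0.7)
  # identical candidates collapse to one cluster
  same <- sites_at(c(10, 10, 10))
  one <- cluster_sites(same, c(0.9, 0.3, 0.5))
  expect_length(one, 1)
  expect_equal(one[[1]]$cluster_score, 0.9)
})

test_that("cluster ranking is invariant to candidate input order", {
  sites <- sites_at(c(5, 6, 60, 61, 30))
  probs <- c(0.3, 0.9, 0.7, 0.2, 0.5)
  base <- cluster_sites(sites, probs)
  perm <- c(4, 1, 5, 2, 3)
  permuted <- cluster_sites(sites[perm], probs[perm])
  base_sets <- canon_partition(lapply(base, function(cl) cl$members))
  perm_sets <- canon_partition(lapply(permuted, function(cl) perm[cl$members]))
  expect_equal(base_sets, perm_sets)
  expect_equal(vapply(base, `[[`, numeric(1), "cluster_score"),
               vapply(permuted, `[[`, numeric(1), "cluster_score"))
})

test_that("average-linkage clustering matches a brute-force oracle on small sets", {
  set.seed(91)
  for (trial in 1:12) {
    n <- sample(3:8, 1)
    # generic (tie-free) sites: 2-4 residues at random coordinates
    sites <- lapply(seq_len(n), function(i)
      mk_site(matrix(rnorm(3 * sample(2:4, 1), sd = 15), ncol = 3)))
    dm <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      dm[i, j] <- site_distance(sites[[i]], sites[[j]])
    oracle <- brute_average_linkage(dm)
    hc <- hclust(as.dist(dm), method = "average")
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-9)
    cutoff <- elbow_cutoff(hc$height)
    pkg_partition <- unname(split(seq_len(n), cutree(hc, h = cutoff)))
    expect_equal(canon_partition(pkg_partition),
                 canon_partition(oracle$cut(cutoff)))
  }
})

test_that("local scores are the probability-weighted membership consensus", {
  chain_len <- 10
  cand <- function(members) {
    vec <- rep(FALSE, chain_len)
    vec[members] <- TRUE
    structure(list(site = list(members = members), interface_vector = vec),
              class = "pb_candidate")
  }
  # single member: full consensus on its site
  cl1 <- list(members = 1L, probabilities = 0.7)
  ls1 <- local_scores(cl1, list(cand(5:7)), chain_len)
  expect_equal(as.numeric(ls1), c(rep(0, 4), 1, 1, 1, rep(0, 3)))
  # 20-member cluster: the top two (w = 0.8 and 0.6, sites {1,2} and {2,3})
  # are the 10% that contribute
  cands <- c(list(cand(1:2), cand(2:3)),
             lapply(3:20, function(i) cand(8:9)))
  cl2 <- list(members = seq_len(20L),
              probabilities = c(0.8, 0.6, rep(0.1, 18)))
  ls2 <- local_scores(cl2, cands, chain_len)
  expect_setequal(attr(ls2, "contributors"), c(1, 2))
  expect_equal(ls2[1], 0.8 / 1.4, tolerance = 1e-9)
  expect_equal(ls2[2], 1.0, tolerance = 1e-9)
  expect_equal(ls2[3], 0.6 / 1.4, tolerance = 1e-9)
  expect_true(all(ls2[4:10] == 0))
})

test_that("exactly the top 10% of cluster members contribute", {
  chain_len <- 30
  cands <- lapply(1:20, function(i) {
    vec <- rep(FALSE, chain_len); vec[i] <- TRUE
    structure(list(site = list(members = i), interface_vector = vec),
              class = "pb_candidate")
  })
  cl <- list(members = 1:20, probabilities = seq(0.05, 1, length.out = 20))
  ls <- local_scores(cl, cands, chain_len)
  expect_length(attr(ls, "contributors"), 2)  # ceil(0.1 * 20)
  expect_setequal(attr(ls, "contributors"), c(19, 20))
  expect_equal(sum(ls > 0), 2)
})

test_that("global score is the fixed 0.61/0.39 convex combination", {
  expect_identical(global_score(1, 1), 1)
  expect_identical(global_score(0.5, 0.5), 0.5)
  expect_equal(global_score(0.9, 1.0), 0.939, tolerance = 1e-12)
  grid <- expand.grid(c = seq(0, 1, 0.05), l = seq(0, 1, 0.05))
  for (i in seq_len(nrow(grid))) {
    expect_equal(global_score(grid$c[i], grid$l[i]),
                 0.61 * grid$c[i] + 0.39 * grid$l[i], tolerance = 1e-12)
  }
  expect_error(global_score(1.2, 0.5), "0, 1")
  expect_error(global_score(0.5, -0.1), "0, 1")
})

test_that("amino-acid preference profile weights contacting partner residues", {
  chain_len <- 12
  mk_cand <- function(tpos, rpos, idx) {
    vec <- rep(FALSE, chain_len); vec[rpos] <- TRUE
    structure(list(site = list(members = rpos), interface_vector = vec,
                   alignment = list(mapping = cbind(rpos, tpos)),
                   template_index = idx), class = "pb_candidate")
  }
  entry_leu <- list(receptor_interface = 4L, partner_contacts = list(`4` = "LL"))
  entry_arg <- list(receptor_interface = 4L, partner_contacts = list(`4` = "RR"))
  lib <- list(entries = list(entry_leu, entry_arg))
  # single template, all-Leu contacts
  cl1 <- list(members = 1L, probabilities = 0.8)
  prof1 <- aa_preference_profile(cl1, list(mk_cand(4L, 6L, 1L)), lib, chain_len)
  expect_equal(unname(prof1[6, "L"]), 1)
  expect_equal(sum(prof1[6, ]), 1)
  # two equal-weight templates, Leu vs Arg, same target residue
  cl2 <- list(members = c(1L, 2L), probabilities = c(0.8, 0.8))
  prof2 <- aa_preference_profile(cl2, list(mk_cand(4L, 6L, 1L),
                                           mk_cand(4L, 6L, 2L)), lib, chain_len)
  expect_equal(unname(prof2[6, "L"]), 0.5)
  expect_equal(unname(prof2[6, "R"]), 0.5)
  rs <- rowSums(prof2)
  expect_true(all(rs[rs > 0] - 1 < 1e-9))
})

test_that("predict_binding_site returns a complete, deterministic prediction", {
  model <- shared_model()
  rec <- make_chain("HELIX_BUNDLE", 60, seed = 92)
  pep <- make_chain("HELIX", 9, seed = 93)
  cx <- make_complex(rec, pep, id = "predfix")
  pl <- make_planted_library(cx, n_decoys = 6, noise_sigma = 0.5, seed = 94,
                             n_shifted = 2)
  p1 <- predict_binding_site(cx$structure, "A", pep$sequence, pl$library, model)
  expect_equal(p1$status, "ok")
  expect_true(all(p1$local_scores >= 0 & p1$local_scores <= 1))
  expect_true(all(diff(vapply(p1$clusters, `[[`, numeric(1), "cluster_score")) <= 0))
  cs <- p1$clusters[[1]]$cluster_score
  ml <- max(p1$local_scores)
  expect_equal(p1$global_score, 0.61 * cs + 0.39 * ml, tolerance = 1e-12)
  expect_gte(p1$global_score, min(cs, ml))
  expect_lte(p1$global_score, max(cs, ml))
  # residues outside contributing sites score exactly 0
  expect_true(all(p1$local_scores[setdiff(seq_len(60), p1$site$members)] == 0))
  # deterministic re-run
  p2 <- predict_binding_site(cx$structure, "A", pep$sequence, pl$library, model)
  expect_identical(p1$local_scores, p2$local_scores)
  expect_identical(p1$global_score, p2$global_score)
})

test_that("prediction reports no_templates when nothing passes the gate", {
  model <- shared_model()
  rec <- make_chain("HELIX_BUNDLE", 60, seed = 95)
  pep <- make_chain("HELIX", 9, seed = 96)
  cx <- make_complex(rec, pep, id = "nofit")
  # library of unrelated decoys only
  decoy <- make_chain("HAIRPIN", 50, seed = 97)
  dcx <- make_complex(decoy, pep, id = "dec")
  lib <- pepbind:::new_template_library(
    list(template_entry_from_pair(dcx$structure, "A", "B")))
  p <- predict_binding_site(cx$structure, "A", pep$sequence, lib, model)
  expect_equal(p$status, "no_templates")
  expect_true(all(p$local_scores == 0))
  expect_true(is.na(p$global_score))
  expect_length(p$site$members, 0)
})

test_that("write_prediction emits scores, JSON and B-factor PDB", {
  model <- shared_model()
  rec <- make_chain("HELIX_BUNDLE", 60, seed = 92)
  pep <- make_chain("HELIX", 9, seed = 93)
  cx <- make_complex(rec, pep, id = "outfix")
  pl <- make_planted_library(cx, n_decoys = 3, noise_sigma = 0.5, seed = 98)
  p <- predict_binding_site(cx$structure, "A", pep$sequence, pl$library, model)
  prefix <- file.path(withr::local_tempdir(), "pred")
  files <- write_prediction(p, cx$structure, "A", prefix)
  expect_true(all(file.exists(paste0(prefix, c(".scores.tsv", ".json",
                                               ".bfactor.pdb")))))
  tab <- read.delim(paste0(prefix, ".scores.tsv"))
  expect_equal(nrow(tab), 60)
  expect_equal(tab$local_score, round(p$local_scores, 6))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(js$global_score, p$global_score, tolerance = 1e-12)
  # B-factors round-trip the local scores (2-decimal PDB precision)
  back <- read_pdb(paste0(prefix, ".bfactor.pdb"))
  expect_equal(back$chains[["A"]]$length, 60)
})
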
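test_that("dataset filters reject out-of-range complexes with logged reasons", {
  rec <- make_chain("HELIX_BUNDLE", 45, seed = 101)
  good <- make_complex(rec, make_chain("HELIX", 9, seed = 102), id = "good")
  short <- make_complex(rec, make_chain("HELIX", 4, seed = 103), id = "short")
  long <- make_complex(rec, make_chain("HELIX", 26, seed = 104), id = "long")
  weak <- make_complex(rec, make_chain("HELIX", 9, seed = 102),
                       contact_offset = 5.5, id = "weak")
  lowres <- make_complex(rec, make_chain("HELIX", 9, seed = 102), id = "lowres")
  lowres$structure$resolution <- 3.5
  # thresholds scaled to the sparse-atom synthetic complexes; boundary
  # semantics (inclusive shared surface, exclusive burial) are what is tested
  cases <- filter_dataset(list(good, short, long, weak, lowres),
                          min_shared_surface = 150, n_points = 240)
  ids <- vapply(cases, function(cs) cs$structure$id, character(1))
  expect_equal(ids, "good")
  rej <- attr(cases, "rejected")
  expect_match(rej[["short"]], "peptide length 4")
  expect_match(rej[["long"]], "peptide length 26")
  expect_match(rej[["weak"]], "shared surface")
  expect_match(rej[["lowres"]], "resolution")
  expect_true(cases[[1]]$metadata$shared_surface >= 150)
  expect_lte(cases[[1]]$metadata$burial, 0.60)
  # idempotent: filtering the survivors changes nothing
  again <- filter_dataset(list(good), min_shared_surface = 150, n_points = 240)
  expect_equal(vapply(again, function(cs) cs$structure$id, character(1)), ids)
})

test_that("shared-surface and burial thresholds are boundary-inclusive", {
  rec <- make_chain("HELIX_BUNDLE", 45, seed = 101)
  cx <- make_complex(rec, make_chain("HELIX", 9, seed = 102), id = "b")
  shared <- buried_surface(cx$structure, "A", "B", n_points = 240)
  burial <- peptide_burial_fraction(cx$structure, "B", n_points = 240)
  # at exactly the measured values the case is kept ("at least" / "more than")
  kept <- filter_dataset(list(cx), min_shared_surface = shared,
                         max_burial = burial, n_points = 240)
  expect_length(kept, 1)
  just_over <- filter_dataset(list(cx), min_shared_surface = shared + 1e-6,
                              n_points = 240)
  expect_length(just_over, 0)
})

test_that("identity clustering keeps one representative per sequence family", {
  rec1 <- make_chain("HELIX_BUNDLE", 45, seed = 105)
  pep <- make_chain("HELIX", 9, seed = 106)
  cx1 <- make_complex(rec1, pep, id = "fam1a")
  # same sequence, slightly different coordinates: same family
  rec2 <- perturb_chain(rec1, 0.4, seed = 107)
  cx2 <- make_complex(rec2, pep, id = "fam1b")
  # unrelated sequence
  rec3 <- make_chain("HELIX_BUNDLE", 45, seed = 108)
  cx3 <- make_complex(rec3, pep, id = "fam2")
  for (cx in list(cx1, cx2, cx3)) cx$true_site <- cx$true_site
  cases <- lapply(list(cx1, cx2, cx3), function(cx)
    c(cx, list(true_site = cx$true_site)))
  reps <- cluster_by_identity(cases)
  ids <- vapply(reps, function(cs) cs$structure$id, character(1))
  expect_length(reps, 2)
  expect_true("fam2" %in% ids)
  expect_equal(sum(grepl("^fam1", ids)), 1)
  # identical receptors collapse to one
  same <- cluster_by_identity(list(cases[[1]], cases[[1]]))
  expect_length(same, 1)
  # single case passes through
  expect_length(cluster_by_identity(cases[3]), 1)
})

test_that("site identification applies the inclusive PPV >= 0.5 rule", {
  truth <- 1:20
  expect_identical(site_identified(c(1:5, 31:35), truth), 1L)  # 5 of 10
  expect_identical(site_identified(c(1:4, 31:36), truth), 0L)  # 4 of 10
  expect_identical(site_identified(integer(0), truth), 0L)
  # monotone: shrinking a prediction to its true-positive subset never flips 1 -> 0
  set.seed(109)
  for (k in 1:30) {
    pred <- sample(1:40, sample(4:12, 1))
    if (site_identified(pred, truth) == 1L) {
      expect_identical(site_identified(intersect(pred, truth), truth), 1L)
    }
  }
})

test_that("residue MCC matches hand-computed confusion matrices", {
  a <- c(1, 1, 0, 0, 1)
  expect_identical(residue_mcc(a, a), 1)
  expect_equal(residue_mcc(a, 1 - a), -1, tolerance = 1e-12)
  # TP=4 TN=4 FP=1 FN=1
  truth <- c(rep(1, 5), rep(0, 5))
  pred <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(residue_mcc(pred, truth), 0.6, tolerance = 1e-12)
  # degenerate marginals return 0 by convention
  expect_identical(residue_mcc(rep(1, 4), c(1, 1, 0, 0)), 0)
  expect_error(residue_mcc(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("precision-recall sweep matches a hand-enumerated 4-case example", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  identified <- c(1, 0, 1, 1)
  pr <- precision_recall_top1(scores, identified)
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3, 3 / 4))
  expect_equal(pr$recall, c(1 / 4, 1 / 4, 2 / 4, 3 / 4))
  # curve terminates at precision = recall when all predictions are made
  expect_equal(pr$precision[4], pr$recall[4] * 4 / 4 + 0)
  expect_equal(tail(pr$precision, 1), mean(identified))
  expect_equal(tail(pr$recall, 1), mean(identified))
  # all-correct predictions hold precision 1 everywhere
  pr2 <- precision_recall_top1(scores, c(1, 1, 1, 1))
  expect_true(all(pr2$precision == 1))
})

test_that("random baseline matches the hypergeometric closed form", {
  rec <- make_chain("HELIX_BUNDLE", 60, seed = 110)
  pep <- make_chain("HELIX", 9, seed = 111)
  cx <- make_complex(rec, pep, id = "rb")
  rb <- random_baseline(get_chain(cx$structure, "A"), cx$true_site,
                        seed = 3, trials = 10000)
  sigma_exact <- sqrt(rb$exact * (1 - rb$exact) / 10000)
  expect_lt(abs(rb$rate - rb$exact), 3 * max(sigma_exact, rb$sigma, 1e-4))
  # true site covering the whole surface is always identified
  chain <- get_chain(cx$structure, "A")
  sasa <- compute_sasa(pb_structure("t", list(chain)))[["A"]]
  aa <- pepbind:::aa_three_to_one(chain$resnames)
  ref <- pepbind:::MAX_SASA[aa]
  surface <- which(sasa / ref > 0.05)
  rb_all <- random_baseline(chain, surface, seed = 3, trials = 200, sasa = sasa)
  expect_equal(rb_all$rate, 1)
  expect_equal(rb_all$exact, 1)
  # per-draw expected overlap equals the hypergeometric mean n*K/N
  expect_error(random_baseline(chain, seq_len(chain$length), seed = 1,
                               trials = 10),
               "larger than the surface")
})

test_that("coverage regression reproduces exact decompositions", {
  y <- c(1, 1, 0, 0, 1, 0)
  fit1 <- coverage_regression(matrix(y, ncol = 1), y)
  expect_equal(fit1$beta, 1, tolerance = 1e-9)
  expect_equal(fit1$residual_norm, 0, tolerance = 1e-9)
  expect_identical(fit1$identified, 1L)
  # two disjoint half-sites whose union is y
  x1 <- c(1, 1, 0, 0, 0, 0)
  x2 <- c(0, 0, 0, 0, 1, 0)
  fit2 <- coverage_regression(cbind(x1, x2), y)
  expect_equal(fit2$beta, c(1, 1), tolerance = 1e-9)
  expect_equal(fit2$residual_norm, 0, tolerance = 1e-9)
  expect_equal(fit2$fitted_site, c(1L, 2L, 5L))
})

test_that("coverage-regression residual is non-increasing in template count", {
  set.seed(112)
  for (inst in 1:100) {
    L <- 40
    y <- as.numeric(seq_len(L) %in% sample(L, 8))
    templates <- lapply(1:6, function(i) as.numeric(runif(L) < 0.2))
    res <- vapply(1:6, function(k)
      coverage_regression(do.call(cbind, templates[1:k]), y)$residual_norm,
      numeric(1))
    expect_true(all(diff(res) <= 1e-9))
  }
})

test_that("random binary templates rarely explain a small site exactly", {
  set.seed(113)
  L <- 60
  y <- as.numeric(seq_len(L) %in% sample(L, 6))
  X <- matrix(as.numeric(runif(L * 5) < 0.15), L, 5)
  fit <- coverage_regression(X, y)
  expect_gt(fit$residual_norm, 0)
})
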
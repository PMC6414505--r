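#' Apply the benchmark dataset filters to candidate complexes
#'
#' Keeps protein-peptide complexes satisfying all of: peptide length 5-25;
#' shared (buried) surface >= 400 A^2; peptide burial <= 60%; and, for X-ray
#' entries, resolution <= 3 A. Rejection reasons are recorded per complex.
#'
#' @param complexes list of complexes, each `list(structure, receptor_chain,
#'   peptide_chain)` (as produced by [make_complex()]).
#' @param min_shared_surface minimum buried surface in square Angstrom.
#' @param max_burial maximum peptide burial fraction.
#' @param max_resolution maximum X-ray resolution in Angstrom.
#' @param n_points SASA sphere points, see [compute_sasa()].
#' @return list of benchmark cases (`pb_case`): the complex fields plus
#'   `true_site` and `metadata`. Rejections are attached as attribute
#'   `"rejected"` (named character vector of reasons).
#' @export
filter_dataset <- function(complexes, min_shared_surface = 400,
                           max_burial = 0.60, max_resolution = 3.0,
                           n_points = 960) {
  cases <- list()
  rejected <- character(0)
  for (cx in complexes) {
    s <- cx$structure
    pep <- get_chain(s, cx$peptide_chain)
    reason <- NULL
    if (pep$length < 5 || pep$length > 25) {
      reason <- sprintf("peptide length %d outside [5, 25]", pep$length)
    } else if (s$method == "XRAY" && !is.na(s$resolution) &&
               s$resolution > max_resolution) {
      reason <- sprintf("resolution %.2f above %.1f A", s$resolution, max_resolution)
    } else {
      shared <- buried_surface(s, cx$receptor_chain, cx$peptide_chain,
                               n_points = n_points)
      if (shared < min_shared_surface) {
        reason <- sprintf("shared surface %.0f below %.0f A^2", shared,
                          min_shared_surface)
      } else {
        burial <- peptide_burial_fraction(s, cx$peptide_chain, n_points = n_points)
        if (burial > max_burial) {
          reason <- sprintf("peptide burial %.2f above %.2f", burial, max_burial)
        }
      }
    }
    if (!is.null(reason)) {
      rejected[s$id] <- reason
      next
    }
    true_site <- interface_residues(s, cx$receptor_chain, cx$peptide_chain)$a
    cases[[length(cases) + 1]] <- base::structure(
      c(cx, list(true_site = true_site,
                 metadata = list(resolution = s$resolution, method = s$method,
                                 shared_surface = shared, burial = burial))),
      class = "pb_case")
  }
  attr(cases, "rejected") <- rejected
  cases
}

#' Greedy redundancy reduction at a sequence-identity threshold
#'
#' Single-linkage clustering on pairwise receptor sequence identity (global
#' alignment, matches over alignment length); one representative per cluster,
#' the longest receptor (ties by structure id).
#'
#' @param cases list of benchmark cases.
#' @param identity_threshold linkage threshold.
#' @return the representative cases.
#' @export
cluster_by_identity <- function(cases, identity_threshold = 0.30) {
  n <- length(cases)
  stopifnot(n >= 1)
  if (n == 1) return(cases)
  seqs <- vapply(cases, function(cs)
    get_chain(cs$structure, cs$receptor_chain)$sequence, character(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sequence_identity(seqs[i], seqs[j]) >= identity_threshold) {
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), root), function(idx) {
    lens <- nchar(seqs[idx])
    ids <- vapply(cases[idx], function(cs) cs$structure$id, character(1))
    idx[order(-lens, ids)][1]
  }, integer(1))
  cases[sort(reps)]
}

#' Is a predicted site identified?
#'
#' A site counts as identified when at least half of the predicted residues
#' lie in the true site (PPV >= 0.5); an empty prediction is never identified.
#'
#' @param predicted_site a [residue_site()] or integer vector.
#' @param true_site same.
#' @return integer, 1 or 0.
#' @export
site_identified <- function(predicted_site, true_site) {
  pred <- site_members(predicted_site)
  if (!length(pred)) return(0L)
  truth <- site_members(true_site)
  as.integer(length(intersect(pred, truth)) / length(pred) >= 0.5)
}

#' Matthews correlation coefficient between binary residue vectors
#'
#' @param prediction_vector,truth_vector equal-length binary (or logical)
#'   vectors.
#' @return MCC in `[-1, 1]`; 0 when any marginal is degenerate.
#' @export
residue_mcc <- function(prediction_vector, truth_vector) {
  p <- as.integer(as.logical(prediction_vector))
  t <- as.integer(as.logical(truth_vector))
  if (length(p) != length(t)) stop("vectors must have equal length")
  tp <- sum(p == 1 & t == 1); tn <- sum(p == 0 & t == 0)
  fp <- sum(p == 1 & t == 0); fn <- sum(p == 0 & t == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Precision-recall curve over top-1 predictions
#'
#' Sweeps the global-score threshold from high to low; at each prediction,
#' precision is the fraction of predictions made so far that are correct and
#' recall the fraction of all cases identified. The curve terminates at
#' precision = recall when every case has a prediction.
#'
#' @param scores numeric vector of global scores (one per case; `NA` = no
#'   prediction made).
#' @param identified binary vector, 1 when the case's top-1 site was
#'   identified.
#' @return data frame with columns `score`, `precision`, `recall`.
#' @export
precision_recall_top1 <- function(scores, identified) {
  stopifnot(length(scores) == length(identified))
  n <- length(scores)
  made <- which(!is.na(scores))
  ord <- made[order(-scores[made])]
  correct <- cumsum(identified[ord])
  data.frame(score = scores[ord],
             precision = correct / seq_along(ord),
             recall = correct / n)
}

#' Random-site baseline identification rate
#'
#' Monte-Carlo estimate of the probability that predicting `n` residues drawn
#' uniformly from the receptor surface identifies the true site (PPV >= 0.5),
#' with `n` the true site size. Surface residues are those with relative
#' exposure above `surface_threshold` in the unbound receptor. The analytic
#' reference is hypergeometric: `P(X >= ceil(n/2))` with `X ~
#' Hypergeom(N = |surface|, K = |true site on surface|, n)`.
#'
#' @param chain receptor [pb_chain()].
#' @param true_site the true [residue_site()].
#' @param seed integer seed.
#' @param trials Monte-Carlo trials.
#' @param surface_threshold relative-exposure cutoff defining the surface.
#' @param sasa optional precomputed per-residue SASA vector for the unbound
#'   chain.
#' @return list with `rate`, `sigma` (binomial standard error), `exact`
#'   (hypergeometric closed form), `n_surface`, `n_true_surface`, `n_drawn`.
#' @export
random_baseline <- function(chain, true_site, seed, trials = 10000,
                            surface_threshold = 0.05, sasa = NULL) {
  if (is.null(sasa)) {
    sasa <- compute_sasa(pb_structure("t", list(chain)))[[chain$chain_id]]
  }
  aa <- aa_three_to_one(chain$resnames)
  ref <- MAX_SASA[aa]; ref[is.na(ref)] <- MAX_SASA[["X"]]
  surface <- which(sasa / ref > surface_threshold)
  truth <- site_members(true_site)
  n_draw <- length(truth)
  if (n_draw > length(surface))
    stop("true site larger than the surface residue set")
  k_true <- length(intersect(truth, surface))
  hits <- with_rng(seed, {
    vapply(seq_len(trials), function(i)
      site_identified(sample(surface, n_draw), truth), integer(1))
  })
  rate <- mean(hits)
  need <- ceiling(n_draw / 2)
  exact <- stats::phyper(need - 1, k_true, length(surface) - k_true, n_draw,
                         lower.tail = FALSE)
  list(rate = rate, sigma = sqrt(rate * (1 - rate) / trials), exact = exact,
       n_surface = length(surface), n_true_surface = k_true, n_drawn = n_draw)
}

#' Template-coverage regression
#'
#' Fits the binary true-interface vector `y` as a linear combination of the
#' binary template interface vectors `x_z` by (minimum-norm) ordinary least
#' squares; the fitted values are the best prediction available from the
#' library. The fitted site is the `|y|` highest-scoring residues, and the
#' target counts as modellable when that site is identified.
#'
#' @param template_vectors matrix with one column per template (rows =
#'   receptor residues), or a list of equal-length vectors.
#' @param truth binary vector over receptor residues.
#' @return a `pb_coverage_fit`: `beta`, `residual_norm`, `best_prediction`,
#'   `fitted_site`, `identified`.
#' @export
coverage_regression <- function(template_vectors, truth) {
  X <- if (is.list(template_vectors)) do.call(cbind, template_vectors)
       else as.matrix(template_vectors)
  y <- as.numeric(truth)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1)
  beta <- as.vector(MASS::ginv(X) %*% y)
  p <- as.vector(X %*% beta)
  n_true <- sum(y > 0)
  fitted_site <- if (n_true > 0) order(-p, seq_along(p))[seq_len(n_true)]
                 else integer(0)
  base::structure(list(beta = beta,
                       residual_norm = sqrt(sum((y - p)^2)),
                       best_prediction = p,
                       fitted_site = sort(fitted_site),
                       identified = site_identified(fitted_site, which(y > 0))),
                  class = "pb_coverage_fit")
}

#' Run the benchmark over a set of cases
#'
#' Predicts every case's binding site and evaluates it with the standard
#' criteria (PPV >= 0.5 identification, per-residue MCC).
#'
#' @param cases list of benchmark cases (see [filter_dataset()] or
#'   [make_complex()] plus a `true_site`).
#' @param library a `pb_library`.
#' @param model a `pb_ranker`.
#' @param aux optional auxiliary inputs passed to every prediction.
#' @return data frame with one row per case: `id`, `global_score`, `ppv`,
#'   `identified`, `mcc`, `status`.
#' @export
run_benchmark <- function(cases, library, model, aux = list()) {
  rows <- lapply(cases, function(cs) {
    pred <- predict_binding_site(cs$structure, cs$receptor_chain,
                                 get_chain(cs$structure, cs$peptide_chain)$sequence,
                                 library, model, aux = aux)
    chain <- get_chain(cs$structure, cs$receptor_chain)
    truth_vec <- seq_len(chain$length) %in% cs$true_site$members
    ppv <- if (length(pred$site$members))
      length(intersect(pred$site$members, cs$true_site$members)) /
        length(pred$site$members) else 0
    data.frame(id = cs$structure$id,
               global_score = pred$global_score,
               ppv = ppv,
               identified = site_identified(pred$site, cs$true_site),
               mcc = residue_mcc(pred$local_scores > 0.5, truth_vec),
               status = pred$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
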
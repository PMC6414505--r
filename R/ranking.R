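#' Label a candidate site against the true site
#'
#' A template is correct when at least `threshold` (default 80%) of the
#' residues it suggests belong to the true interaction site.
#'
#' @param candidate_site a [residue_site()] or integer vector of residue
#'   positions.
#' @param true_site same.
#' @param threshold minimum fraction of suggested residues that are correct.
#' @return integer label, 1 (correct) or 0.
#' @export
label_candidate <- function(candidate_site, true_site, threshold = 0.8) {
  cand <- site_members(candidate_site)
  truth <- site_members(true_site)
  if (!length(cand)) stop("cannot label an empty candidate site")
  as.integer(length(intersect(cand, truth)) / length(cand) >= threshold)
}

#' @noRd
site_members <- function(x) {
  if (inherits(x, "pb_site")) x$members else sort(unique(as.integer(x)))
}

#' Cap the number of training examples contributed per target pair
#'
#' Each `group_id` (one protein-peptide pair) contributes at most `cap`
#' examples, selected uniformly without replacement; deterministic for a
#' fixed seed.
#'
#' @param examples data frame with a `group_id` column.
#' @param cap maximum examples per group.
#' @param seed integer seed.
#' @return the subsampled data frame (original row order preserved).
#' @export
subsample_per_pair <- function(examples, cap = 2000, seed) {
  stopifnot(!missing(seed), "group_id" %in% names(examples))
  keep <- with_rng(seed, {
    unlist(lapply(split(seq_len(nrow(examples)), examples$group_id), function(idx) {
      if (length(idx) <= cap) idx else sort(sample(idx, cap))
    }), use.names = FALSE)
  })
  examples[sort(keep), , drop = FALSE]
}

#' Leave-one-target-out splits with structural-similarity exclusion
#'
#' One split per target: the test set is that target's examples; the training
#' set is every other target's examples except those from targets with a
#' TM-score >= `tm_exclude` to the test target.
#'
#' @param examples data frame with a `group_id` column.
#' @param tm_matrix square numeric matrix of pairwise target TM-scores with
#'   dimnames covering all group ids.
#' @param tm_exclude similarity threshold above which targets are excluded
#'   from training.
#' @return list of splits, each `list(target, train, test)` with integer row
#'   indices into `examples`.
#' @export
jackknife_partitions <- function(examples, tm_matrix, tm_exclude = 0.5) {
  groups <- unique(examples$group_id)
  missing <- setdiff(groups, rownames(tm_matrix))
  if (length(missing))
    stop(sprintf("tm_matrix has no entry for target '%s'", missing[1]))
  lapply(groups, function(g) {
    sim <- tm_matrix[g, groups]
    excluded <- groups[groups == g | sim >= tm_exclude]
    train <- which(!(examples$group_id %in% excluded))
    if (!length(train))
      stop(sprintf("empty training set for target '%s' (all other targets excluded)", g))
    list(target = g, train = train, test = which(examples$group_id == g))
  })
}

#' Train the template-ranking random forest
#'
#' Probability forest with 100 trees, no depth limit and `sqrt(N)` candidate
#' features per split, trained on labelled candidate-site feature vectors.
#'
#' @param examples data frame with feature columns (see [feature_names()]),
#'   plus `label` (0/1). Extra bookkeeping columns `group_id` and
#'   `template_source` are ignored by the learner.
#' @param seed integer seed (required; recorded in the model metadata).
#' @param num_trees number of trees.
#' @return a ranker model of class `pb_ranker`.
#' @export
train_ranker <- function(examples, seed, num_trees = 100) {
  stopifnot(!missing(seed), "label" %in% names(examples))
  feats <- setdiff(names(examples), c("label", "group_id", "template_source"))
  if (length(unique(examples$label)) < 2)
    stop("training requires both correct and incorrect templates")
  dat <- examples[, feats, drop = FALSE]
  dat$label <- factor(examples$label, levels = c(0, 1))
  forest <- ranger::ranger(
    dependent.variable.name = "label", data = dat,
    num.trees = num_trees, mtry = max(1L, floor(sqrt(length(feats)))),
    min.node.size = 1, probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1)
  base::structure(list(forest = forest, features = feats,
                       meta = list(seed = seed, n = nrow(examples),
                                   n_positive = sum(examples$label == 1),
                                   num_trees = num_trees)),
                  class = "pb_ranker")
}

#' @export
print.pb_ranker <- function(x, ...) {
  cat(sprintf("<pb_ranker> %d trees, %d features, trained on %d examples (%d positive)\n",
              x$meta$num_trees, length(x$features), x$meta$n, x$meta$n_positive))
  invisible(x)
}

#' Probability that a candidate template is correct
#'
#' @param model a `pb_ranker`.
#' @param features named numeric vector, matrix or data frame of feature
#'   values (names must cover the model's feature list).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.data.frame(features)
  missing <- setdiff(model$features, names(features))
  if (length(missing))
    stop(sprintf("feature '%s' missing from input", missing[1]))
  pred <- stats::predict(model$forest, data = features[, model$features, drop = FALSE],
                         num.threads = 1)
  unname(pred$predictions[, "1"])
}

#' Gini-impurity feature importances
#'
#' @param model a `pb_ranker`.
#' @return named non-negative weights summing to 1.
#' @export
feature_importances <- function(model) {
  imp <- model$forest$variable.importance
  imp <- pmax(imp, 0)
  imp / sum(imp)
}

#' Jack-knifed out-of-target predictions
#'
#' For every split from [jackknife_partitions()], trains a forest on the
#' training rows and predicts the held-out target's examples.
#'
#' @inheritParams jackknife_partitions
#' @param seed integer seed used for every per-split forest.
#' @return numeric vector of predicted probabilities aligned with
#'   `examples` rows.
#' @export
jackknife_predict <- function(examples, tm_matrix, seed, tm_exclude = 0.5) {
  splits <- jackknife_partitions(examples, tm_matrix, tm_exclude)
  probs <- rep(NA_real_, nrow(examples))
  feats <- setdiff(names(examples), c("label", "group_id", "template_source"))
  for (sp in splits) {
    model <- train_ranker(examples[sp$train, , drop = FALSE], seed = seed)
    probs[sp$test] <- predict_probability(model,
                                          examples[sp$test, feats, drop = FALSE])
  }
  probs
}
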
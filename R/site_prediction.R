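# Weights combining cluster score and best local score into the global
# confidence score.
W_CLUSTER <- 0.61
W_LOCAL <- 0.39

#' Distance between two candidate interaction surfaces
#'
#' Mean Euclidean C-alpha distance over all cross pairs of the two sites'
#' member residues; symmetric and defined for sites of unequal size.
#'
#' @param site_a,site_b [residue_site()]s with coordinates.
#' @return distance in Angstrom.
#' @export
site_distance <- function(site_a, site_b) {
  if (!length(site_a$members) || !length(site_b$members))
    stop("site distance undefined for an empty site")
  mean_cross_distance(site_a$coords, site_b$coords)
}

#' Automatic dendrogram cutoff by the elbow method
#'
#' The cutoff is placed just below the merge with the largest increase over
#' its predecessor (maximum first difference of the sorted merge heights);
#' ties are broken toward the lowest qualifying height. With a single merge
#' the cutoff lies above it (one cluster).
#'
#' @param merge_heights sorted dendrogram merge distances.
#' @return cutoff height in Angstrom.
#' @export
elbow_cutoff <- function(merge_heights) {
  h <- sort(merge_heights)
  if (length(h) < 2) return(h[length(h)] + 1)
  gaps <- diff(h)
  k <- which.max(gaps)  # first maximum on ties
  (h[k] + h[k + 1]) / 2
}

#' Cluster candidate sites and rank the clusters
#'
#' Average-linkage agglomerative clustering under [site_distance()], cut at
#' the [elbow_cutoff()]; each cluster is scored by the highest random-forest
#' probability among its members and clusters are returned in descending
#' score order (ties broken by the lowest first-member index).
#'
#' @param candidates list of `pb_candidate` objects.
#' @param probabilities numeric vector of RF probabilities parallel to
#'   `candidates`.
#' @return list of clusters, each `list(members, probabilities,
#'   cluster_score)` where `members` are indices into `candidates`.
#' @export
cluster_sites <- function(candidates, probabilities) {
  n <- length(candidates)
  stopifnot(n >= 1, length(probabilities) == n)
  if (n == 1) {
    assign <- 1L
  } else {
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <- site_distance(candidates[[i]]$site,
                                            candidates[[j]]$site)
    }
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    assign <- stats::cutree(hc, h = elbow_cutoff(hc$height))
  }
  clusters <- lapply(sort(unique(assign)), function(k) {
    idx <- which(assign == k)
    list(members = idx, probabilities = probabilities[idx],
         cluster_score = max(probabilities[idx]))
  })
  scores <- vapply(clusters, `[[`, numeric(1), "cluster_score")
  firsts <- vapply(clusters, function(cl) min(cl$members), numeric(1))
  clusters[order(-scores, firsts)]
}

#' Per-residue local scores from the top cluster
#'
#' The top 10% (by RF probability, at least one) of the cluster's templates
#' are combined by weighted average of their binary interface vectors, the
#' weights being the probabilities: `score(r) = sum(w_i x_i(r)) / sum(w_i)`.
#'
#' @param cluster one cluster from [cluster_sites()].
#' @param candidates the candidate list the cluster indexes into.
#' @param n_residues target chain length.
#' @return numeric vector of length `n_residues` with values in `[0, 1]`,
#'   non-zero only on residues suggested by the contributing templates. The
#'   indices of the contributing candidates are attached as attribute
#'   `"contributors"`.
#' @export
local_scores <- function(cluster, candidates, n_residues) {
  stopifnot(length(cluster$members) >= 1)
  n_top <- max(1L, ceiling(0.1 * length(cluster$members)))
  ord <- order(-cluster$probabilities, cluster$members)
  top <- ord[seq_len(n_top)]
  idx <- cluster$members[top]
  w <- cluster$probabilities[top]
  num <- numeric(n_residues)
  for (k in seq_along(idx)) {
    num <- num + w[k] * as.numeric(candidates[[idx[k]]]$interface_vector)
  }
  out <- num / sum(w)
  attr(out, "contributors") <- idx
  out
}

#' Global confidence score
#'
#' Weighted mean of the top cluster score and the maximum local score with
#' weights 0.61 and 0.39.
#'
#' @param cluster_score top cluster score in `[0, 1]`.
#' @param max_local maximum local score in `[0, 1]`.
#' @return global score in `[0, 1]`.
#' @export
global_score <- function(cluster_score, max_local) {
  if (cluster_score < 0 || cluster_score > 1 || max_local < 0 || max_local > 1)
    stop("global score inputs must lie in [0, 1]")
  W_CLUSTER * cluster_score + W_LOCAL * max_local
}

#' Amino-acid preference profile of the predicted site
#'
#' For each predicted target residue, the probability-weighted frequency of
#' the partner-chain residue types that contact the template interface
#' residue mapped onto it, accumulated over all templates in the cluster
#' (weighted by their probabilities). Rows sum to 1; residues with no contacting template
#' evidence are all-zero. This construction is a documented reconstruction:
#' contacts are read from the template's heavy-atom contact map recorded at
#' library build time.
#'
#' @param cluster one cluster from [cluster_sites()].
#' @param candidates the candidate list.
#' @param library the template library the candidates were scanned from.
#' @param n_residues target chain length.
#' @return `n_residues x 20` matrix of amino-acid frequencies.
#' @export
aa_preference_profile <- function(cluster, candidates, library, n_residues) {
  stopifnot(length(cluster$members) >= 1)
  prof <- matrix(0, n_residues, 20, dimnames = list(NULL, AA1))
  for (k in seq_along(cluster$members)) {
    cand <- candidates[[cluster$members[k]]]
    w <- cluster$probabilities[k]
    entry <- library$entries[[cand$template_index]]
    mapping <- cand$alignment$mapping
    for (p in entry$receptor_interface) {
      hit <- match(p, mapping[, 2])
      if (is.na(hit)) next
      r <- mapping[hit, 1]
      letters1 <- strsplit(entry$partner_contacts[[as.character(p)]], "")[[1]]
      letters1 <- letters1[letters1 %in% AA1]
      for (l in letters1) prof[r, l] <- prof[r, l] + w
    }
  }
  rs <- rowSums(prof)
  nz <- rs > 0
  prof[nz, ] <- prof[nz, , drop = FALSE] / rs[nz]
  prof
}

#' Predict the peptide binding site on a receptor structure
#'
#' Full pipeline: scan the template library with the receptor chain, compute
#' the feature vector of every surviving candidate, score candidates with the
#' ranking forest, cluster the candidate surfaces, and derive local scores,
#' the global confidence score and the amino-acid preference profile from the
#' top cluster.
#'
#' @param target a [pb_structure()].
#' @param chain_id receptor chain identifier.
#' @param peptide_seq one-letter peptide sequence.
#' @param library a `pb_library`.
#' @param model a `pb_ranker`.
#' @param aux optional auxiliary inputs (see [compute_features()]).
#' @param tm_cutoff TM-score significance gate for the library scan.
#' @return a `pb_prediction`: `status` (`"ok"` or `"no_templates"`),
#'   `clusters`, `candidates`, `probabilities`, `local_scores`,
#'   `global_score`, `site` (predicted [residue_site()], local score > 0),
#'   `aa_profile`, and `provenance`.
#' @export
predict_binding_site <- function(target, chain_id, peptide_seq, library, model,
                                 aux = list(), tm_cutoff = 0.5) {
  chain <- get_chain(target, chain_id)
  if (is.null(aux$target_ss)) aux$target_ss <- assign_secondary_structure(chain)
  if (is.null(aux$target_sasa)) {
    aux$target_sasa <- compute_sasa(pb_structure("t", list(chain)))[[chain$chain_id]]
  }
  provenance <- list(structure = target$id, chain = chain_id,
                     peptide = peptide_seq,
                     library = library$meta, model = model$meta,
                     tm_cutoff = tm_cutoff,
                     peptide_ss_source = if (is.null(aux$peptide_ss))
                       "chou-fasman fallback" else "user-supplied",
                     weights = c(cluster = W_CLUSTER, local = W_LOCAL))

  candidates <- scan_library(chain, library, tm_cutoff)
  if (!length(candidates)) {
    return(base::structure(list(status = "no_templates", clusters = list(),
                                candidates = list(), probabilities = numeric(0),
                                local_scores = numeric(chain$length),
                                global_score = NA_real_,
                                site = residue_site(chain, integer(0)),
                                aa_profile = NULL, provenance = provenance),
                           class = "pb_prediction"))
  }
  fmat <- do.call(rbind, lapply(candidates, function(cand)
    compute_features(chain, peptide_seq, cand,
                     library$entries[[cand$template_index]], aux)))
  probs <- predict_probability(model, fmat)
  clusters <- cluster_sites(candidates, probs)
  top <- clusters[[1]]
  loc <- local_scores(top, candidates, chain$length)
  gs <- global_score(top$cluster_score, max(loc))
  prof <- aa_preference_profile(top, candidates, library, chain$length)
  base::structure(list(status = "ok", clusters = clusters,
                       candidates = candidates, probabilities = probs,
                       local_scores = as.numeric(loc), global_score = gs,
                       site = residue_site(chain, which(loc > 0)),
                       aa_profile = prof, provenance = provenance),
                  class = "pb_prediction")
}

#' @export
print.pb_prediction <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<pb_prediction> %s (no template passed the TM-score gate)\n",
                x$status))
    return(invisible(x))
  }
  cat(sprintf("<pb_prediction> %d candidate(s) in %d cluster(s)\n",
              length(x$candidates), length(x$clusters)))
  cat(sprintf("  global score %.3f (cluster %.3f, max local %.3f)\n",
              x$global_score, x$clusters[[1]]$cluster_score, max(x$local_scores)))
  cat(sprintf("  predicted site: %s\n", paste(x$site$members, collapse = ",")))
  invisible(x)
}

#' Write prediction outputs to files
#'
#' Writes `<prefix>.scores.tsv` (residue index, residue name, local score),
#' `<prefix>.json` (clusters, scores, profile, provenance) and
#' `<prefix>.bfactor.pdb` (local scores in the B-factor column).
#'
#' @param prediction a `pb_prediction`.
#' @param target the [pb_structure()] that was predicted on.
#' @param chain_id receptor chain identifier.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_prediction <- function(prediction, target, chain_id, prefix) {
  chain <- get_chain(target, chain_id)
  tsv <- paste0(prefix, ".scores.tsv")
  utils::write.table(
    data.frame(pos = seq_len(chain$length), residue = chain$resnames,
               local_score = round(prediction$local_scores, 6)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    status = prediction$status,
    global_score = prediction$global_score,
    clusters = lapply(prediction$clusters, function(cl)
      list(members = cl$members, cluster_score = cl$cluster_score)),
    predicted_site = prediction$site$members,
    aa_profile = prediction$aa_profile,
    provenance = prediction$provenance), js, auto_unbox = TRUE, digits = NA,
    null = "null")
  pdbf <- paste0(prefix, ".bfactor.pdb")
  scores <- list()
  scores[[chain_id]] <- prediction$local_scores
  write_pdb(target, pdbf, scores = scores)
  invisible(c(tsv, js, pdbf))
}
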
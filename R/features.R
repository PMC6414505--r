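#' Names of the candidate-site features, in model order
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c("target_peptide_len", "target_protein_len", "template_chain_len",
    "aligned_segment_len", "aligned_interface_count",
    "tm_target", "tm_template", "rmsd",
    "contact_order", "longest_aligned_helix",
    "pep_comp_dist", "prot_comp_dist",
    "target_pep_ss_h", "target_pep_ss_e", "target_pep_ss_c",
    "template_surface_ss_h", "template_surface_ss_e", "template_surface_ss_c",
    "rel_exposure", "conservation",
    "mean_seq_dist", "median_seq_dist", "summed_segment_lengths")
}

#' Amino-acid composition distance between two sequences
#'
#' Euclidean distance between the 20-dimensional relative amino-acid
#' frequency vectors; 0 iff the compositions are identical, order-independent.
#'
#' @param seq_a,seq_b one-letter sequences.
#' @return non-negative scalar.
#' @export
composition_distance <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("composition of an empty sequence")
  fa <- aa_frequencies(seq_a)
  fb <- aa_frequencies(seq_b)
  sqrt(sum((fa - fb)^2))
}

#' @noRd
aa_frequencies <- function(seq) {
  letters1 <- strsplit(seq, "")[[1]]
  counts <- table(factor(letters1, levels = AA1))
  n <- sum(counts)
  if (n == 0) stop("sequence contains no standard amino acids")
  as.numeric(counts) / n
}

#' Relative contact order of an aligned region
#'
#' Over residues in `aligned_positions`, contacts are pairs with any heavy
#' atoms within `cutoff` and sequence separation `|i - j| >= 3`. The relative
#' contact order is `sum(|i - j|) / (L * N)` with `L` the aligned-region span
#' and `N` the number of contacts; 0 when there are no contacts.
#'
#' @param target_chain a [pb_chain()].
#' @param aligned_positions integer vector of aligned residue positions.
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @return scalar >= 0.
#' @export
contact_order <- function(target_chain, aligned_positions, cutoff = 6.0) {
  pos <- sort(unique(as.integer(aligned_positions)))
  if (length(pos) < 2) stop("contact order requires at least 2 aligned positions")
  a <- target_chain$atoms[target_chain$atoms$pos %in% pos, , drop = FALSE]
  pairs <- .contact_pairs_cpp(as.matrix(a[, c("x", "y", "z")]), as.integer(a$pos),
                              as.matrix(a[, c("x", "y", "z")]), as.integer(a$pos),
                              cutoff)
  sep <- pairs[, 2] - pairs[, 1]
  keep <- sep >= 3  # each contact counted once (i < j)
  if (!any(keep)) return(0)
  span <- max(pos) - min(pos) + 1
  sum(sep[keep]) / (span * sum(keep))
}

#' Longest run of aligned helical residues
#'
#' @param target_ss secondary-structure string covering the chain.
#' @param aligned_positions integer vector of aligned residue positions.
#' @return length (residues) of the longest run of consecutive aligned
#'   positions labelled `H`.
#' @export
longest_aligned_helix <- function(target_ss, aligned_positions) {
  ss <- strsplit(target_ss, "")[[1]]
  pos <- sort(unique(as.integer(aligned_positions)))
  flag <- logical(length(ss))
  flag[pos] <- TRUE
  run <- flag & ss == "H"
  if (!any(run)) return(0L)
  r <- rle(run)
  max(r$lengths[r$values])
}

#' Sequential statistics of a template's partner interface
#'
#' Gaps are the index differences between consecutive (sorted) partner
#' interface residues. Returns the mean and median gap (0 for a singleton)
#' and the summed length of the maximal consecutive runs.
#'
#' @param template_entry a `pb_template`.
#' @return named numeric vector `mean_seq_dist`, `median_seq_dist`,
#'   `summed_segment_lengths`.
#' @export
template_partner_stats <- function(template_entry) {
  m <- sort(template_entry$partner_interface)
  if (!length(m)) stop("partner interface is empty")
  gaps <- diff(m)
  segments <- split(m, cumsum(c(1, diff(m) != 1)))
  c(mean_seq_dist = if (length(gaps)) mean(gaps) else 0,
    median_seq_dist = if (length(gaps)) stats::median(gaps) else 0,
    summed_segment_lengths = sum(lengths(segments)))
}

#' Secondary-structure fractions of a template's partner interface
#'
#' @param template_entry a `pb_template`.
#' @return numeric vector `(h, e, c)` summing to 1.
#' @export
surface_ss_fractions <- function(template_entry) {
  m <- template_entry$partner_interface
  if (!length(m)) stop("partner interface is empty")
  ss <- strsplit(template_entry$partner$ss, "")[[1]][m]
  c(h = mean(ss == "H"), e = mean(ss == "E"), c = mean(ss == "C"))
}

#' Conservation of a residue site from a multiple sequence alignment
#'
#' Per-column conservation is `1 -` the Shannon entropy of the amino-acid
#' distribution (20-letter alphabet, gaps excluded) normalised by `log(20)`;
#' the site value is the mean over member columns. Without an MSA a neutral
#' 0.5 is returned.
#'
#' @param target_chain a [pb_chain()].
#' @param site a [residue_site()] on the target chain.
#' @param msa optional `Biostrings::AAStringSet` of aligned sequences (equal
#'   widths) containing the target sequence.
#' @return conservation in `[0, 1]`.
#' @export
conservation_score <- function(target_chain, site, msa = NULL) {
  if (is.null(msa)) return(0.5)
  widths <- Biostrings::width(msa)
  if (length(unique(widths)) != 1) stop("MSA sequences must have equal width")
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  degapped <- apply(mat, 1, function(r) paste(r[r != "-"], collapse = ""))
  trow <- match(target_chain$sequence, degapped)
  if (is.na(trow)) stop("MSA does not contain the target sequence")
  colmap <- which(mat[trow, ] != "-")  # target position -> alignment column
  cons <- vapply(site$members, function(p) {
    col <- mat[, colmap[p]]
    col <- col[col %in% AA1]
    if (!length(col)) return(0)
    f <- table(col) / length(col)
    1 - (-sum(f * log(f))) / log(20)
  }, numeric(1))
  mean(cons)
}

#' Secondary-structure probabilities for the target peptide
#'
#' Uses the supplied per-position 3-state prediction when given (averaged
#' over peptide positions), otherwise falls back to normalised Chou-Fasman
#' propensities of the peptide sequence.
#'
#' @param peptide_seq one-letter peptide sequence.
#' @param peptide_ss optional data frame with columns `pC`, `pH`, `pE`
#'   (PSIPRED ss2 layout, see [read_ss2()]).
#' @return numeric vector `(h, e, c)` summing to 1.
#' @export
peptide_ss_probs <- function(peptide_seq, peptide_ss = NULL) {
  if (!is.null(peptide_ss)) {
    v <- c(h = mean(peptide_ss$pH), e = mean(peptide_ss$pE), c = mean(peptide_ss$pC))
    return(v / sum(v))
  }
  letters1 <- strsplit(peptide_seq, "")[[1]]
  letters1 <- letters1[letters1 %in% rownames(CHOU_FASMAN)]
  if (!length(letters1)) return(c(h = 1, e = 1, c = 1) / 3)
  probs <- CHOU_FASMAN[letters1, , drop = FALSE]
  probs <- probs / rowSums(probs)
  v <- colMeans(probs)
  v <- v / sum(v)
  c(h = v[["H"]], e = v[["E"]], c = v[["C"]])
}

#' Compute the full feature vector for a candidate site
#'
#' @param target_chain the target [pb_chain()].
#' @param peptide_seq one-letter peptide sequence.
#' @param candidate a `pb_candidate` from [transfer_interface()] /
#'   [scan_library()].
#' @param template_entry the `pb_template` the candidate came from.
#' @param aux optional auxiliary inputs: `peptide_ss` (data frame from
#'   [read_ss2()]), `msa` (`AAStringSet`), `model_seq_identity` (scalar),
#'   `target_ss` (precomputed secondary-structure string), `target_sasa`
#'   (precomputed per-residue SASA vector).
#' @return named numeric feature vector (see [feature_names()]); when
#'   `aux$model_seq_identity` is supplied it is appended as
#'   `model_seq_identity`.
#' @export
compute_features <- function(target_chain, peptide_seq, candidate,
                             template_entry, aux = list()) {
  stopifnot(nzchar(peptide_seq))
  aln <- candidate$alignment
  tss <- aux$target_ss %||% assign_secondary_structure(target_chain)
  sasa <- aux$target_sasa
  if (is.null(sasa)) {
    str1 <- pb_structure("target", list(target_chain))
    sasa <- compute_sasa(str1)[[target_chain$chain_id]]
  }
  apos <- aln$mapping[, 1]
  pep_ss <- peptide_ss_probs(peptide_seq, aux$peptide_ss)
  surf_ss <- surface_ss_fractions(template_entry)
  pstats <- template_partner_stats(template_entry)

  fv <- c(
    target_peptide_len = nchar(peptide_seq),
    target_protein_len = target_chain$length,
    template_chain_len = template_entry$receptor_length,
    aligned_segment_len = nrow(aln$mapping),
    aligned_interface_count = candidate$aligned_interface_count,
    tm_target = aln$tm_target,
    tm_template = aln$tm_template,
    rmsd = aln$rmsd,
    contact_order = contact_order(target_chain, apos),
    longest_aligned_helix = longest_aligned_helix(tss, apos),
    pep_comp_dist = composition_distance(peptide_seq, template_entry$partner$sequence),
    prot_comp_dist = composition_distance(target_chain$sequence,
                                          template_entry$receptor$sequence),
    target_pep_ss_h = pep_ss[["h"]],
    target_pep_ss_e = pep_ss[["e"]],
    target_pep_ss_c = pep_ss[["c"]],
    template_surface_ss_h = surf_ss[["h"]],
    template_surface_ss_e = surf_ss[["e"]],
    template_surface_ss_c = surf_ss[["c"]],
    rel_exposure = relative_exposure(target_chain, candidate$site, sasa),
    conservation = conservation_score(target_chain, candidate$site, aux$msa),
    mean_seq_dist = pstats[["mean_seq_dist"]],
    median_seq_dist = pstats[["median_seq_dist"]],
    summed_segment_lengths = pstats[["summed_segment_lengths"]]
  )
  if (!is.null(aux$model_seq_identity))
    fv <- c(fv, model_seq_identity = aux$model_seq_identity)
  fv
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 3-state secondary-structure prediction (PSIPRED ss2 layout)
#'
#' Expects whitespace-separated columns: position, residue, state, and the
#' three state probabilities pC, pH, pE. Comment/header lines starting with
#' `#` are skipped.
#'
#' @param path path to the ss2 file.
#' @return data frame with columns `pos`, `res`, `state`, `pC`, `pH`, `pE`.
#' @export
read_ss2 <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("ss2 file must have 6 columns: pos res state pC pH pE")
  names(tab)[1:6] <- c("pos", "res", "state", "pC", "pH", "pE")
  tab[, 1:6]
}

#' Read a multiple sequence alignment in FASTA format
#' @param path path to an aligned FASTA file.
#' @return a `Biostrings::AAStringSet`.
#' @export
read_msa <- function(path) Biostrings::readAAStringSet(path)
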
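#' Build one interaction template entry from a chain pair
#'
#' An entry records one chain pair in contact: the receptor-role chain
#' (sequence, C-alpha trace, secondary structure), the partner chain, both
#' interface residue sets at the heavy-atom contact cutoff, and, for each
#' receptor interface residue, the residue types of the partner residues it
#' contacts (used for the amino-acid preference profile).
#'
#' @param structure a [pb_structure()].
#' @param receptor_id,partner_id chain identifiers.
#' @param contact_cutoff heavy-atom contact cutoff in Angstrom.
#' @param min_receptor_len minimum receptor chain length.
#' @return a template entry (list of class `pb_template`), or `NULL` when the
#'   receptor is too short or the chains do not touch.
#' @export
template_entry_from_pair <- function(structure, receptor_id, partner_id,
                                     contact_cutoff = 6.0,
                                     min_receptor_len = 25L) {
  rec <- get_chain(structure, receptor_id)
  par <- get_chain(structure, partner_id)
  if (rec$length < min_receptor_len) return(NULL)
  pairs <- .contact_pairs_cpp(as.matrix(rec$atoms[, c("x", "y", "z")]),
                              as.integer(rec$atoms$pos),
                              as.matrix(par$atoms[, c("x", "y", "z")]),
                              as.integer(par$atoms$pos), contact_cutoff)
  if (!nrow(pairs)) return(NULL)
  rec_iface <- sort(unique(pairs[, 1]))
  par_iface <- sort(unique(pairs[, 2]))
  par_letters <- strsplit(par$sequence, "")[[1]]
  contacts <- lapply(rec_iface, function(p)
    paste(par_letters[sort(unique(pairs[pairs[, 1] == p, 2]))], collapse = ""))
  names(contacts) <- as.character(rec_iface)
  base::structure(list(
    source_id = paste(structure$id, receptor_id, partner_id, sep = "_"),
    receptor = list(sequence = rec$sequence, ca = rec$ca,
                    ss = assign_secondary_structure(rec)),
    partner = list(sequence = par$sequence, ca = par$ca,
                   ss = assign_secondary_structure(par)),
    receptor_interface = rec_iface,
    partner_interface = par_iface,
    partner_contacts = contacts,
    receptor_length = rec$length,
    partner_length = par$length), class = "pb_template")
}

#' @noRd
new_template_library <- function(entries, meta = list()) {
  ids <- vapply(entries, function(e) e$source_id, character(1))
  if (anyDuplicated(ids)) stop("template source ids must be unique")
  structure(list(entries = entries,
                 meta = utils::modifyList(list(format_version = 1L,
                                               contact_cutoff = 6.0,
                                               min_receptor_len = 25L), meta)),
            class = "pb_library")
}

#' @export
print.pb_library <- function(x, ...) {
  cat(sprintf("<pb_library> %d template entries (cutoff %.1f A, min receptor %d)\n",
              length(x$entries), x$meta$contact_cutoff, x$meta$min_receptor_len))
  invisible(x)
}

#' Build an interaction template library from a directory of PDB files
#'
#' Every ordered pair of distinct chains in heavy-atom contact contributes an
#' entry with the first chain in the receptor role, provided the receptor has
#' at least `min_receptor_len` residues; a single contacting pair can thus
#' yield up to two entries. Files with more than `max_chains_per_file` chains
#' (e.g. full capsids) are skipped; unreadable files are logged and skipped.
#'
#' @param pdb_dir directory containing `.pdb`/`.ent` files.
#' @param contact_cutoff heavy-atom contact cutoff in Angstrom.
#' @param min_receptor_len minimum receptor chain length.
#' @param max_chains_per_file skip files with more chains than this.
#' @return a template library (class `pb_library`).
#' @export
build_library <- function(pdb_dir, contact_cutoff = 6.0, min_receptor_len = 25L,
                          max_chains_per_file = 30L) {
  files <- sort(list.files(pdb_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no PDB files found in '%s'", pdb_dir))
  entries <- list()
  for (f in files) {
    s <- tryCatch(read_pdb(f), error = function(e) {
      message(sprintf("skipping '%s': %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(s)) next
    if (length(s$chains) > max_chains_per_file) {
      message(sprintf("skipping '%s': %d chains exceeds limit %d",
                      f, length(s$chains), max_chains_per_file))
      next
    }
    ids <- names(s$chains)
    for (a in ids) for (b in ids) {
      if (a == b) next
      e <- template_entry_from_pair(s, a, b, contact_cutoff, min_receptor_len)
      if (!is.null(e)) entries[[length(entries) + 1]] <- e
    }
  }
  if (!length(entries)) warning("no template entries survived the filters")
  new_template_library(entries,
                       meta = list(contact_cutoff = contact_cutoff,
                                   min_receptor_len = as.integer(min_receptor_len),
                                   max_chains_per_file = as.integer(max_chains_per_file),
                                   source = normalizePath(pdb_dir)))
}

#' Split a library into peptide-binding and non-peptide-binding parts
#'
#' An entry is peptide-binding iff its partner chain is 5-25 residues long
#' (both bounds inclusive), the length range of molecular recognition
#' features.
#'
#' @param library a `pb_library`.
#' @return list with `peptide` and `non_peptide` libraries partitioning the
#'   input.
#' @export
split_library <- function(library) {
  if (!length(library$entries)) stop("cannot split an empty library")
  is_pep <- vapply(library$entries,
                   function(e) e$partner_length >= 5 && e$partner_length <= 25,
                   logical(1))
  list(peptide = new_template_library(library$entries[is_pep], library$meta),
       non_peptide = new_template_library(library$entries[!is_pep], library$meta))
}

#' Remove templates homologous to a target sequence
#'
#' Uses `blastp` when available on the PATH (entries whose receptor matches
#' the target with E-value below `e_threshold` are dropped); otherwise falls
#' back, with a warning, to a global-alignment identity filter (entries with
#' at least 30% sequence identity to the target removed).
#'
#' @param library a `pb_library`.
#' @param target_sequence one-letter target sequence.
#' @param e_threshold BLAST E-value threshold.
#' @return the filtered `pb_library`.
#' @export
exclude_homologs <- function(library, target_sequence, e_threshold = 0.001) {
  stopifnot(nzchar(target_sequence))
  if (!length(library$entries)) return(library)
  seqs <- vapply(library$entries, function(e) e$receptor$sequence, character(1))
  if (nzchar(Sys.which("blastp"))) {
    drop <- blast_hits(target_sequence, seqs, e_threshold)
  } else {
    warning("blastp not found on PATH; falling back to identity-based filter")
    drop <- vapply(seqs, function(s)
      sequence_identity(target_sequence, s) >= 0.30, logical(1))
  }
  new_template_library(library$entries[!drop], library$meta)
}

#' @noRd
blast_hits <- function(query, subjects, e_threshold) {
  qf <- tempfile(fileext = ".fasta"); sf <- tempfile(fileext = ".fasta")
  of <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qf, sf, of)))
  writeLines(c(">query", query), qf)
  writeLines(as.vector(rbind(sprintf(">s%d", seq_along(subjects)), subjects)), sf)
  system2("blastp", c("-query", qf, "-subject", sf,
                      "-outfmt", shQuote("6 sseqid evalue"),
                      "-evalue", format(e_threshold, scientific = TRUE),
                      "-out", of), stdout = FALSE, stderr = FALSE)
  drop <- logical(length(subjects))
  if (file.exists(of) && file.size(of) > 0) {
    hits <- utils::read.table(of, sep = "\t", stringsAsFactors = FALSE)
    idx <- as.integer(sub("^s", "", hits[[1]]))[hits[[2]] < e_threshold]
    drop[unique(idx)] <- TRUE
  }
  drop
}

#' Global-alignment sequence identity (matches over alignment length)
#' @noRd
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5,
                                       type = "global")
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Serialize a template library to a versioned JSON file
#'
#' Plain-text format: a manifest (`meta`) plus one record per entry holding
#' sequences, C-alpha coordinates, secondary structure and interface lists.
#' [read_library()] reproduces the library exactly.
#'
#' @param library a `pb_library`.
#' @param path output path (conventionally `.ipl.json`).
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  ser <- list(meta = library$meta,
              entries = lapply(library$entries, function(e) {
                e$receptor$ca <- as.vector(t(e$receptor$ca))
                e$partner$ca <- as.vector(t(e$partner$ca))
                unclass(e)
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a template library written by [write_library()]
#' @param path path to the JSON library file.
#' @return a `pb_library`.
#' @export
read_library <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  entries <- lapply(ser$entries, function(e) {
    e$receptor$ca <- matrix(unlist(e$receptor$ca), ncol = 3, byrow = TRUE)
    e$partner$ca <- matrix(unlist(e$partner$ca), ncol = 3, byrow = TRUE)
    e$receptor_interface <- as.integer(unlist(e$receptor_interface))
    e$partner_interface <- as.integer(unlist(e$partner_interface))
    e$partner_contacts <- lapply(e$partner_contacts, as.character)
    e$receptor_length <- as.integer(e$receptor_length)
    e$partner_length <- as.integer(e$partner_length)
    class(e) <- "pb_template"
    e
  })
  new_template_library(entries, ser$meta)
}
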
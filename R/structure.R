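#' Protein structure containers
#'
#' `pepbind` represents a structure as a plain list of chains; each chain
#' stores its one-letter sequence, per-residue C-alpha coordinates and a flat
#' table of heavy atoms. Residue positions are 1-based indices into the
#' chain's residue list (insertion codes and author numbering are preserved
#' only inside the atom table; all internal bookkeeping is positional).
#'
#' @param id structure identifier.
#' @param chains named list of chain objects (names are chain ids).
#' @param method experimental method, one of `"XRAY"`, `"NMR"`, `"OTHER"`,
#'   `"UNKNOWN"`.
#' @param resolution resolution in Angstrom, or `NA`.
#' @param model_number model retained (relevant for multi-model NMR entries).
#' @return an object of class `pb_structure`.
#' @export
pb_structure <- function(id, chains, method = "UNKNOWN", resolution = NA_real_,
                         model_number = 1L) {
  stopifnot(is.list(chains), length(chains) >= 1)
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("chain identifiers must be unique")
  names(chains) <- ids
  structure(list(id = id, chains = chains,
                 method = match.arg(method, c("XRAY", "NMR", "OTHER", "UNKNOWN")),
                 resolution = resolution, model_number = as.integer(model_number)),
            class = "pb_structure")
}

#' Construct a chain
#'
#' @param chain_id single-character chain identifier.
#' @param resnames character vector of 3-letter residue names.
#' @param ca numeric matrix (n x 3) of C-alpha coordinates; rows may be `NA`
#'   for residues without a C-alpha atom.
#' @param atoms data frame with columns `pos` (1-based residue position),
#'   `atom` (atom name), `element`, `x`, `y`, `z`. Heavy atoms only.
#' @return an object of class `pb_chain`.
#' @export
pb_chain <- function(chain_id, resnames, ca, atoms) {
  n <- length(resnames)
  stopifnot(nrow(ca) == n, ncol(ca) == 3,
            all(c("pos", "atom", "element", "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  structure(list(chain_id = chain_id,
                 resnames = resnames,
                 sequence = paste(aa_three_to_one(resnames), collapse = ""),
                 ca = unname(as.matrix(ca)),
                 atoms = atoms,
                 length = n),
            class = "pb_chain")
}

#' @export
print.pb_structure <- function(x, ...) {
  cat(sprintf("<pb_structure> %s: %d chain(s), method %s, resolution %s\n",
              x$id, length(x$chains), x$method,
              ifelse(is.na(x$resolution), "NA", sprintf("%.2f A", x$resolution))))
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues\n", ch$chain_id, ch$length))
  invisible(x)
}

#' @export
print.pb_chain <- function(x, ...) {
  cat(sprintf("<pb_chain> %s: %d residues\n%s\n", x$chain_id, x$length, x$sequence))
  invisible(x)
}

#' Look up a chain by identifier
#' @param structure a `pb_structure`.
#' @param chain_id chain identifier.
#' @return the `pb_chain`.
#' @export
get_chain <- function(structure, chain_id) {
  ch <- structure$chains[[chain_id]]
  if (is.null(ch))
    stop(sprintf("chain '%s' not found in structure '%s'", chain_id, structure$id))
  ch
}

#' Construct a residue site
#'
#' A residue site is a set of residue positions on one chain plus their
#' C-alpha coordinates; it is the unit in which interface surfaces are
#' stored, transferred and clustered.
#'
#' @param chain a `pb_chain`.
#' @param members integer vector of 1-based residue positions on `chain`.
#' @return an object of class `pb_site` with sorted `members` and a parallel
#'   coordinate matrix `coords`.
#' @export
residue_site <- function(chain, members) {
  members <- sort(unique(as.integer(members)))
  if (length(members) && (min(members) < 1 || max(members) > chain$length))
    stop("site members outside chain positions")
  structure(list(chain_id = chain$chain_id, members = members,
                 coords = chain$ca[members, , drop = FALSE]),
            class = "pb_site")
}

#' @export
print.pb_site <- function(x, ...) {
  cat(sprintf("<pb_site> chain %s: %d residue(s): %s\n", x$chain_id,
              length(x$members), paste(x$members, collapse = ",")))
  invisible(x)
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (waters, ligands and hydrogens are dropped), keeping
#' only the first MODEL of multi-model (NMR) entries. Alternate locations are
#' resolved by keeping the highest-occupancy conformer (first on ties).
#' Experimental method is taken from EXPDTA and resolution from REMARK 2 when
#' present.
#'
#' @param path path to a PDB file.
#' @return a [pb_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read PDB file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("empty PDB file '%s'", path))

  method <- "UNKNOWN"
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta)) {
    txt <- toupper(expdta[1])
    method <- if (grepl("X-RAY", txt)) "XRAY" else if (grepl("NMR", txt)) "NMR" else "OTHER"
  }
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) resolution <- as.numeric(m)
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("failed to parse PDB file '%s': %s",
                                     path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% WATER_RESNAMES), , drop = FALSE]
  if (!nrow(at)) stop(sprintf("no protein chains in '%s'", path))

  # element: use column when present, else first letter of the atom name
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1, 1)
  at$element <- toupper(trimws(elem))
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop(sprintf("no heavy atoms in '%s'", path))

  # altloc policy: per (chain, residue, atom name) keep highest occupancy,
  # first record on ties
  at$.row <- seq_len(nrow(at))
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -occ, at$.row)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$.row), , drop = FALSE]  # restore file order

  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert, sep = "|")
    upos <- unique(rkey)
    pos <- match(rkey, upos)
    resnames <- ca$resid[!duplicated(rkey)]
    n <- length(upos)
    camat <- matrix(NA_real_, n, 3)
    is_ca <- ca$elety == "CA"
    if (any(is_ca)) {
      first_ca <- !duplicated(pos[is_ca])
      camat[pos[is_ca][first_ca], ] <- as.matrix(
        ca[is_ca, c("x", "y", "z")][first_ca, , drop = FALSE])
    }
    atoms <- data.frame(pos = pos, atom = ca$elety, element = ca$element,
                        x = ca$x, y = ca$y, z = ca$z,
                        stringsAsFactors = FALSE)
    chains[[cid]] <- pb_chain(ifelse(is.na(cid) | cid == "", "A", cid),
                              resnames, camat, atoms)
  }
  pb_structure(id = sub("\\.(pdb|ent)$", "", basename(path)), chains = chains,
               method = method, resolution = resolution, model_number = 1L)
}

#' Write a structure to a PDB file, optionally with per-residue scores
#'
#' Scores (e.g. local binding-site scores) are written to the B-factor column
#' so predictions can be coloured in any molecular viewer.
#'
#' @param structure a `pb_structure`.
#' @param path output file path.
#' @param scores optional named list, `chain_id -> numeric vector` (one value
#'   per residue) written as B-factors; residues without a score get 0.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, scores = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (structure$method != "UNKNOWN") {
    label <- c(XRAY = "X-RAY DIFFRACTION", NMR = "SOLUTION NMR", OTHER = "OTHER")
    writeLines(sprintf("EXPDTA    %s", label[[structure$method]]), con)
  }
  if (!is.na(structure$resolution))
    writeLines(sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.",
                       structure$resolution), con)
  serial <- 0L
  for (ch in structure$chains) {
    b <- rep(0, ch$length)
    if (!is.null(scores) && !is.null(scores[[ch$chain_id]])) {
      s <- scores[[ch$chain_id]]
      b[seq_along(s)] <- s
    }
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, ch$resnames[a$pos[i]], ch$chain_id, a$pos[i],
        a$x[i], a$y[i], a$z[i], 1.00, b[a$pos[i]], a$element[i]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
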
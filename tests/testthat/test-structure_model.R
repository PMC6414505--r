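test_that("read_pdb round-trips structures written by write_pdb", {
  ch <- make_chain("HELIX", 12, seed = 1)
  s <- pb_structure("fix1", list(ch), method = "XRAY", resolution = 1.8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  r <- read_pdb(f)
  expect_length(r$chains, 1)
  expect_equal(r$chains[["A"]]$length, 12)
  expect_equal(r$chains[["A"]]$sequence, ch$sequence)
  expect_equal(r$method, "XRAY")
  expect_equal(r$resolution, 1.8)
  expect_equal(r$chains[["A"]]$ca, ch$ca, tolerance = 1e-3)
})

test_that("read_pdb keeps only the first MODEL of multi-model files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  mk_atom <- function(serial, res, x) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    serial, res, x, 0, 0)
  lines <- c("EXPDTA    SOLUTION NMR", "MODEL        1",
             vapply(1:5, function(i) mk_atom(i, i, i * 3.8), character(1)),
             "ENDMDL", "MODEL        2",
             vapply(1:5, function(i) mk_atom(i + 5, i, i * 3.8 + 100), character(1)),
             "ENDMDL", "END")
  writeLines(lines, f)
  r <- read_pdb(f)
  expect_equal(r$method, "NMR")
  expect_equal(r$model_number, 1L)
  expect_equal(r$chains[["A"]]$length, 5)
  # model-1 coordinates, not model-2
  expect_equal(r$chains[["A"]]$ca[1, 1], 3.8, tolerance = 1e-6)
})

test_that("read_pdb drops water chains and hydrogens", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:4, 1:4, (1:4) * 3.8, rep(0, 4), rep(0, 4)),
    "ATOM      5  H   GLY A   1       0.000   1.000   0.000  1.00  0.00           H",
    "HETATM    6  O   HOH W   1      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  writeLines(lines, f)
  r <- read_pdb(f)
  expect_length(r$chains, 1)
  expect_false(any(r$chains[["A"]]$atoms$element == "H"))
})

test_that("read_pdb rejects unreadable or empty input", {
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "empty|parse")
})

test_that("single-sphere SASA matches the closed form", {
  s <- atoms_structure(c(0, 0, 0))
  expect_equal(sum(unlist(compute_sasa(s))), 4 * pi * (1.87 + 1.4)^2,
               tolerance = 1e-6)
})

test_that("two coincident atoms expose the surface of one", {
  s <- atoms_structure(rbind(c(0, 0, 0), c(0, 0, 0)), pos = c(1L, 2L),
                       resnames = c("ALA", "ALA"))
  expect_equal(sum(unlist(compute_sasa(s))), 4 * pi * (1.87 + 1.4)^2,
               tolerance = 1e-6)
})

test_that("SASA agrees with an independent Monte-Carlo estimator within 2%", {
  ch <- make_chain("HELIX", 15, seed = 4)  # 45 atoms
  s <- pb_structure("mc", list(ch))
  pkg <- sum(unlist(compute_sasa(s)))
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
  ref <- mc_sasa(xyz, rep(1.87, nrow(xyz)))
  expect_lt(abs(pkg - ref) / ref, 0.02)
})

test_that("SASA is invariant under rigid-body motion up to lattice resolution", {
  ch <- make_chain("HAIRPIN", 14, seed = 5)
  s <- pb_structure("rot", list(ch))
  base <- sum(unlist(compute_sasa(s)))
  set.seed(11)
  for (k in 1:3) {
    R <- random_rotation()
    a <- ch$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, c(5, -3, 2), "+")
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    rot <- pb_structure("rot2", list(pb_chain("A", ch$resnames,
      { ca <- ch$ca %*% t(R); sweep(ca, 2, c(5, -3, 2), "+") }, a)))
    expect_equal(sum(unlist(compute_sasa(rot))), base, tolerance = 1e-9)
  }
})

test_that("buried surface is symmetric, near zero for distant chains", {
  rec <- make_chain("HELIX_BUNDLE", 45, seed = 2)
  pep <- make_chain("HELIX", 8, seed = 3)
  far <- make_complex(rec, pep, contact_offset = 25)
  expect_lt(abs(buried_surface(far$structure, "A", "B")), 1e-6)
  near <- make_complex(rec, pep)
  ab <- buried_surface(near$structure, "A", "B")
  ba <- buried_surface(near$structure, "B", "A")
  expect_gt(ab, 0)
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("peptide burial fraction spans its limits", {
  rec <- make_chain("HELIX_BUNDLE", 45, seed = 2)
  pep <- make_chain("HELIX", 8, seed = 3)
  far <- make_complex(rec, pep, contact_offset = 25)
  expect_lt(peptide_burial_fraction(far$structure, "B"), 0.01)
  # fully enclosed: peptide single atom inside a dense cage of atoms
  cage <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3), z = c(-3, 0, 3)))
  cage <- cage[rowSums(abs(cage)) > 0, ]
  n <- nrow(cage)
  rec_ch <- pb_chain("A", rep("ALA", n), cage,
    data.frame(pos = seq_len(n), atom = "CA", element = "C",
               x = cage[, 1], y = cage[, 2], z = cage[, 3]))
  pep_ch <- pb_chain("B", "GLY", matrix(0, 1, 3),
    data.frame(pos = 1L, atom = "CA", element = "C", x = 0, y = 0, z = 0))
  s <- pb_structure("cage", list(rec_ch, pep_ch))
  expect_gt(peptide_burial_fraction(s, "B"), 0.95)
})

test_that("interface residues follow the 6 A heavy-atom definition", {
  two_res <- function(d) {
    a <- pb_chain("A", "ALA", matrix(c(0, 0, 0), 1, 3),
      data.frame(pos = 1L, atom = "CB", element = "C", x = 0, y = 0, z = 0))
    b <- pb_chain("B", "ALA", matrix(c(d, 0, 0), 1, 3),
      data.frame(pos = 1L, atom = "CB", element = "C", x = d, y = 0, z = 0))
    pb_structure("pair", list(a, b))
  }
  close_ <- interface_residues(two_res(5.9), "A", "B")
  expect_equal(close_$a$members, 1L)
  expect_equal(close_$b$members, 1L)
  apart <- interface_residues(two_res(6.01), "A", "B")
  expect_length(apart$a$members, 0)
  expect_length(apart$b$members, 0)
})

test_that("interface detection is symmetric and monotone in cutoff", {
  rec <- make_chain("HELIX_BUNDLE", 45, seed = 6)
  pep <- make_chain("HELIX", 9, seed = 7)
  cx <- make_complex(rec, pep)
  i6 <- interface_residues(cx$structure, "A", "B", cutoff = 6)
  i6r <- interface_residues(cx$structure, "B", "A", cutoff = 6)
  expect_equal(i6$a$members, i6r$b$members)
  i8 <- interface_residues(cx$structure, "A", "B", cutoff = 8)
  expect_true(all(i6$a$members %in% i8$a$members))
  expect_true(all(i6$b$members %in% i8$b$members))
})

test_that("secondary structure: ideal helix interior is H, extended chain has no H", {
  helix <- make_chain("HELIX", 12, seed = 1)
  ss <- assign_secondary_structure(helix)
  expect_equal(nchar(ss), 12)
  expect_true(all(strsplit(substr(ss, 3, 10), "")[[1]] == "H"))
  ext <- atoms_structure(cbind((0:9) * 3.8, 0, 0))$chains[["A"]]
  expect_false(grepl("H", assign_secondary_structure(ext)))
  tri <- make_chain("HELIX", 3, seed = 1)
  expect_equal(assign_secondary_structure(tri), "CCC")
})

test_that("relative exposure averages clamped per-residue fractions", {
  ch <- make_chain("HELIX", 10, seed = 2)
  site <- residue_site(ch, c(2, 5))
  sasa <- numeric(10)
  ref <- pepbind:::MAX_SASA[pepbind:::aa_three_to_one(ch$resnames[c(2, 5)])]
  sasa[2] <- 0.2 * ref[1]
  sasa[5] <- 0.6 * ref[2]
  expect_equal(relative_exposure(ch, site, sasa), 0.4, tolerance = 1e-12)
  sasa[2] <- 0; sasa[5] <- 0
  expect_equal(relative_exposure(ch, site, sasa), 0)
  sasa[2] <- 2 * ref[1]; sasa[5] <- 2 * ref[2]  # clamped at 1
  expect_equal(relative_exposure(ch, site, sasa), 1)
  expect_error(relative_exposure(ch, residue_site(ch, integer(0)), sasa),
               "empty")
})
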
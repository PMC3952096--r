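test_that("a minimal PDB parses into atoms grouped by residue", {
  pdb <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.420   0.000  1.00  0.00           C",
    sep = "\n")
  s <- read_structure(pdb)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(nrow(residue_table(s)), 1)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_false(any(s$atoms$is_sidechain))
})

test_that("toy structures parse with the requested residue count", {
  for (n in c(3, 6)) {
    s <- read_structure(make_toy_structure(n, "extended"))
    expect_equal(nrow(residue_table(s)), n)
  }
})

test_that("multi-model files read only the selected model", {
  one <- make_toy_structure(3, "extended")
  lines <- strsplit(one, "\n")[[1]]
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  two_model <- c("MODEL        1", atom_lines, "ENDMDL",
                 "MODEL        2", atom_lines[1:5], "ENDMDL", "END")
  s <- read_structure(paste(two_model, collapse = "\n"), model_index = 0)
  expect_equal(nrow(s$atoms), length(atom_lines))
  s2 <- read_structure(paste(two_model, collapse = "\n"), model_index = 1)
  expect_equal(nrow(s2$atoms), 5)
  expect_error(read_structure(paste(two_model, collapse = "\n"),
                              model_index = 5), "model")
})

test_that("no ATOM records is a parse error", {
  expect_error(read_structure("HEADER    NOTHING\nEND"), "ATOM")
})

test_that("altloc resolution keeps the highest-occupancy copy, ties to A", {
  pdb <- paste(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA BALA A   1       6.500   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA AALA A   1       1.460   0.000   0.000  0.50  0.00           C",
    sep = "\n")
  s <- read_structure(pdb)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 5.0)   # occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1.46) # tie -> altloc A
})

test_that("unknown residue names warn but atoms are kept", {
  pdb <- paste(
    "ATOM      1  N   XXX A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  XXX A   1       1.460   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  expect_warning(s <- read_structure(pdb), "XXX")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(residue_table(s)$hydrophobicity, "none")
})

test_that("writing and re-parsing a structure round-trips", {
  s <- read_structure(make_toy_structure(5, "helix_like"))
  txt <- write_structure(s)
  s2 <- read_structure(paste(txt, collapse = "\n"))
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
})

test_that("covalent detection follows the radius-sum rule", {
  mk <- function(d) {
    paste(sprintf(
      "ATOM  %5d  C%d  UNK A   1    %8.3f   0.000   0.000  1.00  0.00           C",
      1:2, 1:2, c(0, d)), collapse = "\n")
  }
  expect_warning(
    cov <- detect_covalent_bonds(read_structure(mk(1.50))), "UNK")
  expect_equal(nrow(cov), 1)  # cutoff 0.77 + 0.77 + 0.4 = 1.94
  suppressWarnings(
    cov2 <- detect_covalent_bonds(read_structure(mk(5.0))))
  expect_equal(nrow(cov2), 0)
})

test_that("peptide bonds are locked with 6 bars", {
  s <- read_structure(make_toy_structure(3, "extended"))
  cov <- detect_covalent_bonds(s)
  a <- s$atoms
  peptide <- cov$provenance == "peptide_bond"
  expect_equal(sum(peptide), 2)
  expect_true(all(cov$bars[peptide] == 6L))
  expect_true(all(cov$kind[peptide] == "covalent_locked"))
  ## carbonyl C=O locked via the template rule
  carbonyl <- cov$provenance == "template_locked"
  expect_true(all(cov$bars[carbonyl] == 6L))
})

test_that("atoms with unknown elements give a named error", {
  pdb <- "ATOM      1 ZN    ZN A   1       0.000   0.000   0.000  1.00  0.00          ZN"
  suppressWarnings(s <- read_structure(pdb, keep_hetatm = TRUE))
  expect_error(detect_covalent_bonds(s), "ZN")
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  mk <- function(extra) {
    paste(c(
      "ATOM      1  O   ALA A   1       0.000   0.000   0.000  1.00  0.00           O",
      extra), collapse = "\n")
  }
  n_at <- function(d) sprintf(
    "ATOM      2  N   ALA A   5    %8.3f   0.000   0.000  1.00  0.00           N", d)
  hb <- detect_hydrogen_bonds(read_structure(mk(n_at(2.9))))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$bars, 5L)
  hb2 <- detect_hydrogen_bonds(read_structure(mk(n_at(4.2))))
  expect_equal(nrow(hb2), 0)
  ## explicit hydrogen at a 90 degree D-H...A angle rejects the bond
  prot <- paste(c(
    "ATOM      1  O   ALA A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  N   ALA A   5       2.900   0.000   0.000  1.00  0.00           N",
    "ATOM      3  H   ALA A   5       2.900   1.000   0.000  1.00  0.00           H"),
    collapse = "\n")
  expect_equal(nrow(detect_hydrogen_bonds(read_structure(prot))), 0)
})

test_that("hydrophobic tethers require side-chain C/S pairs >= 2 apart", {
  mk <- function(d, name_a = "CB", name_b = "CB", res_b = 5) {
    paste(sprintf(
      "ATOM  %5d  %-3s ALA A%4d    %8.3f   0.000   0.000  1.00  0.00           C",
      1:2, c(name_a, name_b), c(1, res_b), c(0, d)), collapse = "\n")
  }
  expect_equal(nrow(detect_hydrophobic_tethers(read_structure(mk(3.5)))), 1)
  expect_equal(nrow(detect_hydrophobic_tethers(read_structure(mk(4.0)))), 0)
  ## backbone CA pairs never tether
  expect_equal(nrow(detect_hydrophobic_tethers(
    read_structure(mk(3.5, "CA", "CA")))), 0)
  ## adjacent residues never tether
  expect_equal(nrow(detect_hydrophobic_tethers(
    read_structure(mk(3.5, res_b = 2)))), 0)
})

test_that("interaction detection is symmetric under atom reordering", {
  txt <- make_toy_structure(8, "two_domain_hinge", n_tethers = 2)
  s <- read_structure(txt)
  s_rev <- s
  s_rev$atoms <- s_rev$atoms[rev(seq_len(nrow(s_rev$atoms))), ]
  key <- function(x) {
    paste(pmin(x$serial_a, x$serial_b), pmax(x$serial_a, x$serial_b), x$kind)
  }
  for (f in list(detect_covalent_bonds, detect_hydrogen_bonds,
                 detect_hydrophobic_tethers)) {
    expect_setequal(key(f(s)), key(f(s_rev)))
  }
  ## no interaction duplicates a covalent bond
  cov <- detect_covalent_bonds(s)
  other <- dplyr::bind_rows(detect_hydrogen_bonds(s),
                            detect_hydrophobic_tethers(s))
  expect_length(intersect(key(cov), key(other)), 0)
})

test_that("parsed coordinates agree with an independent PDB reader", {
  txt <- make_toy_structure(8, "two_domain_hinge", n_tethers = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, path)
  ours <- read_structure(txt)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-3)
  expect_equal(ours$atoms$name, ref$atom$elety)
  expect_equal(ours$atoms$resno, ref$atom$resno)
})
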
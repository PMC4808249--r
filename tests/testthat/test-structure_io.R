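test_that("read_pdb captures SEQRES, observed residues and het inventory", {
  path <- simple_chain_fixture(observed = 1:25,
                               extra_lines = gnp_het_lines(n_atoms = 32))
  sf <- read_pdb(path)

  ps <- sf$protein_chains[["A"]]
  expect_equal(nchar(ps$seqres), 30)
  expect_length(ps$observed_idx, 25)
  expect_equal(disordered_indices(ps), 26:30)

  expect_equal(nrow(sf$het_groups), 1)
  expect_equal(sf$het_groups$comp_id, "GNP")
  expect_equal(sf$het_groups$n_atoms, 32L)
})

test_that("MSE in SEQRES maps to M; waters counted not inventoried", {
  s3 <- c(rep("ALA", 4), "MSE", rep("GLY", 5))
  lines <- c(pdb_seqres_lines("A", s3))
  serial <- 1
  for (i in 1:10) {
    resn <- s3[i]
    rec <- if (resn == "MSE") "HETATM" else "ATOM"
    lines <- c(lines, pdb_atom_line(rec, serial, "CA", resn, "A", i,
                                    i * 3.8, 0, 0))
    serial <- serial + 1
  }
  lines <- c(lines,
             pdb_atom_line("HETATM", 90, "O", "HOH", "W", 1, 9, 9, 9,
                           element = "O"),
             pdb_atom_line("HETATM", 91, "O", "HOH", "W", 2, 8, 8, 8,
                           element = "O"))
  sf <- read_pdb(write_pdb_text(lines))

  ps <- sf$protein_chains[["A"]]
  expect_equal(substr(ps$seqres, 5, 5), "M")
  expect_equal(ps$observed[[5]]$name3, "MSE")
  expect_length(ps$observed_idx, 10)
  expect_equal(sf$waters, 2L)
  expect_equal(nrow(sf$het_groups), 0)
})

test_that("altlocs resolve to highest occupancy, ties to first", {
  lines <- c(
    pdb_seqres_lines("A", rep("ALA", 3)),
    pdb_atom_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
                  altloc = "A"),
    pdb_atom_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6,
                  altloc = "B"),
    pdb_atom_line("ATOM", 3, "CA", "ALA", "A", 2, 3.8, 0, 0, occ = 0.5,
                  altloc = "A"),
    pdb_atom_line("ATOM", 4, "CA", "ALA", "A", 2, 7, 7, 7, occ = 0.5,
                  altloc = "B"),
    pdb_atom_line("ATOM", 5, "CA", "ALA", "A", 3, 7.6, 0, 0)
  )
  sf <- read_pdb(write_pdb_text(lines))
  ps <- sf$protein_chains[["A"]]
  expect_equal(ps$observed[[1]]$atoms[[1]]$coords, c(9, 9, 9))       # occ 0.6
  expect_equal(ps$observed[[2]]$atoms[[1]]$coords, c(3.8, 0, 0))     # tie: first
})

test_that("metadata (resolution, pH, temperature) is parsed", {
  lines <- c(
    "REMARK   2 RESOLUTION.    1.85 ANGSTROMS.",
    "REMARK 200  PH                             : 6.50",
    "REMARK 200  TEMPERATURE           (KELVIN) : 100",
    pdb_seqres_lines("A", rep("GLY", 4)),
    vapply(1:4, function(i)
      pdb_atom_line("ATOM", i, "CA", "GLY", "A", i, i * 3.8, 0, 0),
      character(1))
  )
  sf <- read_pdb(write_pdb_text(lines))
  expect_equal(sf$metadata$resolution, 1.85)
  expect_equal(sf$metadata$ph, 6.5)
  expect_equal(sf$metadata$temperature, 100)
})

test_that("only MODEL 1 of a multi-model file is read", {
  lines <- c(
    pdb_seqres_lines("A", rep("GLY", 4)),
    "MODEL        1",
    vapply(1:4, function(i)
      pdb_atom_line("ATOM", i, "CA", "GLY", "A", i, i * 3.8, 0, 0),
      character(1)),
    "ENDMDL",
    "MODEL        2",
    vapply(1:4, function(i)
      pdb_atom_line("ATOM", i + 10, "CA", "GLY", "A", i, 99, 99, 99),
      character(1)),
    "ENDMDL"
  )
  sf <- read_pdb(write_pdb_text(lines))
  ps <- sf$protein_chains[["A"]]
  expect_equal(ps$observed[[1]]$atoms[[1]]$coords[1], 3.8)
})

test_that("observed-to-SEQRES mapping: identity, deletions, offset fallback", {
  # identity
  sf <- read_pdb(simple_chain_fixture(observed = 1:30))
  expect_equal(sf$protein_chains[["A"]]$observed_idx, 1:30)

  # deleted interior range -> disordered
  sf <- read_pdb(simple_chain_fixture(observed = setdiff(1:30, 5:8)))
  expect_equal(disordered_indices(sf$protein_chains[["A"]]), 5:8)

  # author numbering offset by +10, letters unique per window
  seq1 <- "MKTAYIAKQRQISFVKSHFS"
  s3 <- unname(ccprofiler:::AA_ONE_TO_THREE[strsplit(seq1, "")[[1]]])
  lines <- c(pdb_seqres_lines("A", s3))
  for (i in seq_along(s3)) {
    lines <- c(lines, pdb_atom_line("ATOM", i, "CA", s3[i], "A", i + 10,
                                    i * 3.8, 0, 0))
  }
  sf <- read_pdb(write_pdb_text(lines))
  expect_equal(sf$protein_chains[["A"]]$observed_idx, seq_along(s3))

  # mismatching observed letters are an error
  lines <- c(pdb_seqres_lines("A", rep("ALA", 5)),
             pdb_atom_line("ATOM", 1, "CA", "TRP", "A", 1, 0, 0, 0))
  expect_error(read_pdb(write_pdb_text(lines)), "embedded")
})

test_that("heavy_atoms drops hydrogens/deuterium and is idempotent", {
  res <- new_residue("ALA", "A", 1, atoms = list(
    new_atom("N", "N", c(0, 0, 0)), new_atom("CA", "C", c(1.5, 0, 0)),
    new_atom("C", "C", c(2, 1, 0)), new_atom("O", "O", c(3, 1, 0)),
    new_atom("CB", "C", c(1.5, 1.5, 0)),
    new_atom("H", "H", c(-0.5, 0, 0)), new_atom("HA", "H", c(1.5, -1, 0)),
    new_atom("D1", "D", c(0, -1, 0))
  ))
  ha <- heavy_atoms(res)
  expect_length(ha, 5)   # N, CA, C, O, CB
  expect_setequal(vapply(ha, function(a) a$name, character(1)),
                  c("N", "CA", "C", "O", "CB"))
  # idempotent
  res2 <- res; res2$atoms <- ha
  expect_length(heavy_atoms(res2), 5)

  water <- new_residue("HOH", "W", 1, atoms = list(
    new_atom("O", "O", c(0, 0, 0)), new_atom("H1", "H", c(1, 0, 0)),
    new_atom("H2", "H", c(0, 1, 0))), is_het = TRUE)
  expect_length(heavy_atoms(water), 1)
})

test_that("write_pdb round-trips coordinates at PDB precision", {
  pairf <- make_hinge_pair(length = 30, hinge = 15, seed = 7)
  p1 <- tempfile(fileext = ".pdb")
  write_pdb(pairf$bound, p1)
  back <- read_pdb(p1)
  ps0 <- pairf$bound$protein_chains[["A"]]
  ps1 <- back$protein_chains[["A"]]
  expect_equal(ps1$observed_idx, ps0$observed_idx)
  expect_equal(ca_matrix(ps1), ca_matrix(ps0), tolerance = 1e-3)
  expect_equal(back$het_groups$comp_id, "GNP")

  # re-serialising the parsed file is byte-identical (lossless at precision)
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(back, p2)
  l1 <- readLines(p1); l2 <- readLines(p2)
  expect_identical(grep("^ATOM|^HETATM", l1, value = TRUE),
                   grep("^ATOM|^HETATM", l2, value = TRUE))
})

test_that("two-model output: MODEL 2 of identical structures equals MODEL 1", {
  sf <- make_backbone(12, "helix", seed = 5)
  ps <- sf$protein_chains[["A"]]
  path <- tempfile(fileext = ".pdb")
  write_pdb(list(ps, ps), path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  m1 <- grep("^ATOM", lines[seq_len(which(grepl("^ENDMDL", lines))[1])],
             value = TRUE)
  rest <- lines[(which(grepl("^ENDMDL", lines))[1] + 1):length(lines)]
  m2 <- grep("^ATOM", rest, value = TRUE)
  expect_identical(substr(m1, 31, 54), substr(m2, 31, 54))
})
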
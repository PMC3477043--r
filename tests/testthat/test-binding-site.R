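toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C"
)

test_that("PDB parsing keeps atoms, drops waters and resolves altlocs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_lines, "END"), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$elety, c("N", "CA", "C"))

  # altloc A/B with occupancies 0.6/0.4 -> only A survives
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, path2)
  m2 <- read_structure(path2)
  expect_equal(nrow(m2$atoms), 1L)
  expect_equal(m2$atoms$x, 0)
  expect_false(any(m2$atoms$resid == "HOH"))
})

test_that("contact extraction applies an inclusive heavy-atom cutoff", {
  m <- generate_structure_fixture("contact_shell",
                                  distances = c(4.9, 5.0, 5.1))
  cs <- extract_contact_residues(m, list(resname = "LIG"), cutoff = 5.0,
                                 chains = NA)
  # 4.9 in, 5.0 in (inclusive), 5.1 out
  expect_equal(cs$resno, c(1L, 2L))
  expect_equal(cs$min_dist, c(4.9, 5.0), tolerance = 1e-9)

  # residues with only hydrogen atoms are invisible to the detector
  mh <- generate_structure_fixture("contact_shell", distances = c(3.0, 4.0),
                                   hydrogen_only = 1L)
  csh <- extract_contact_residues(mh, list(resname = "LIG"), cutoff = 5.0,
                                  chains = NA)
  expect_equal(csh$resno, 2L)

  # unknown ligand names the selector
  expect_error(extract_contact_residues(m, list(resname = "TA1")),
               "TA1")
})

test_that("raising the cutoff never removes contact residues", {
  m <- generate_structure_fixture("contact_shell",
                                  distances = c(2, 3.5, 4.2, 5, 6.5, 8))
  prev <- integer(0)
  for (cut in c(2.5, 4, 5.5, 7, 9)) {
    cur <- extract_contact_residues(m, list(resname = "LIG"), cutoff = cut,
                                    chains = NA)$resno
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contact sets are invariant under rigid motion and match a brute-force scan", {
  for (seed in 1:3) {
    set.seed(seed)
    dists <- sort(runif(8, 2, 8))
    m <- generate_structure_fixture("contact_shell", distances = dists)
    ref <- extract_contact_residues(m, list(resname = "LIG"), cutoff = 5,
                                    chains = NA)
    expect_equal(ref$resno, bruteforce_contacts(m, "LIG", 5))
    R <- random_rotation(seed + 10)
    m2 <- transform_structure(m, R, c(11.2, -3.4, 7.9))
    rot <- extract_contact_residues(m2, list(resname = "LIG"), cutoff = 5,
                                    chains = NA)
    expect_equal(rot$resno, ref$resno)
    expect_equal(rot$min_dist, ref$min_dist, tolerance = 1e-9)
  }
})

test_that("contact search defaults to the ligand's own chain", {
  m <- generate_structure_fixture("contact_shell", distances = c(3, 4))
  # move residue 2 to another chain; default search (ligand chain X ->
  # contacts restricted to chain X) finds nothing, chains=NA finds both
  m$atoms$chain[m$atoms$resno == 2 & m$atoms$record == "ATOM"] <- "B"
  on_lig_chain <- extract_contact_residues(m, list(resname = "LIG"),
                                           cutoff = 5)
  expect_equal(nrow(on_lig_chain), 0L)
  all_chains <- extract_contact_residues(m, list(resname = "LIG"),
                                         cutoff = 5, chains = NA)
  expect_equal(sort(all_chains$resno), c(1L, 2L))
})

test_that("structure numbering maps onto alignment columns", {
  # ungapped reference: identity map
  p <- write_toy_fasta(c(ref = "EVDDHA", other = "QTGDHA"))
  aln <- read_alignment(p, "fasta")
  expect_equal(unname(map_residues_to_columns(1:6, aln, "ref")), 1:6)
  # one leading gap shifts every column by one
  p2 <- write_toy_fasta(c(ref = "-EVDDHA", other = "QQTGDHA"))
  aln2 <- read_alignment(p2, "fasta")
  expect_equal(unname(map_residues_to_columns(1:6, aln2, "ref")), 2:7)
  # scattered gaps: verified against an exhaustive scan of the reference
  p3 <- write_toy_fasta(c(ref = "-EV--DD-HA", other = "AAAAAAAAAA"))
  aln3 <- read_alignment(p3, "fasta")
  ref_chars <- strsplit("-EV--DD-HA", "")[[1]]
  expected <- which(ref_chars != "-")  # column of the k-th residue
  got <- map_residues_to_columns(seq_along(expected), aln3, "ref")
  expect_equal(unname(got), expected)
  # offset numbering
  got20 <- map_residues_to_columns(20:22, aln3, "ref", first_resno = 20L)
  expect_equal(unname(got20), expected[1:3])
  # unmappable residue is an error listing the residue
  expect_error(map_residues_to_columns(99, aln, "ref"), "99")
  expect_error(map_residues_to_columns(1, aln, "nope"), "nope")
})

test_that("written structures re-read to PDB precision", {
  m <- generate_structure_fixture("staple_triangle", d12 = 4, d13 = 4.5,
                                  d23 = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
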
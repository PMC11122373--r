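test_that("read_pdb parses minimal and multi-chain records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(one_atom_pdb_lines(), f)
  s <- read_pdb(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(nrow(residues(s)), 1L)
  expect_equal(s$atoms$x, 1)
  expect_equal(s$atoms$name, "CA")

  two <- protstruct(rbind(ala_residue(1, "A"), ala_residue(2, "B", 5)))
  writeLines(readLines(write_pdb(two, f)), f)
  r <- read_pdb(f)
  expect_equal(residues(r)$chain, c("A", "B"))
})

test_that("read_pdb rejects malformed input and empty structures", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM")
  bad <- one_atom_pdb_lines()
  substr(bad[1], 31, 38) <- "   xx.yy"
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 1")
  # insertion codes rejected
  ins <- one_atom_pdb_lines()
  substr(ins[1], 27, 27) <- "A"
  writeLines(ins, f)
  expect_error(read_pdb(f), "insertion")
})

test_that("waters, heteroatoms and hydrogens are filtered by default", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       1.500   2.000   3.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "HETATM    4 MG    MG A 201       5.000   5.000   5.000  1.00  0.00          MG",
    "END"), f)
  expect_equal(n_atoms(read_pdb(f)), 1L)
  expect_equal(n_atoms(read_pdb(f, keep_hydrogens = TRUE)), 2L)
  expect_equal(n_atoms(read_pdb(f, keep_hetero = TRUE)), 2L)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$atoms$x, 2)
})

test_that("write_pdb/read_pdb round-trips a synthetic bundle", {
  b <- build_bundle(c("ADKLEQSVMFWYCHRNTGIPVAD", "KLEQSVMFWYCHRNTGIPVADKL",
                      "EQSVMFWYCHRNTGIPVADKLEQ"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b, f)
  r <- read_pdb(f)
  expect_equal(n_atoms(r), n_atoms(b))
  expect_equal(r$atoms$name, b$atoms$name)
  expect_equal(r$atoms$resid, b$atoms$resid)
  expect_lt(max(abs(coords(r) - coords(b))), 1e-3)

  expect_error(write_pdb(protstruct(ala_residue(1)[0, ]), f), "empty")
  expect_error(write_pdb(protstruct(ala_residue(100000)), f), "field width")
})

test_that("extract_range is inclusive and reports precise errors", {
  s <- build_helix(paste(rep("A", 232), collapse = ""))
  sub <- extract_range(s, "A", 164, 232)
  expect_equal(nrow(residues(sub)), 69L)        # 232 - 164 + 1
  expect_equal(range(residues(sub)$resid), c(164L, 232L))

  one <- extract_range(s, "A", 50, 50)
  expect_equal(nrow(residues(one)), 1L)

  # kinase-domain-style numbering: 449..722 inside a 440..730 chain
  k <- build_helix(paste(rep("A", 291), collapse = ""))
  k$atoms$resid <- k$atoms$resid + 439L
  expect_equal(nrow(residues(extract_range(k, "A", 449, 722))), 274L)

  expect_error(extract_range(s, "B", 1, 5), "chain 'B'")
  expect_error(extract_range(s, "A", 500, 600), "no residues in range")
})

test_that("mutation specs parse and reject invalid input", {
  m <- parse_mutation_spec("V600E")
  expect_equal(m$wt, "V"); expect_equal(m$pos, 600L); expect_equal(m$mut, "E")
  m2 <- parse_mutation_spec("I543A")
  expect_equal(unlist(m2[c("wt", "mut")]), c(wt = "I", mut = "A"))
  expect_error(parse_mutation_spec("X123A"), "not a standard")
  expect_error(parse_mutation_spec("A123A"), "itself")
  expect_error(parse_mutation_spec("123A"), "expected")
})

test_that("apply_mutations honours numbering offset and wild-type checks", {
  expect_equal(as.character(apply_mutations("ACDEF", list())), "ACDEF")

  seqv <- paste(rep("V", 5), collapse = "")
  out <- as.character(apply_mutations(seqv, "V600E", offset = 598))
  expect_equal(substr(out, 3, 3), "E")

  expect_error(apply_mutations("AAAAA", "V3E", offset = 1),
               "expected V, found A")
  expect_error(apply_mutations("VV", list(parse_mutation_spec("V1E"),
                                          parse_mutation_spec("V1L"))),
               "duplicate")
  expect_error(apply_mutations("VV", "V9E"), "outside the numbered range")
})

test_that("the 15 solubilizing mutations plus V600E apply in any grouping", {
  specs <- braf_solubilizing_mutations()
  expect_length(specs, 15L)
  muts <- lapply(specs, parse_mutation_spec)
  expect_true(all(vapply(muts, function(m) inherits(m, "mutation_spec"),
                         logical(1))))

  # conforming receptor sequence numbered 449..723
  offset <- 449L
  chars <- rep("G", 723 - 449 + 1)
  for (m in muts) chars[m$pos - offset + 1] <- m$wt
  chars[600 - offset + 1] <- "V"
  chars[chars == "G" & seq_along(chars) %% 2 == 0] <- "A"  # mixed filler
  seq0 <- paste(chars, collapse = "")

  two_step <- apply_mutations(apply_mutations(seq0, muts, offset),
                              "V600E", offset)
  one_step <- apply_mutations(seq0, c(specs, "V600E"), offset)
  expect_equal(as.character(two_step), as.character(one_step))
  expect_equal(substr(as.character(one_step), 600 - offset + 1,
                      600 - offset + 1), "E")
})
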
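test_that("a minimal two-residue PDB parses into 2 residues x 4 backbone atoms", {
  s <- readBackbone(paste(two_residue_pdb(), collapse = "\n"), chain = "A")
  expect_s4_class(s, "BackboneStructure")
  expect_equal(nResidues(s), 2L)
  expect_equal(nrow(atomTable(s)), 8L)
  expect_setequal(unique(atomTable(s)$tag), c("N", "CA", "C", "O"))
})

test_that("HETATM records and other chains are ignored", {
  lines <- c(two_residue_pdb()[1:8],
             pdb_record(90, "O", "HOH", "A", 99, 30, 30, 30, record = "HETATM"),
             pdb_record(91, "CA", "ALA", "B", 1, -20, 0, 0),
             "END")
  s <- readBackbone(paste(lines, collapse = "\n"), chain = "A")
  expect_equal(nrow(atomTable(s)), 8L)
  expect_false(99L %in% atomTable(s)$seq_pos)
})

test_that("altloc resolution keeps highest occupancy, ties go to first letter", {
  mk <- function(occA, occB) {
    lines <- c(pdb_record(1, "N", "ALA", "A", 1, 0, 0, 0),
               pdb_record(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = occA, alt = "A"),
               pdb_record(3, "CA", "ALA", "A", 1, 2, 0, 0, occ = occB, alt = "B"),
               pdb_record(4, "C", "ALA", "A", 1, 3, 0, 0),
               "END")
    readBackbone(paste(lines, collapse = "\n"), chain = "A")
  }
  # hand count after the altloc rule: exactly one CA survives either way
  s <- mk(0.4, 0.6)
  ca <- atomTable(s)[atomTable(s)$tag == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 2)          # B has the higher occupancy
  s2 <- mk(0.5, 0.5)
  ca2 <- atomTable(s2)[atomTable(s2)$tag == "CA", ]
  expect_equal(ca2$x, 1)         # tie: altloc A wins
})

test_that("only the first MODEL of a multi-model file is used", {
  lines <- c("MODEL        1", two_residue_pdb()[1:8], "ENDMDL",
             "MODEL        2",
             vapply(1:8, function(k)
               pdb_record(8 + k, c("N", "CA", "C", "O")[(k - 1) %% 4 + 1],
                          "ALA", "A", (k - 1) %/% 4 + 1, 100 + k, 0, 0),
               character(1)),
             "ENDMDL", "END")
  s <- readBackbone(paste(lines, collapse = "\n"), chain = "A")
  expect_equal(nrow(atomTable(s)), 8L)
  expect_true(all(atomTable(s)$x < 100))
})

test_that("residues are ordered by sequence number then insertion code", {
  lines <- c(pdb_record(1, "CA", "ALA", "A", 11, 3, 0, 0),
             pdb_record(2, "CA", "GLY", "A", 10, 1, 0, 0),
             pdb_record(3, "CA", "SER", "A", 10, 2, 0, 0, icode = "A"),
             "END")
  s <- readBackbone(paste(lines, collapse = "\n"), chain = "A")
  rt <- residueTable(s)
  expect_equal(rt$seq_pos, c(10L, 10L, 11L))
  expect_equal(rt$icode, c("", "A", ""))
  expect_equal(rt$residue, 1:3)
})

test_that("missing chain and chains without backbone atoms raise clear errors", {
  expect_error(readBackbone(paste(two_residue_pdb(), collapse = "\n"), "Z"),
               "chain not found")
  lines <- c(pdb_record(1, "CB", "ALA", "A", 1, 0, 0, 0), "END")
  expect_error(readBackbone(paste(lines, collapse = "\n"), "A"),
               "empty structure")
})

test_that("profile TSV round-trips, preserving values to 6+ significant digits", {
  p <- profile_from_values(c(3.141593, 5.25, 10.123456), id = "toy:A")
  tf <- tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  txt <- readLines(tf)
  expect_true(any(grepl("3.141593", txt, fixed = TRUE)))
  q <- readProfile(tf)
  expect_equal(q@structureId, p@structureId)
  expect_equal(q@metric, p@metric)
  expect_equal(q@window, p@window)
  expect_equal(ladValues(q), ladValues(p), tolerance = 1e-6)

  # parsing is idempotent: serialize(parse(file)) re-parses identically
  tf2 <- tempfile(fileext = ".tsv")
  writeProfile(q, tf2)
  expect_equal(readProfile(tf2)@entries, q@entries)
})

test_that("an empty profile writes a header-only file that round-trips", {
  p <- new("LADProfile", structureId = "empty:A", metric = "GD",
           window = 9L,
           entries = data.frame(residue = integer(0), seq_pos = integer(0),
                                resname = character(0), lad = numeric(0)))
  tf <- tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  q <- readProfile(tf)
  expect_equal(nResidues(q), 0L)
  expect_equal(q@metric, "GD")
})

test_that("malformed profile files fail with the offending line number", {
  p <- profile_from_values(c(1, 2))
  tf <- tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  txt <- readLines(tf)
  bad <- sub("^2\t2\tGLY\t.*$", "2\t2\tGLY\tnot_a_number", txt)
  writeLines(bad, tf)
  expect_error(readProfile(tf), "line 7.*non-numeric")
  writeLines(txt[-5], tf)   # drop the column header
  expect_error(readProfile(tf), "parse error")
})

test_that("round-tripping a backbone through PDB preserves geometry", {
  s <- makeToyChain(8, "helix")
  tf <- tempfile(fileext = ".pdb")
  writeBackbonePDB(s, tf)
  s2 <- readBackbone(tf, chain = "A")
  expect_equal(nResidues(s2), 8L)
  expect_equal(atomTable(s2)$x, atomTable(s)$x, tolerance = 1e-3)
})
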
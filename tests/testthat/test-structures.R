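test_that("a minimal one-residue PDB parses into a one-chain structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(miniPDBText(), f)
  s <- readPDB(f)
  expect_s4_class(s, "ZFStructure")
  expect_equal(chainIds(s), "A")
  expect_equal(nAtoms(s), 1L)
  a <- atomData(s)
  expect_equal(unname(unlist(a[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(unname(chainRoles(s)[["A"]]), "protein")
})

test_that("write/read round trip preserves names, counts and coordinates", {
  for (s in list(WRAPPED$structure, buildBDNADuplex("ACGT"))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    writePDB(s, f)
    s2 <- readPDB(f)
    expect_equal(nAtoms(s2), nAtoms(s))
    a <- atomData(s); b <- atomData(s2)
    expect_equal(a$name, b$name)
    expect_equal(a$resno, b$resno)
    expect_equal(a$resname, b$resname)
    expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                        as.matrix(b[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("degenerate PDB inputs raise clear errors", {
  expect_error(readPDB(file.path(tempdir(), "nope.pdb")), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK empty", "END"), f)
  expect_error(readPDB(f), "no ATOM records|cannot parse")
})

test_that("altloc conformers collapse to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_equal(nAtoms(s), 1L)
  expect_equal(atomData(s)$x, 2)
})

test_that("merging complementary strands renumbers 1..2n with a map", {
  sq <- "AGGGGCGGGGCC"  # Sp1 consensus site
  d <- buildBDNADuplex(sq)
  expect_equal(sort(unique(atomData(d)$resno)), 1:24)
  # rebuild the strands separately and merge by hand
  n <- nchar(sq)
  a <- atomData(d)
  sA <- ZFStructure(transform(a[a$resno <= n, ], chain = "X"),
                    chainRoles = c(X = "dna"))
  sB <- ZFStructure(transform(a[a$resno > n, ],
                              resno = resno - n, chain = "Y"),
                    chainRoles = c(Y = "dna"))
  m <- mergeAndRenumberDNA(sA, sB)
  expect_equal(sort(unique(atomData(m$structure)$resno)), 1:24)
  expect_equal(m$map$newResno, 1:24)
  expect_equal(m$map$oldResno, c(1:12, 1:12))
})

test_that("non-complementary or unequal strands fail with the mismatch", {
  d4 <- buildBDNADuplex("AAGG")
  a <- atomData(d4)
  sA <- ZFStructure(transform(a[a$resno <= 4, ], chain = "X"),
                    chainRoles = c(X = "dna"))
  sBbad <- ZFStructure(transform(a[a$resno <= 4, ], chain = "Y"),
                       chainRoles = c(Y = "dna"))  # same strand: not compl.
  expect_error(mergeAndRenumberDNA(sA, sBbad), "not complementary")
  d6 <- buildBDNADuplex("ACGTAA")
  b <- atomData(d6)
  sBlong <- ZFStructure(transform(b[b$resno <= 6, ], chain = "Y"),
                        chainRoles = c(Y = "dna"))
  expect_error(mergeAndRenumberDNA(sA, sBlong), "length")
})

test_that("zinc-finger annotation finds embedded Cys2His2 motifs", {
  one <- paste0(strrep("A", 5), "CAAC", strrep("G", 12), "HAAAH",
                strrep("A", 4))
  doms <- annotateZincFingers(one)
  expect_length(doms, 1L)
  expect_equal(doms[[1]]@znLigands, c(6L, 9L, 22L, 26L))
  # helix +1 sits helixOffset residues after the second Cys
  expect_equal(unname(helixPositions(doms[[1]])[["+1"]]), 9L + 7L)
  expect_equal(unname(helixPositions(doms[[1]])[["-1"]]), 9L + 6L)
  expect_length(annotateZincFingers(strrep("A", 60)), 0L)
  expect_error(annotateZincFingers(strrep("A", 60), minDomains = 1L),
               "motif")
})

test_that("the Zif268 sequence yields three fingers at canonical anchors", {
  doms <- zif268Domains()
  expect_length(doms, 3L)
  anchors <- vapply(doms, function(d) helixPositions(d)[["-1"]],
                    integer(1))
  expect_equal(anchors, c(18L, 46L, 74L))
  expect_equal(doms[[2]]@znLigands, c(37L, 40L, 53L, 57L))
  # deterministic and order-stable
  expect_identical(lapply(zif268Domains(), helixPositions),
                   lapply(doms, helixPositions))
})
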
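test_that("pairwise restraint sets carry the printed per-domain counts", {
  set1 <- buildPairwiseAirs(zif268AIRPairs("i"), label = "set i")
  expect_length(set1, 18L)
  perDomain <- table(vapply(airs(set1), function(a) a@domainIndex,
                            integer(1)))
  expect_equal(as.integer(perDomain), c(7L, 5L, 6L))
  set3 <- buildPairwiseAirs(zif268AIRPairs("iii"), label = "set iii")
  expect_length(set3, 6L)
  expect_true(all(table(vapply(airs(set3), function(a) a@domainIndex,
                               integer(1))) == 2L))
  expect_length(buildPairwiseAirs(zif268AIRPairs("i")[0, ]), 0L)
})

test_that("two-per-domain selection picks the helix ends", {
  doms <- zif268Domains()
  # restricted to the minimal candidates, the selection returns them
  s3 <- selectTwoPerDomain(zif268AIRPairs("iii"), doms)
  expect_equal(vapply(airs(s3), function(a) a@activeProtein, integer(1)),
               c(19L, 28L, 48L, 56L, 76L, 80L))
  # the full interaction table still yields exactly two per domain
  sFull <- selectTwoPerDomain(zif268AIRPairs("i"), doms)
  expect_length(sFull, 6L)
  expect_equal(unname(table(vapply(airs(sFull), function(a) a@domainIndex,
                                   integer(1)))), rep(2L, 3),
               ignore_attr = TRUE)
  # candidates exactly at -1 and +6 are chosen
  toy <- data.frame(domain = 1L, proteinRes = c(18L, 24L),
                    dnaBase = c(10L, 8L))
  st <- selectTwoPerDomain(toy, doms[1])
  expect_equal(vapply(airs(st), function(a) a@activeProtein, integer(1)),
               c(18L, 24L))
  # one candidate only, or one-sided candidates, fail with guidance
  expect_error(selectTwoPerDomain(toy[1, ], doms[1]), "another")
  oneSide <- data.frame(domain = 1L, proteinRes = c(18L, 19L),
                        dnaBase = c(10L, 9L))
  expect_error(selectTwoPerDomain(oneSide, doms[1]), "one half")
})

test_that("effective distance matches hand-computed and brute-force sums", {
  one <- effectiveDistance(matrix(c(0, 0, 0), 1), matrix(c(3, 0, 0), 1))
  expect_equal(one$value, 3.0)
  expect_equal(one$nPairs, 1L)
  two <- effectiveDistance(matrix(c(0, 0, 0), 1),
                           matrix(c(3, 0, 0, -3, 0, 0), 2, byrow = TRUE))
  expect_equal(two$value, 3 * 2^(-1 / 6), tolerance = 1e-12)
  set.seed(7)
  for (k in 1:10) {
    A <- matrix(runif(3 * sample(2:50, 1), -10, 10), ncol = 3)
    B <- matrix(runif(3 * sample(2:50, 1), 12, 25), ncol = 3)
    got <- effectiveDistance(A, B)
    expect_equal(got$value, bruteEffectiveDistance(A, B),
                 tolerance = 1e-9)
    minD <- min(sqrt(crossDistSlow(A, B)))
    expect_lte(got$value, minD + 1e-12)
  }
  expect_error(effectiveDistance(matrix(0, 1, 3), matrix(0, 1, 3)),
               "coincident")
})

test_that("restraint tables encode the 2 A bound and round-trip", {
  set <- buildPairwiseAirs(zif268AIRPairs("iii"))
  f <- withr::local_tempfile(fileext = ".tbl")
  writeTbl(set, f)
  lines <- readLines(f)
  expect_length(grep("^assign ", lines), 6L)
  expect_true(all(grepl("2\\.0 2\\.0 0\\.0$", grep("^assign ", lines,
                                                   value = TRUE))))
  rt <- readTbl(f)
  expect_equal(lapply(airs(rt), function(a)
    list(a@domainIndex, a@activeProtein, a@activeDna, a@upperBound)),
    lapply(airs(set), function(a)
      list(a@domainIndex, a@activeProtein, a@activeDna, a@upperBound)))
  expect_equal(airMode(rt), airMode(set))
  # byte-stable output
  f2 <- withr::local_tempfile(fileext = ".tbl")
  writeTbl(set, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty set: header-only file
  fe <- withr::local_tempfile(fileext = ".tbl")
  writeTbl(AIRSet(), fe)
  expect_length(grep("^assign", readLines(fe)), 0L)
  expect_length(grep("^!", readLines(fe)), 1L)
})

test_that("restraint energy is flat-bottomed, additive and quadratic", {
  gt <- WRAPPED
  tab <- makeToyInteractionTable(gt)
  set <- buildPairwiseAirs(tab[, c("domain", "proteinRes", "dnaBase")])
  ea <- airEnergy(set, gt$structure)
  expect_equal(ea$energy, 0)
  expect_true(all(ea$violations$delta == 0))
  # one violated restraint with a known effective distance
  a <- atomData(gt$structure)
  one <- AIRSet(list(AIR(1L, 10L, 4L, upperBound = 0.5)))
  d0 <- airEnergy(one, gt$structure, k = 50)
  deff <- d0$violations$deff[1]
  expect_equal(d0$energy, 50 * (deff - 0.5)^2, tolerance = 1e-10)
  # additivity over the union of two sets
  s1 <- AIRSet(airs(set)[1:4])
  s2 <- AIRSet(airs(set)[5:12])
  dec <- makeMismatchedDecoy(gt, 3, 150)
  eu <- airEnergy(set, dec)$energy
  expect_equal(airEnergy(s1, dec)$energy + airEnergy(s2, dec)$energy, eu,
               tolerance = 1e-9)
  expect_gte(eu, 0)
  expect_error(airEnergy(AIRSet(list(AIR(1L, 999L, 4L))), gt$structure),
               "999")
})

test_that("non-pairwise expansion collects exposed surface neighbours", {
  gt <- WRAPPED
  prot <- getChain(gt$structure, "A")
  dna <- getChain(gt$structure, "B")
  tab <- makeToyInteractionTable(gt)[c(1, 4), c("domain", "proteinRes",
                                                "dnaBase")]
  np <- expandNonPairwise(tab, prot, dna, sasaThreshold = 0.15,
                          neighborCutoff = 6.5)
  expect_equal(airMode(np), "non-pairwise")
  a1 <- airs(np)[[1]]
  # brute-force check: every passive protein residue is exposed and near
  aa <- atomData(prot, heavy = TRUE)
  act <- as.matrix(aa[aa$resno == a1@activeProtein, c("x", "y", "z")])
  for (pr in a1@passiveProtein) {
    d2 <- crossDistSlow(as.matrix(aa[aa$resno == pr, c("x", "y", "z")]),
                        act)
    expect_lte(min(sqrt(d2)), 6.5)
  }
  expect_false(a1@activeProtein %in% a1@passiveProtein)
  # an impossible threshold empties the passive sets -> pairwise-like
  np0 <- expandNonPairwise(tab, prot, dna, sasaThreshold = 2.0)
  expect_true(all(vapply(airs(np0), function(a)
    length(a@passiveProtein) + length(a@passiveDna), integer(1)) == 0L))
  # accepted by the table writer
  f <- withr::local_tempfile(fileext = ".tbl")
  writeTbl(np, f)
  expect_length(grep("^assign", readLines(f)), 2L)
})
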
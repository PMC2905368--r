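test_that("contact enumeration honors the cutoff boundary", {
  mk <- function(dx) {
    ZFStructure(rbind(
      data.frame(serial = 1L, name = "CA", resname = "ALA", chain = "A",
                 resno = 1L, x = 0, y = 0, z = 0, element = "C",
                 het = FALSE),
      data.frame(serial = 2L, name = "C1'", resname = "DA", chain = "B",
                 resno = 1L, x = dx, y = 0, z = 0, element = "C",
                 het = FALSE)),
      chainRoles = c(A = "protein", B = "dna"))
  }
  expect_equal(nrow(enumerateContacts(mk(4.9))), 1L)
  expect_equal(nrow(enumerateContacts(mk(5.1))), 0L)
  expect_equal(nrow(enumerateContacts(mk(100))), 0L)
})

test_that("contact enumeration equals the brute-force pair scan", {
  got <- enumerateContacts(WRAPPED$structure)
  expect_equal(attr(got, "cutoff"), 5.0)
  brute <- bruteContacts(WRAPPED$structure)
  expect_equal(as.matrix(got[, c("proteinRes", "dnaRes")]), brute,
               ignore_attr = TRUE)
  # every designed ground-truth contact is recovered
  key <- paste(got$proteinRes, got$dnaRes)
  expect_true(all(paste(WRAPPED$contacts$proteinRes,
                        WRAPPED$contacts$dnaBase) %in% key))
})

test_that("F_nat is 1 on self, decreases for decoys, 0 at separation", {
  s <- WRAPPED$structure
  expect_equal(fnat(s, s), 1.0)
  dec <- makeMismatchedDecoy(WRAPPED, 3, 150)
  fn <- fnat(dec, s)
  expect_lt(fn, 1.0)
  # brute-force recount of the decoy's recovered native contacts
  ref <- bruteContacts(s)
  mod <- bruteContacts(dec)
  expect_equal(fn, sum(paste(ref[, 1], ref[, 2]) %in%
                         paste(mod[, 1], mod[, 2])) / nrow(ref))
  far <- applyRigid(s, list(R = diag(3), t = c(500, 0, 0)))
  a <- atomData(s)
  a[a$chain == "A", c("x", "y", "z")] <-
    a[a$chain == "A", c("x", "y", "z")] + 100
  apart <- ZFStructure(a, chainRoles = chainRoles(s))
  expect_equal(fnat(apart, s), 0.0)
  expect_error(fnat(s, apart), "no intermolecular contacts")
})

test_that("Kabsch superposition: identity, rigid motions, proper rotation", {
  set.seed(3)
  X <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabschSuperpose(X, X)$rmsd, 0, tolerance = 1e-12)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- sweep(X %*% t(R), 2, c(5, 0, 0), "+")
  fit <- kabschSuperpose(X, Y)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabschSuperpose(X, Y[1:5, ]), "length")
  expect_true(kabschSuperpose(cbind(1:5, 0, 0),
                              cbind(2 * (1:5), 0, 0))$degenerate)
})

test_that("Kabsch RMSD matches the exhaustive rotation-grid oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(30, sd = 4), ncol = 3)
    B <- matrix(rnorm(30, sd = 4), ncol = 3)
    expect_equal(kabschSuperpose(A, B)$rmsd, gridRmsd(B, A),
                 tolerance = 1e-3)
  }
})

test_that("Kabsch agrees with the bio3d fitting routine", {
  set.seed(11)
  A <- matrix(rnorm(60, sd = 6), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.8), ncol = 3)
  ours <- kabschSuperpose(A, B)$rmsd
  fixed <- bio3d::fit.xyz(as.numeric(t(A)), as.numeric(t(B)),
                          fixed.inds = 1:60, mobile.inds = 1:60)
  theirs <- sqrt(mean(rowSums(
    (matrix(fixed, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("iRMSD is zero under rigid motions and tracks seeded noise", {
  s <- WRAPPED$structure
  expect_equal(irmsd(s, s), 0, tolerance = 1e-6)
  for (seed in 1:3) {
    moved <- applyRigid(s, randomRigid(seed))
    expect_equal(irmsd(moved, s), 0, tolerance = 1e-6)
  }
  pert <- perturbCoordinates(s, 0.5, seed = 99)
  got <- irmsd(pert, s)
  expect_gt(got, 0)
  # independent recomputation: brute-force interface + direct Kabsch
  ref <- atomData(s, heavy = TRUE, noHet = TRUE)
  cont <- enumerateContacts(s, cutoff = 10.0)
  sel <- c(paste("A", unique(cont$proteinRes)),
           paste("B", unique(cont$dnaRes)))
  keep <- paste(ref$chain, ref$resno) %in% sel
  mod <- atomData(pert, heavy = TRUE, noHet = TRUE)
  expect_equal(got, kabschSuperpose(
    as.matrix(ref[keep, c("x", "y", "z")]),
    as.matrix(mod[keep, c("x", "y", "z")]))$rmsd, tolerance = 1e-6)
})

test_that("wrap-around classification separates wrapped and decoy poses", {
  s <- WRAPPED$structure
  w <- classifyWrapAround(s)
  expect_true(w$wrapAround)
  expect_gte(w$coverage, 240)
  expect_true(all(w$domainContacts > 0))
  # all domains crowded into one narrow sector -> not wrapped
  narrow <- makeWrappedComplex(decoyConfig(azimuths = c(0, 20, 40)))
  wn <- classifyWrapAround(narrow$structure)
  expect_false(wn$wrapAround)
  expect_lt(wn$coverage, 180)
  # mismatched decoy: not wrapped, and its restraints are violated
  dec <- makeMismatchedDecoy(WRAPPED, 3, 150)
  wd <- classifyWrapAround(dec)
  expect_false(wd$wrapAround)
  tab <- makeToyInteractionTable(WRAPPED)
  set <- buildPairwiseAirs(tab[, c("domain", "proteinRes", "dnaBase")])
  viol <- airEnergy(set, dec)$violations
  expect_true(all(viol$delta[viol$domain == 3] > 0))
  expect_true(all(viol$delta[viol$domain != 3] == 0))
  # invariant under a joint rigid transform of the whole complex
  moved <- applyRigid(s, randomRigid(5))
  wm <- classifyWrapAround(moved)
  expect_true(wm$wrapAround)
  expect_equal(wm$coverage, w$coverage, tolerance = 1e-6)
})

test_that("ranking is ascending, stable and bounded by the pool", {
  rec <- data.frame(model_id = c("m1", "m2", "m3"),
                    haddock_score = c(-10, -5, -20))
  rk <- rescoreAndRank(rec, n = 10)
  expect_equal(rk$model_id, c("m3", "m1", "m2"))
  expect_equal(rk$rank, 1:3)
  ties <- data.frame(model_id = c("a", "b", "c"),
                     haddock_score = c(-7, -7, -7))
  expect_equal(rescoreAndRank(ties, n = 2)$model_id, c("a", "b"))
  expect_error(rescoreAndRank(data.frame(model_id = "x",
                                         haddock_score = NA_real_)),
               "missing")
  wrec <- data.frame(model_id = "x", e_elec = -100, e_vdw = NA_real_)
  expect_error(rescoreAndRank(wrec, weights = c(e_vdw = 1)), "e_vdw")
  expect_equal(rescoreAndRank(wrec, weights = c(e_elec = 0.5))$score, -50)
})

test_that("population splitting recovers seeded energy clusters", {
  set.seed(21)
  ids <- sprintf("m%02d", 1:40)
  truth <- rep(1:2, each = 20)
  e <- ifelse(truth == 1, runif(40, 0, 4), runif(40, 80, 95))
  rec <- data.frame(model_id = ids, haddock_score = rnorm(40, -200, 5))
  pt <- populationTable(rec, stats::setNames(e, ids))
  expect_equal(nrow(pt$populations), 2L)
  expect_equal(unname(pt$table$population), truth)
  one <- populationTable(rec, stats::setNames(runif(40, 0, 3), ids))
  expect_equal(nrow(one$populations), 1L)
  expect_error(populationTable(rec[0, ], numeric()), "no score")
  expect_error(populationTable(rec, stats::setNames(e[1:10], ids[1:10])),
               "m11")
})
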
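test_that("the fitted axis of an ideal duplex is the construction axis", {
  d <- buildBDNADuplex("AGGGGCGGGGCC")
  ax <- fitHelixAxis(d)
  expect_lt(max(abs(axisDirection(ax) - c(0, 0, 1))), 1e-3)
  expect_lt(ax@rmsResidual, 0.1)
})

test_that("axis fitting is equivariant under rigid motions", {
  d <- buildBDNADuplex("GCGTGGGCGT")
  d0 <- axisDirection(fitHelixAxis(d))
  for (seed in 1:5) {
    rg <- randomRigid(seed)
    ax <- fitHelixAxis(applyRigid(d, rg))
    expect_lt(max(abs(axisDirection(ax) - as.numeric(rg$R %*% d0))),
              1e-3)
  }
  expect_error(fitHelixAxis(buildBDNADuplex("ACG")), ">= 4")
})

test_that("a scrambled duplex reports a large residual without crashing", {
  d <- buildBDNADuplex("ACGTACGT")
  a <- atomData(d)
  set.seed(1)
  a[, c("x", "y", "z")] <- matrix(runif(3 * nrow(a), -30, 30), ncol = 3)
  ax <- fitHelixAxis(ZFStructure(a, chainRoles = chainRoles(d)))
  expect_gt(ax@rmsResidual, 1)
})

test_that("projection geometry: on-axis points, opposition, invariance", {
  ax <- HelixAxis(point = c(0, 0, 0), direction = c(0, 0, 1),
                  reference = c(1, 0, 0))
  mk <- function(xyz, resno) {
    ZFStructure(data.frame(serial = seq_len(nrow(xyz)), name = "CA",
                           resname = "ALA", chain = "A", resno = resno,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           element = "C", het = FALSE),
                chainRoles = c(A = "protein"))
  }
  onAxis <- mk(matrix(c(0, 0, 5), 1), 1L)
  v <- projectionPoints(projectResidues(onAxis, ax, 1L))
  expect_equal(v$radius, 0)
  expect_equal(v$azimuth, 0)
  opp <- mk(rbind(c(4, 0, 1), c(-6, 0, 9)), 1:2)
  vo <- projectionPoints(projectResidues(opp, ax, 1:2))
  expect_equal(abs(((vo$azimuth[2] - vo$azimuth[1]) + 360) %% 360), 180,
               tolerance = 0.1)
  # invariance to translation along the axis
  shifted <- mk(rbind(c(4, 0, 21), c(-6, 0, 29)), 1:2)
  vs <- projectionPoints(projectResidues(shifted, ax, 1:2))
  expect_equal(vs$azimuth, vo$azimuth, tolerance = 1e-9)
  expect_equal(vs$radius, vo$radius, tolerance = 1e-9)
  expect_error(projectResidues(mk(matrix(c(1, 1, 1), 1), 5L), ax, 6L),
               "no CA")
})

test_that("balance verdicts follow counts and azimuthal clustering", {
  gt <- WRAPPED
  tab <- makeToyInteractionTable(gt)
  doms <- gt$domains
  axis <- gt$axis
  # equal 2/2/2 with clustered geometry -> balanced
  set3 <- selectTwoPerDomain(tab, doms)
  v3 <- projectAIRSet(set3, gt$structure, axis)
  r3 <- assessDistribution(set3, v3)
  expect_true(isBalanced(r3))
  expect_equal(r3@perDomainCounts, c(2L, 2L, 2L))
  # unequal counts (the complete-interface situation, 7/5/6) -> unbalanced
  lop <- buildPairwiseAirs(tab[c(1:4, 5:7, 9:12), c("domain",
                                                    "proteinRes",
                                                    "dnaBase")])
  vl <- projectAIRSet(lop, gt$structure, axis)
  rl <- assessDistribution(lop, vl)
  expect_false(isBalanced(rl))
  expect_equal(rl@perDomainCounts, c(4L, 3L, 4L))
  # a single restraint residue rotated 150 deg out of its domain cluster
  resno3 <- vapply(airs(set3), function(a) a@activeProtein, integer(1))
  odd <- resno3[6]
  a <- atomData(gt$structure)
  sel <- a$chain == "A" & a$resno == odd
  th <- 150 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
  a[sel, c("x", "y", "z")] <-
    as.matrix(a[sel, c("x", "y", "z")]) %*% t(rot)
  oddStruct <- ZFStructure(a, chainRoles = chainRoles(gt$structure))
  vd <- projectAIRSet(set3, oddStruct, axis)
  rd <- assessDistribution(set3, vd)
  expect_false(isBalanced(rd))
  expect_true(odd %in% rd@offenders)
  expect_error(assessDistribution(AIRSet(), v3), "empty")
})

test_that("balance reports are stable under restraint relabeling", {
  gt <- WRAPPED
  tab <- makeToyInteractionTable(gt)
  set <- selectTwoPerDomain(tab, gt$domains)
  rev <- AIRSet(rev(airs(set)))
  v1 <- projectAIRSet(set, gt$structure, gt$axis)
  v2 <- projectAIRSet(rev, gt$structure, gt$axis)
  r1 <- assessDistribution(set, v1)
  r2 <- assessDistribution(rev, v2)
  expect_equal(isBalanced(r1), isBalanced(r2))
  expect_equal(sort(r1@perDomainCounts), sort(r2@perDomainCounts))
})
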
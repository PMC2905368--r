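# Shared fixtures and independent oracles.  The wrapped complex is built
# once per test run; every oracle below is a deliberately naive
# re-computation, independent of the package's code paths.

WRAPPED <- makeWrappedComplex()

# brute-force O(N^2) residue-base contact scan
bruteContacts <- function(model, cutoff = 5.0) {
  a <- atomData(model, heavy = TRUE, noHet = TRUE)
  roles <- chainRoles(model)
  p <- a[a$chain == names(roles)[roles == "protein"], ]
  d <- a[a$chain == names(roles)[roles == "dna"], ]
  out <- list()
  for (pr in unique(p$resno)) {
    pa <- p[p$resno == pr, c("x", "y", "z")]
    for (dr in unique(d$resno)) {
      da <- d[d$resno == dr, c("x", "y", "z")]
      found <- FALSE
      for (i in seq_len(nrow(pa))) {
        if (found) break
        for (j in seq_len(nrow(da))) {
          if (sqrt(sum((pa[i, ] - da[j, ])^2)) <= cutoff) {
            found <- TRUE
            break
          }
        }
      }
      if (found) out[[length(out) + 1L]] <- c(pr, dr)
    }
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(), ncol = 2)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# naive squared cross-distance matrix
crossDistSlow <- function(a, b) {
  m <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      m[i, j] <- sum((a[i, ] - b[j, ])^2)
  m
}

# double-loop effective distance
bruteEffectiveDistance <- function(a, b, exponent = 6) {
  s <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      s <- s + sqrt(sum((a[i, ] - b[j, ])^2))^(-exponent)
  s^(-1 / exponent)
}

# best-fit RMSD by exhaustive ZYZ Euler-angle grid search with zoom
gridRmsd <- function(A, B, levels = 4, coarse = 15) {
  ctrA <- colMeans(A); ctrB <- colMeans(B)
  A0 <- sweep(A, 2, ctrA); B0 <- sweep(B, 2, ctrB)
  rotZ <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
  rotY <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
  rmsdOf <- function(ang) {
    R <- rotZ(ang[1]) %*% rotY(ang[2]) %*% rotZ(ang[3])
    sqrt(mean(rowSums((B0 %*% t(R) - A0)^2)))
  }
  best <- c(0, 0, 0); bestV <- rmsdOf(best)
  step <- coarse * pi / 180
  grid <- list(seq(0, 2 * pi, by = step), seq(0, pi, by = step),
               seq(0, 2 * pi, by = step))
  for (a1 in grid[[1]]) for (a2 in grid[[2]]) for (a3 in grid[[3]]) {
    v <- rmsdOf(c(a1, a2, a3))
    if (v < bestV) { bestV <- v; best <- c(a1, a2, a3) }
  }
  for (lv in seq_len(levels)) {
    step <- step / 5
    for (a1 in best[1] + (-5:5) * step)
      for (a2 in best[2] + (-5:5) * step)
        for (a3 in best[3] + (-5:5) * step) {
          v <- rmsdOf(c(a1, a2, a3))
          if (v < bestV) { bestV <- v; best <- c(a1, a2, a3) }
        }
  }
  bestV
}

# random rigid motion, seeded
randomRigid <- function(seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  list(R = Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3]),
       t = runif(3, -20, 20))
}

applyRigid <- function(s, rigid) {
  a <- atomData(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rigid$R)
  a[, c("x", "y", "z")] <- sweep(xyz, 2, rigid$t, "+")
  ZFStructure(a, chainRoles = chainRoles(s), source = s@source)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# large flat cloud of pseudo-atoms for Monte-Carlo noise checks
mkNoiseCloud <- function(n) {
  ZFStructure(data.frame(serial = seq_len(n), name = "CA",
                         resname = "ALA", chain = "A", resno = seq_len(n),
                         x = 0, y = 0, z = 0, element = "C", het = FALSE),
              chainRoles = c(A = "protein"))
}

# minimal single-residue PDB text
miniPDBText <- function() {
  c(paste0("ATOM      1  CA  ALA A   1      ",
           " 1.000   2.000   3.000  1.00  0.00           C"),
    "END")
}
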
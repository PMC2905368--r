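#' Fiber-model parameters for canonical B-DNA construction
#'
#' @param twist helical twist per base-pair step, degrees (default 36.0).
#' @param rise axial rise per step, Angstrom (default 3.38).
#' @param templateSet identifier of the embedded nucleotide templates.
#' @return list of class `FiberParameters`.
#' @export
fiberParameters <- function(twist = 36.0, rise = 3.38,
                            templateSet = "idealized-v1") {
  if (twist <= 0 || twist >= 60) stop("twist must be in (0, 60) degrees")
  if (rise <= 2 || rise >= 5) stop("rise must be in (2, 5) Angstrom")
  structure(list(twist = twist, rise = rise, templateSet = templateSet),
            class = "FiberParameters")
}

#' Watson-Crick reverse complement
#'
#' @param seq DNA sequence string over the alphabet A, C, G, T.
#' @return the reverse complement, written 5' to 3'.
#' @export
wcComplement <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-ACGT character '", chars[bad[1]], "' at position ", bad[1])
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste(chars, collapse = ""))))
}

## ---- embedded nucleotide templates ----------------------------------------
##
## Idealized standard-geometry nucleotides in a base-pair frame: helix axis =
## z through the origin, base-pair plane = z = 0, strand-1 C1' on the +y
## side.  The paired C1' atoms sit symmetrically about the axis so that the
## base-pair midpoint (mean of paired C1') lies exactly on the axis.  The
## glycosidic bond leaves C1' at 55 degrees from the C1'-C1' line, which
## reproduces the ~8.8 A separation of the glycosidic nitrogens; rings are
## regular polygons (1.37 A sides) with exocyclic substituents 1.35 A
## outward.  Backbone atoms use fixed offsets from C1' (C2'-endo-like
## pucker, phosphate at ~9.5 A radius).  Strand 2 applies the Watson-Crick
## dyad: (x, y, z) -> (x, -y, -z).

.C1P <- c(0, 5.25, 0)
.GLYC_LEN <- 1.48
.GLYC_DIR <- c(sin(55 * pi / 180), -cos(55 * pi / 180), 0)

## regular ring attached at `attach`, extending along unit vector u
ringVertices <- function(attach, u, n, side = 1.37) {
  R <- side / (2 * sin(pi / n))
  center <- attach[1:2] + R * u[1:2]
  phi0 <- atan2(attach[2] - center[2], attach[1] - center[1])
  phis <- phi0 + (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + R * cos(phis), center[2] + R * sin(phis), 0)
}

exoAtom <- function(ring, i, bond = 1.35) {
  center <- colMeans(ring)
  v <- ring[i, ] - center
  v[3] <- 0
  ring[i, ] + bond * v / sqrt(sum(v^2))
}

baseAtoms <- function(base) {
  Ngly <- .C1P + .GLYC_LEN * .GLYC_DIR
  if (base %in% c("C", "T")) {
    ring <- ringVertices(Ngly, .GLYC_DIR, 6)
    rownames(ring) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    exo <- if (base == "C")
      rbind(O2 = exoAtom(ring, 2), N4 = exoAtom(ring, 4))
    else
      rbind(O2 = exoAtom(ring, 2), O4 = exoAtom(ring, 4),
            C7 = exoAtom(ring, 5))
    rbind(ring, exo)
  } else {
    pent <- ringVertices(Ngly, .GLYC_DIR, 5, side = 1.38)
    rownames(pent) <- c("N9", "C8", "N7", "C5", "C4")
    ## hexagon fused on the C4-C5 edge, on the far side of the pentagon
    C4 <- pent["C4", 1:2]; C5 <- pent["C5", 1:2]
    mid <- (C4 + C5) / 2
    p5c <- colMeans(pent)[1:2]
    nrm <- mid - p5c; nrm <- nrm / sqrt(sum(nrm^2))
    side <- sqrt(sum((C4 - C5)^2))
    hc <- mid + (side * sqrt(3) / 2) * nrm
    phi4 <- atan2(C4[2] - hc[2], C4[1] - hc[1])
    phi5 <- atan2(C5[2] - hc[2], C5[1] - hc[1])
    dphi <- ((phi5 - phi4 + pi) %% (2 * pi)) - pi
    step <- -sign(dphi) * pi / 3
    R6 <- side
    hex <- t(vapply(1:4, function(k) {
      c(hc[1] + R6 * cos(phi4 + k * step),
        hc[2] + R6 * sin(phi4 + k * step), 0)
    }, numeric(3)))
    rownames(hex) <- c("N3", "C2", "N1", "C6")
    ring6 <- rbind(C4 = c(C4, 0), hex, C5 = c(C5, 0))
    exo <- if (base == "A")
      rbind(N6 = exoAtom(ring6, 5))
    else
      rbind(O6 = exoAtom(ring6, 5), N2 = exoAtom(ring6, 3))
    rbind(pent, hex, exo)
  }
}

.BACKBONE <- rbind(
  `C1'` = c(0, 0, 0),
  `O4'` = c(-1.2, 0.6, 0.5),
  `C2'` = c(0.7, 0.9, -1.1),
  `C3'` = c(-0.2, 1.9, -1.5),
  `O3'` = c(0.7, 2.9, -1.9),
  `C4'` = c(-1.5, 1.8, -0.3),
  `C5'` = c(-2.3, 2.2, 0.9),
  `O5'` = c(-2.0, 3.0, 1.9),
  P     = c(-2.7, 3.9, 2.9),
  OP1   = c(-4.1, 3.7, 2.9),
  OP2   = c(-2.2, 5.2, 2.6))

## full nucleotide template (coordinate matrix, rownames = atom names)
nucleotideTemplate <- function(base) {
  bb <- sweep(.BACKBONE, 2, .C1P, "+")
  rbind(bb, baseAtoms(base))
}

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Build a canonical B-DNA duplex from sequence
#'
#' Places embedded standard-geometry nucleotide templates by rotating
#' `(i-1) * twist` about, and translating `(i-1) * rise` along, the global
#' z axis, which is therefore the helical axis of construction.  Strand 2
#' carries the Watson-Crick complement via the base-pair dyad.  The two
#' strands are merged into one consecutively renumbered chain (1..2n) with
#' [mergeAndRenumberDNA()].
#'
#' @param seq DNA string (length >= 2) for strand 1, 5' to 3'.
#' @param params a [fiberParameters()] list.
#' @param chainId chain id of the merged duplex chain.
#' @return a single-chain DNA [ZFStructure-class].
#' @export
buildBDNADuplex <- function(seq, params = fiberParameters(),
                            chainId = "B") {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 2) stop("sequence must have length >= 2")
  invisible(wcComplement(seq))  # alphabet check
  n <- length(chars)
  tw <- params$twist * pi / 180
  mirror <- diag(c(1, -1, -1))
  strand <- function(which) {
    rows <- list()
    for (i in seq_len(n)) {
      base <- if (which == 1) chars[i] else .COMPLEMENT[[chars[i]]]
      tmpl <- nucleotideTemplate(base)
      if (which == 2) tmpl <- tmpl %*% t(mirror)
      ang <- (i - 1) * tw
      rot <- matrix(c(cos(ang), sin(ang), 0,
                      -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
      xyz <- tmpl %*% t(rot)
      xyz[, 3] <- xyz[, 3] + (i - 1) * params$rise
      resno <- if (which == 1) i else n - i + 1L
      ## 5'-terminal residue carries no phosphate
      if ((which == 1 && i == 1) || (which == 2 && resno == 1))
        xyz <- xyz[!rownames(xyz) %in% c("P", "OP1", "OP2"), , drop = FALSE]
      rows[[i]] <- data.frame(
        serial = 0L, name = rownames(xyz), resname = paste0("D", base),
        chain = if (which == 1) "X" else "Y", resno = resno,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = guessElement(rownames(xyz)), het = FALSE,
        stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms <- atoms[order(atoms$resno), , drop = FALSE]
    atoms$serial <- seq_len(nrow(atoms))
    rownames(atoms) <- NULL
    ZFStructure(atoms, chainRoles = stats::setNames(
      "dna", atoms$chain[1]), source = "bdna-template")
  }
  merged <- mergeAndRenumberDNA(strand(1), strand(2), chainId = chainId)
  s <- merged$structure
  s@source <- sprintf("bdna:%s", paste(chars, collapse = ""))
  s
}

#' Base pairing of a merged duplex chain
#'
#' For a single chain of 2n nucleotides renumbered as produced by
#' [mergeAndRenumberDNA()], base i pairs base 2n+1-i.  Complementarity is
#' validated; the first mismatch (e.g. a deleted base pair) raises an error.
#'
#' @param duplex single-chain DNA [ZFStructure-class].
#' @return data.frame with columns `pair`, `resnoA`, `resnoB`, `baseA`,
#'   `baseB`.
#' @export
basePairs <- function(duplex) {
  roles <- chainRoles(duplex)
  dnaId <- names(roles)[roles == "dna"]
  if (length(dnaId) != 1L) stop("need exactly one DNA chain")
  sq <- chainSequence(duplex, dnaId)
  n2 <- length(sq)
  if (n2 %% 2L != 0L)
    stop("duplex has an odd number of nucleotides (", n2,
         "): unpaired or gapped")
  n <- n2 %/% 2L
  resno <- as.integer(names(sq))
  pairs <- data.frame(pair = seq_len(n),
                      resnoA = resno[seq_len(n)],
                      resnoB = resno[n2 + 1L - seq_len(n)],
                      baseA = unname(sq[seq_len(n)]),
                      baseB = unname(sq[n2 + 1L - seq_len(n)]),
                      stringsAsFactors = FALSE)
  bad <- which(.COMPLEMENT[pairs$baseA] != pairs$baseB)
  if (length(bad))
    stop("not Watson-Crick paired: base ", pairs$resnoA[bad[1]], " (",
         pairs$baseA[bad[1]], ") vs base ", pairs$resnoB[bad[1]], " (",
         pairs$baseB[bad[1]], ")")
  pairs
}

## C1' coordinate of every residue of the (single) DNA chain, by resno
c1pCoords <- function(duplex) {
  a <- atomData(duplex, noHet = TRUE)
  a <- a[a$name == "C1'", , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Measure per-step twist and rise of a duplex
#'
#' Rise is the axial separation of successive base-pair midpoints (mean of
#' the paired C1' atoms); twist is the rotation about the fitted helix axis
#' between successive C1'-C1' vectors.
#'
#' @param duplex merged-duplex [ZFStructure-class] (see [basePairs()]).
#' @return data.frame with columns `step`, `twist` (degrees), `rise`
#'   (Angstrom).
#' @export
measureStepParameters <- function(duplex) {
  pairs <- basePairs(duplex)
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 base pairs")
  c1 <- c1pCoords(duplex)
  A <- c1[as.character(pairs$resnoA), , drop = FALSE]
  B <- c1[as.character(pairs$resnoB), , drop = FALSE]
  mids <- (A + B) / 2
  d <- lineDirection(mids)
  if (sum((mids[n, ] - mids[1, ]) * d) < 0) d <- -d
  v <- B - A
  vperp <- v - outer(as.numeric(v %*% d), d)
  out <- data.frame(step = seq_len(n - 1), twist = NA_real_,
                    rise = NA_real_)
  for (i in seq_len(n - 1)) {
    out$rise[i] <- abs(sum((mids[i + 1, ] - mids[i, ]) * d))
    a <- vperp[i, ]; b <- vperp[i + 1, ]
    ang <- atan2(sum(crossProd(a, b) * d), sum(a * b))
    out$twist[i] <- ang * 180 / pi
  }
  out
}

crossProd <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## principal direction of a point cloud (unit vector)
lineDirection <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  d <- sv$v[, 1]
  d / sqrt(sum(d^2))
}
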
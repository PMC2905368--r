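.AMINO1TO3 <- stats::setNames(names(.AMINO3), .AMINO3)

## run code under a temporary RNG state (restores .Random.seed afterwards)
localSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for synthetic wrapped-complex fixtures
#'
#' @param seq DNA sequence of the binding site (default the Sp1 consensus
#'   site 5'-AGGGGCGGGGCC-3').
#' @param nDomains number of pseudo-zinc-finger domains (default 3).
#' @param azimuths placement azimuth (degrees about the DNA axis) per
#'   domain; defaults to an even spread.
#' @param contactOffset closest-approach distance (Angstrom) between a
#'   contacting side-chain pseudo-atom and its target base (default 1.8,
#'   chosen so a pairwise restraint on a true contact is satisfied at the
#'   2.0 Angstrom bound).
#' @param noiseSigma Gaussian coordinate noise, Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @return a named list of class `DecoyConfig`.
#' @export
decoyConfig <- function(seq = "AGGGGCGGGGCC", nDomains = 3L,
                        azimuths = NULL, contactOffset = 1.8,
                        noiseSigma = 0, seed = 1L) {
  if (is.null(azimuths))
    azimuths <- (seq_len(nDomains) - 1L) * 360 / nDomains
  if (length(azimuths) != nDomains)
    stop("need one azimuth per domain (", nDomains, ")")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  structure(list(seq = seq, nDomains = as.integer(nDomains),
                 azimuths = azimuths, contactOffset = contactOffset,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "DecoyConfig")
}

## 21-residue pseudo-finger: Cys2His2 motif with canonical helix residues
.FINGER_SEQ <- c("C", "A", "A", "C", "A", "A", "A", "A", "A", "R", "S",
                 "D", "E", "A", "A", "R", "H", "A", "A", "A", "H")
.LINKER_SEQ <- c("G", "G", "G", "G", "G")
## local index of the DNA-contacting helix positions (-1, +2, +3, +6)
.CONTACT_LOCAL <- c(`-1` = 10L, `+2` = 12L, `+3` = 13L, `+6` = 16L)

#' Generate a synthetic wrapped protein-DNA complex with ground truth
#'
#' Builds an ideal B-DNA duplex from the configured sequence plus a
#' pseudo-protein of `nDomains` mini zinc fingers (C-alpha trace plus
#' side-chain pseudo-atoms, each carrying the Cys2His2 sequence motif)
#' placed at the configured azimuths about the DNA axis.  The recognition
#' positions (-1, +2, +3, +6) of each finger touch their own DNA subsite at
#' `contactOffset`, so the generated residue-base pairs are true contacts
#' and pairwise restraints built on them are satisfied by construction.
#'
#' @param cfg a [decoyConfig()] list.
#' @return list with `structure` (complex [ZFStructure-class], protein
#'   chain "A", DNA chain "B"), `domains` (annotated
#'   [ZincFingerDomain-class] list), `contacts` (data.frame `domain`,
#'   `proteinRes`, `dnaBase`, `helixPos`: the designed true contacts),
#'   `axis` (fitted [HelixAxis-class]) and `config`.
#' @export
makeWrappedComplex <- function(cfg = decoyConfig()) {
  dna <- buildBDNADuplex(cfg$seq, chainId = "B")
  dnaAtoms <- atomData(dna, heavy = TRUE)
  n <- nchar(cfg$seq)
  sub <- max(1L, n %/% cfg$nDomains)
  rise <- 3.38
  rCa <- 12.0
  spreadDeg <- 2.5
  zStep <- 1.2
  rows <- list()
  contacts <- list()
  resno <- 0L
  serial <- 0L
  for (d in seq_len(cfg$nDomains)) {
    alpha <- cfg$azimuths[d]
    zc <- ((d - 0.5) * sub - 0.5) * rise
    baseIds <- (d - 1L) * sub + seq_len(sub)
    for (j in seq_along(.FINGER_SEQ)) {
      resno <- resno + 1L
      theta <- (alpha + (j - 11) * spreadDeg) * pi / 180
      ca <- c(rCa * cos(theta), rCa * sin(theta), zc + (j - 11) * zStep)
      serial <- serial + 1L
      res3 <- .AMINO1TO3[[.FINGER_SEQ[j]]]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "CA", resname = res3, chain = "A",
        resno = resno, x = ca[1], y = ca[2], z = ca[3], element = "C",
        het = FALSE, stringsAsFactors = FALSE)
      hit <- which(.CONTACT_LOCAL == j)
      if (length(hit)) {
        ## side chain reaches its target base at the contact offset
        pos <- names(.CONTACT_LOCAL)[hit]
        k <- match(pos, c("-1", "+2", "+3", "+6"))
        target <- baseIds[min(sub, 1L + (length(.CONTACT_LOCAL) - k))]
        ba <- dnaAtoms[dnaAtoms$resno == target, , drop = FALSE]
        bxyz <- as.matrix(ba[, c("x", "y", "z")])
        d2 <- rowSums(sweep(bxyz, 2, ca)^2)
        anchor <- bxyz[which.min(d2), ]
        dir <- ca - anchor
        dir <- dir / sqrt(sum(dir^2))
        cb <- anchor + cfg$contactOffset * dir
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = "CB", resname = res3, chain = "A",
          resno = resno, x = cb[1], y = cb[2], z = cb[3], element = "C",
          het = FALSE, stringsAsFactors = FALSE)
        contacts[[length(contacts) + 1L]] <- data.frame(
          domain = d, proteinRes = resno, dnaBase = target,
          helixPos = pos, stringsAsFactors = FALSE)
      }
    }
    if (d < cfg$nDomains) {
      for (g in .LINKER_SEQ) {
        resno <- resno + 1L
        theta <- (alpha + 30 + resno) * pi / 180
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = "CA", resname = .AMINO1TO3[[g]],
          chain = "A", resno = resno,
          x = 17 * cos(theta), y = 17 * sin(theta),
          z = zc + 14 + 0.5 * resno, element = "C", het = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  protAtoms <- do.call(rbind, rows)
  allAtoms <- rbind(protAtoms, atomData(dna))
  allAtoms$serial <- seq_len(nrow(allAtoms))
  s <- ZFStructure(allAtoms,
                   chainRoles = c(A = "protein", B = "dna"),
                   source = "fixture:wrapped")
  if (cfg$noiseSigma > 0)
    s <- perturbCoordinates(s, cfg$noiseSigma, seed = cfg$seed)
  list(structure = s,
       domains = annotateZincFingers(getChain(s, "A")),
       contacts = do.call(rbind, contacts),
       axis = fitHelixAxis(getChain(s, "B")),
       config = cfg)
}

#' Rotate one domain of a wrapped fixture away from its site
#'
#' Rigidly rotates the named domain's residues about the DNA helix axis,
#' leaving everything else untouched.  Large rotations (>= 120 degrees)
#' break the wrap-around conformation and violate that domain's restraints
#' while the other domains stay matched - the classic single-mismatch
#' failure mode of an unbalanced restraint set.
#'
#' @param base output of [makeWrappedComplex()].
#' @param domain domain index to displace.
#' @param rotation rotation about the DNA axis, degrees.
#' @return the decoy complex [ZFStructure-class].
#' @export
makeMismatchedDecoy <- function(base, domain, rotation) {
  doms <- base$domains
  if (domain < 1L || domain > length(doms)) stop("bad domain index ", domain)
  span <- domainSpan(doms[[domain]])
  s <- base$structure
  a <- atomData(s)
  sel <- a$chain == "A" & a$resno >= span[1] & a$resno <= span[2]
  axis <- base$axis
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  w <- sweep(xyz, 2, axisPoint(axis))
  ang <- rotation * pi / 180
  k <- axisDirection(axis)
  ## Rodrigues rotation about the axis direction
  rot <- t(vapply(seq_len(nrow(w)), function(i) {
    v <- w[i, ]
    v * cos(ang) + crossProd(k, v) * sin(ang) +
      k * sum(k * v) * (1 - cos(ang))
  }, numeric(3)))
  a[sel, c("x", "y", "z")] <- sweep(rot, 2, axisPoint(axis), "+")
  ZFStructure(a, chainRoles = chainRoles(s),
              source = sprintf("fixture:decoy-d%d-r%g", domain, rotation))
}

#' Add seeded Gaussian noise to heavy-atom coordinates
#'
#' @param s a [ZFStructure-class].
#' @param sigma per-coordinate standard deviation, Angstrom (>= 0).
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return the perturbed structure.
#' @export
perturbCoordinates <- function(s, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(s)
  a <- atomData(s)
  heavy <- a$element != "H"
  nh <- sum(heavy)
  noise <- localSeed(seed, matrix(stats::rnorm(3 * nh, sd = sigma), nh, 3))
  a[heavy, c("x", "y", "z")] <- a[heavy, c("x", "y", "z")] + noise
  ZFStructure(a, chainRoles = chainRoles(s), modelId = s@modelId,
              source = s@source)
}

#' Interaction table of a fixture's designed contacts
#'
#' Formats the ground-truth residue-base contacts of a wrapped fixture as
#' the per-domain interaction table consumed by [selectTwoPerDomain()] and
#' [buildPairwiseAirs()].
#'
#' @param groundTruth output of [makeWrappedComplex()].
#' @return data.frame with columns `domain`, `proteinRes`, `dnaBase`,
#'   `helixPos`.
#' @export
makeToyInteractionTable <- function(groundTruth) {
  groundTruth$contacts
}
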
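## heavy-atom coordinates of given residues of one chain
residueCoords <- function(s, chain, resno) {
  a <- atomData(s, heavy = TRUE, noHet = TRUE)
  a <- a[a$chain == chain & a$resno %in% resno, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

## the unique protein and dna chain ids of a complex model
complexChains <- function(model) {
  roles <- chainRoles(model)
  p <- names(roles)[roles == "protein"]
  d <- names(roles)[roles == "dna"]
  if (length(p) != 1L || length(d) != 1L)
    stop("model must have exactly one protein and one DNA chain (found ",
         length(p), " protein, ", length(d), " DNA)")
  list(protein = p, dna = d)
}

#' Build a pairwise restraint set from an interaction table
#'
#' One restraint per (residue, base) pair, grouped per zinc-finger domain
#' and carried together as a single set.
#'
#' @param pairs data.frame with columns `domain`, `proteinRes`, `dnaBase`.
#' @param bound upper distance bound in Angstrom (default 2.0).
#' @param label free-text label for the set.
#' @return an [AIRSet-class] in `"pairwise"` mode.
#' @export
buildPairwiseAirs <- function(pairs, bound = 2.0, label = "") {
  need <- c("domain", "proteinRes", "dnaBase")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  pairs <- pairs[order(pairs$domain), , drop = FALSE]
  lst <- lapply(seq_len(nrow(pairs)), function(i) {
    AIR(pairs$domain[i], pairs$proteinRes[i], pairs$dnaBase[i],
        upperBound = bound)
  })
  AIRSet(lst, mode = "pairwise", label = label)
}

#' Select two restraints per domain from candidate interactions
#'
#' Implements the minimal-restraint heuristic: per zinc finger keep two
#' pairwise restraints, one at the N-terminus of the recognition helix (the
#' candidate residue closest to canonical position -1) and one at or near
#' its C-terminus (closest to position +6).  Ties break toward the smaller
#' residue number.  A domain whose candidates all fall on one half of the
#' helix cannot be covered at both ends; this raises an error asking for
#' another interaction pair, mirroring the pre-screening back-loop of the
#' docking workflow.
#'
#' @param interactions data.frame with columns `domain`, `proteinRes`,
#'   `dnaBase`.
#' @param domains list of [ZincFingerDomain-class], indexed by `domain`.
#' @param bound upper distance bound in Angstrom.
#' @return an [AIRSet-class] with exactly `2 * length(domains)` restraints.
#' @export
selectTwoPerDomain <- function(interactions, domains, bound = 2.0) {
  picks <- list()
  for (dom in domains) {
    cand <- interactions[interactions$domain == dom@index, , drop = FALSE]
    if (nrow(cand) < 2)
      stop("domain ", dom@index, ": need at least 2 candidate ",
           "interactions, got ", nrow(cand),
           " - supply another interaction pair")
    hp <- helixPositions(dom)
    nAnchor <- hp[["-1"]]
    cAnchor <- hp[["+6"]]
    mid <- (nAnchor + cAnchor) / 2
    nHalf <- cand[cand$proteinRes <= mid, , drop = FALSE]
    cHalf <- cand[cand$proteinRes > mid, , drop = FALSE]
    if (nrow(nHalf) == 0L || nrow(cHalf) == 0L)
      stop("domain ", dom@index, ": all candidates lie on one half of ",
           "the recognition helix - supply another interaction pair")
    pick <- function(half, anchor) {
      d <- abs(half$proteinRes - anchor)
      half[order(d, half$proteinRes)[1], , drop = FALSE]
    }
    picks[[length(picks) + 1L]] <- pick(nHalf, nAnchor)
    picks[[length(picks) + 1L]] <- pick(cHalf, cAnchor)
  }
  buildPairwiseAirs(do.call(rbind, picks), bound = bound,
                    label = "two-per-domain")
}

#' Expand active pairs into non-pairwise restraints with passive neighbours
#'
#' For every active (residue, base) pair, the passive selections are the
#' solvent-exposed surface neighbours of the active residue/base: residues
#' with any heavy atom within `neighborCutoff` of the active selection and
#' relative solvent accessibility at or above `sasaThreshold`.  Relative
#' accessibility is the residue's in-context SASA divided by its SASA when
#' extracted in isolation.
#'
#' @param pairs data.frame with columns `domain`, `proteinRes`, `dnaBase`.
#' @param protein,dna [ZFStructure-class] objects carrying the surfaces.
#' @param sasaThreshold relative-SASA threshold (default 0.15).
#' @param neighborCutoff heavy-atom neighbour cutoff in Angstrom
#'   (default 6.5).
#' @param bound upper distance bound in Angstrom.
#' @return an [AIRSet-class] in `"non-pairwise"` mode.
#' @export
expandNonPairwise <- function(pairs, protein, dna, sasaThreshold = 0.15,
                              neighborCutoff = 6.5, bound = 2.0) {
  pChain <- names(chainRoles(protein))[chainRoles(protein) == "protein"][1]
  dChain <- names(chainRoles(dna))[chainRoles(dna) == "dna"][1]
  if (is.na(pChain) || is.na(dChain))
    stop("need a protein structure and a DNA structure")
  relP <- relativeSASA(protein, pChain)
  relD <- relativeSASA(dna, dChain)
  neighbours <- function(s, chain, active, rel) {
    act <- residueCoords(s, chain, active)
    a <- atomData(s, heavy = TRUE, noHet = TRUE)
    a <- a[a$chain == chain, , drop = FALSE]
    d2 <- crossDist2(as.matrix(a[, c("x", "y", "z")]), act)
    near <- unique(a$resno[apply(d2, 1, min) <= neighborCutoff^2])
    near <- setdiff(near, active)
    near[rel[as.character(near)] >= sasaThreshold]
  }
  actP <- unique(pairs$proteinRes)
  actD <- unique(pairs$dnaBase)
  lst <- lapply(seq_len(nrow(pairs)), function(i) {
    pp <- setdiff(neighbours(protein, pChain, pairs$proteinRes[i], relP),
                  actP)
    pd <- setdiff(neighbours(dna, dChain, pairs$dnaBase[i], relD), actD)
    AIR(pairs$domain[i], pairs$proteinRes[i], pairs$dnaBase[i],
        passiveProtein = sort(pp), passiveDna = sort(pd),
        upperBound = bound)
  })
  AIRSet(lst, mode = "non-pairwise", label = "non-pairwise")
}

#' Write a restraint set as a docking restraint table
#'
#' One `assign` block per restraint with segid/resid selection expressions
#' and the distance triple `d d- d+` encoding the flat-bottom upper bound
#' (2.0 Angstrom by default, written as `2.0 2.0 0.0`).  Output is
#' byte-stable for a fixed input and can be read back with [readTbl()].
#'
#' @param set an [AIRSet-class].
#' @param path output path.
#' @param proteinSegid,dnaSegid segment ids used in the selections.
#' @return `path`, invisibly.
#' @export
writeTbl <- function(set, path, proteinSegid = "A", dnaSegid = "B") {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  writeLines(sprintf("! zfAIR restraint table | mode=%s | label=%s",
                     airMode(set), airLabel(set)), con)
  for (a in airs(set)) {
    writeLines(sprintf("! domain %d", a@domainIndex), con)
    if (length(a@passiveProtein))
      writeLines(paste("! passive-protein",
                       paste(a@passiveProtein, collapse = " ")), con)
    selB <- paste(sprintf("(segid %s and resid %d)", dnaSegid,
                          c(a@activeDna, a@passiveDna)), collapse = " or ")
    if (length(a@activeDna) + length(a@passiveDna) > 1L)
      selB <- paste0("(", selB, ")")
    writeLines(sprintf("assign (segid %s and resid %d) %s %.1f %.1f %.1f",
                       proteinSegid, a@activeProtein, selB,
                       a@upperBound, a@upperBound, 0), con)
  }
  invisible(path)
}

#' Read a restraint table written by writeTbl
#'
#' @param path path to a `.tbl` file.
#' @return an [AIRSet-class]; `readTbl(writeTbl(x))` is the identity.
#' @export
readTbl <- function(path) {
  lines <- readLines(path)
  head <- grep("^! zfAIR restraint table", lines, value = TRUE)
  mode <- sub(".*mode=([^ |]+).*", "\\1", head[1])
  label <- sub(".*label=", "", head[1])
  dom <- NA_integer_
  passiveP <- integer()
  out <- list()
  for (ln in lines) {
    if (grepl("^! domain ", ln)) {
      dom <- as.integer(sub("^! domain ", "", ln))
      passiveP <- integer()
    } else if (grepl("^! passive-protein", ln)) {
      passiveP <- as.integer(strsplit(sub("^! passive-protein ", "", ln),
                                      " ")[[1]])
    } else if (grepl("^assign ", ln)) {
      resids <- regmatches(ln, gregexpr("resid [0-9]+", ln))[[1]]
      ids <- as.integer(sub("resid ", "", resids))
      nums <- regmatches(ln, gregexpr("[0-9]+\\.[0-9]+", ln))[[1]]
      ub <- as.numeric(nums[1])
      nDna <- length(ids) - 1L
      ## actives precede passives in the written order
      nPassive <- if (mode == "non-pairwise") nDna - 1L else 0L
      activeD <- ids[2:(1L + nDna - nPassive)]
      passiveD <- if (nPassive > 0) ids[(2L + nDna - nPassive):(1L + nDna)]
        else integer()
      out[[length(out) + 1L]] <- AIR(dom, ids[1], activeD,
                                     passiveProtein = passiveP,
                                     passiveDna = passiveD,
                                     upperBound = ub)
      passiveP <- integer()
    }
  }
  AIRSet(out, mode = mode, label = label)
}

## squared cross-distance matrix between two coordinate matrices
crossDist2 <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Effective (ambiguous) distance between two atom selections
#'
#' The r^-6-summed ambiguous distance
#' `d_eff = (sum over all cross pairs d_mn^-6)^(-1/6)`, which is always at
#' most the minimum pairwise distance; additional nearby atom pairs only
#' shorten it.
#'
#' @param atomsA,atomsB coordinate matrices (n x 3, Angstrom), both
#'   non-empty.
#' @param exponent the summing exponent (default 6).
#' @return list with `value` (Angstrom) and `nPairs`.
#' @export
effectiveDistance <- function(atomsA, atomsB, exponent = 6) {
  atomsA <- matrix(atomsA, ncol = 3)
  atomsB <- matrix(atomsB, ncol = 3)
  if (nrow(atomsA) == 0L || nrow(atomsB) == 0L)
    stop("both atom selections must be non-empty")
  d2 <- crossDist2(atomsA, atomsB)
  if (any(d2 < 1e-12))
    stop("coincident atoms in the two selections (zero distance)")
  val <- sum(d2^(-exponent / 2))^(-1 / exponent)
  list(value = val, nPairs = nrow(atomsA) * nrow(atomsB))
}

#' Restraint-violation energy of a complex model
#'
#' Flat-bottom harmonic restraint energy: per restraint the violation is
#' `max(0, d_eff - upperBound)` with `d_eff` the effective distance between
#' the heavy atoms of the active protein residue and of the active plus
#' passive DNA bases; the energy is `k * sum(violation^2)`.  A restraint
#' whose residue and bases have drifted apart therefore contributes a
#' growing penalty, which is what exposes mismatched restraints in
#' non-wrap-around models.
#'
#' @param set an [AIRSet-class].
#' @param model complex [ZFStructure-class] (one protein + one DNA chain).
#' @param k force constant, kcal mol^-1 A^-2 (default 50).
#' @return list with `energy` (kcal mol^-1) and `violations` (data.frame
#'   `index`, `domain`, `proteinRes`, `deff`, `delta`).
#' @export
airEnergy <- function(set, model, k = 50) {
  ch <- complexChains(model)
  rows <- lapply(seq_along(airs(set)), function(i) {
    a <- airs(set)[[i]]
    A <- residueCoords(model, ch$protein, a@activeProtein)
    B <- residueCoords(model, ch$dna, c(a@activeDna, a@passiveDna))
    if (nrow(A) == 0L)
      stop("restraint ", i, ": protein residue ", a@activeProtein,
           " not found in model")
    if (nrow(B) == 0L)
      stop("restraint ", i, ": DNA base(s) ",
           paste(a@activeDna, collapse = ","), " not found in model")
    deff <- effectiveDistance(A, B)$value
    data.frame(index = i, domain = a@domainIndex,
               proteinRes = a@activeProtein, deff = deff,
               delta = max(0, deff - a@upperBound))
  })
  viol <- do.call(rbind, rows)
  if (is.null(viol))
    viol <- data.frame(index = integer(), domain = integer(),
                       proteinRes = integer(), deff = numeric(),
                       delta = numeric())
  list(energy = k * sum(viol$delta^2), violations = viol)
}
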
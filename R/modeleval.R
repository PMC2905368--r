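#' Enumerate intermolecular residue-base contacts
#'
#' A protein residue and a DNA base are in contact when any heavy-atom
#' cross distance is at or below the cutoff (default 5.0 Angstrom, the
#' standard intermolecular-contact criterion; hydrogen-bonded and
#' non-bonded contacts are counted identically).
#'
#' @param model complex [ZFStructure-class] with one protein and one DNA
#'   chain.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return data.frame with columns `proteinRes`, `dnaRes`, deduplicated and
#'   sorted, with the cutoff kept as attribute `"cutoff"`.
#' @export
enumerateContacts <- function(model, cutoff = 5.0) {
  ch <- complexChains(model)
  a <- atomData(model, heavy = TRUE, noHet = TRUE)
  p <- a[a$chain == ch$protein, , drop = FALSE]
  d <- a[a$chain == ch$dna, , drop = FALSE]
  d2 <- crossDist2(as.matrix(p[, c("x", "y", "z")]),
                   as.matrix(d[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  out <- unique(data.frame(proteinRes = p$resno[hit[, 1]],
                           dnaRes = d$resno[hit[, 2]]))
  out <- out[order(out$proteinRes, out$dnaRes), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Fraction of native contacts
#'
#' Number of reference (native) residue-base contacts recovered by a model,
#' divided by the total number of contacts in the reference structure.
#' Model and reference must share residue/base numbering.
#'
#' @param model,reference complex [ZFStructure-class] objects.
#' @param cutoff contact cutoff in Angstrom (default 5.0).
#' @return fraction in \[0, 1\].
#' @export
fnat <- function(model, reference, cutoff = 5.0) {
  ref <- enumerateContacts(reference, cutoff)
  if (nrow(ref) == 0L)
    stop("reference structure has no intermolecular contacts: ",
         "F_nat undefined")
  mod <- enumerateContacts(model, cutoff)
  keyR <- paste(ref$proteinRes, ref$dnaRes)
  keyM <- paste(mod$proteinRes, mod$dnaRes)
  sum(keyR %in% keyM) / length(keyR)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form optimal rotation/translation minimising the RMSD between two
#' matched coordinate sets, with the usual determinant guard so the result
#' is a proper rotation.
#'
#' @param coordsA,coordsB matched n x 3 coordinate matrices (n >= 3);
#'   `coordsB` is superposed onto `coordsA`.
#' @return list with `rotation` (3 x 3), `translation` (so that
#'   `coordsB %*% t(rotation) + translation` matches `coordsA`), `rmsd`
#'   (Angstrom) and `degenerate` (TRUE when the point sets are essentially
#'   collinear and the rotation is not unique).
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- matrix(coordsA, ncol = 3)
  coordsB <- matrix(coordsB, ncol = 3)
  if (nrow(coordsA) != nrow(coordsB))
    stop("coordinate sets differ in length (", nrow(coordsA), " vs ",
         nrow(coordsB), ")")
  if (nrow(coordsA) < 3) stop("need at least 3 matched points")
  ctrA <- colMeans(coordsA)
  ctrB <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ctrA)
  B <- sweep(coordsB, 2, ctrB)
  H <- crossprod(B, A)
  sv <- svd(H)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, sgn))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R, translation = ctrA - as.numeric(R %*% ctrB),
       rmsd = rmsd, degenerate = degenerate)
}

## matched heavy-atom coordinates for a residue selection shared by two
## structures (match on chain + resno + atom name, reference order)
matchedCoords <- function(reference, model, selection) {
  ra <- atomData(reference, heavy = TRUE, noHet = TRUE)
  ma <- atomData(model, heavy = TRUE, noHet = TRUE)
  key <- function(a) paste(a$chain, a$resno, a$name)
  ra <- ra[paste(ra$chain, ra$resno) %in% selection, , drop = FALSE]
  hit <- match(key(ra), key(ma))
  ok <- !is.na(hit)
  list(ref = as.matrix(ra[ok, c("x", "y", "z")]),
       mod = as.matrix(ma[hit[ok], c("x", "y", "z")]),
       n = sum(ok))
}

#' Interface RMSD
#'
#' The interface is defined on the reference: every residue or nucleotide
#' with any heavy atom within `interfaceCutoff` of the partner chain.  All
#' heavy atoms of those residues (shared between model and reference by
#' chain, residue number and atom name) are superposed with
#' [kabschSuperpose()] and the RMSD is reported.
#'
#' @param model,reference complex [ZFStructure-class] objects sharing
#'   numbering.
#' @param interfaceCutoff heavy-atom interface cutoff on the reference,
#'   Angstrom (default 10.0).
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interfaceCutoff = 10.0) {
  ch <- complexChains(reference)
  cont <- enumerateContacts(reference, cutoff = interfaceCutoff)
  if (nrow(cont) == 0L) stop("empty interface at ", interfaceCutoff, " A")
  selection <- unique(c(paste(ch$protein, cont$proteinRes),
                        paste(ch$dna, cont$dnaRes)))
  mc <- matchedCoords(reference, model, selection)
  if (mc$n < 3) stop("fewer than 3 shared interface atoms")
  kabschSuperpose(mc$ref, mc$mod)$rmsd
}

#' Wrap-around classification configuration
#'
#' @param minCoverage minimum azimuthal coverage (degrees) of the interface
#'   protein residues about the DNA axis for a model to count as
#'   wrap-around (default 180).
#' @param gapTol azimuthal gaps smaller than this (degrees) are treated as
#'   covered when accumulating coverage (default 120; a three-finger
#'   protein samples the circle sparsely).
#' @param contactCutoff contact cutoff in Angstrom (default 5.0).
#' @return a named list.
#' @export
wrapConfig <- function(minCoverage = 180, gapTol = 120,
                       contactCutoff = 5.0) {
  stopifnot(minCoverage > 0, gapTol > 0, contactCutoff > 0)
  list(minCoverage = minCoverage, gapTol = gapTol,
       contactCutoff = contactCutoff)
}

#' Classify the wrap-around conformation of a complex model
#'
#' Operational definition of the wrap-around binding mode: the C-alpha
#' azimuths (about the DNA helix axis) of the protein residues in contact
#' with DNA must cover at least `minCoverage` degrees of the circle (gaps
#' below `gapTol` count as covered), and every zinc-finger domain must
#' contribute at least one contact.  The coverage is returned so borderline
#' models can be audited.
#'
#' @param model complex [ZFStructure-class].
#' @param axis [HelixAxis-class] of the model's DNA (fitted when `NULL`).
#' @param config a [wrapConfig()] list.
#' @param domains list of [ZincFingerDomain-class]; annotated from the
#'   protein sequence when `NULL`.
#' @return list with `wrapAround` (logical), `coverage` (degrees) and
#'   `domainContacts` (contacts per domain).
#' @export
classifyWrapAround <- function(model, axis = NULL, config = wrapConfig(),
                               domains = NULL) {
  ch <- complexChains(model)
  if (is.null(axis)) axis <- fitHelixAxis(getChain(model, ch$dna))
  if (is.null(domains))
    domains <- annotateZincFingers(getChain(model, ch$protein))
  cont <- enumerateContacts(model, cutoff = config$contactCutoff)
  if (nrow(cont) == 0L)
    return(list(wrapAround = FALSE, coverage = 0,
                domainContacts = rep(0L, length(domains))))
  ires <- sort(unique(cont$proteinRes))
  view <- projectResidues(model, axis, ires, chain = ch$protein)
  coverage <- coverageDeg(projectionPoints(view)$azimuth, config$gapTol)
  domCont <- vapply(domains, function(d) {
    sum(ires >= d@span[1] & ires <= d@span[2])
  }, integer(1))
  list(wrapAround = coverage >= config$minCoverage && all(domCont > 0L),
       coverage = coverage, domainContacts = domCont)
}

#' Parse docking-engine score records
#'
#' Recognised dialects: a `file.list`-style listing (`"name" { score }`
#' per line), a TSV with a `model_id` column plus any of `e_elec`, `e_vdw`,
#' `e_desolv`, `e_air`, `bsa`, `haddock_score`, or a directory / PDB file
#' whose `REMARK scores:` line carries `key=value` pairs.  Missing
#' components stay `NA`, never zero.
#'
#' @param path file or directory.
#' @return data.frame of score records, one row per model.
#' @export
parseHaddockScores <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(pdb|list|tsv)$",
                        full.names = TRUE)
    if (!length(files)) stop("no parsable score records in ", path)
    recs <- do.call(rbind, lapply(sort(files), parseHaddockScores))
    rownames(recs) <- NULL
    return(recs)
  }
  if (!file.exists(path)) stop("no such score file: ", path)
  cols <- c("e_elec", "e_vdw", "e_desolv", "e_air", "bsa", "haddock_score")
  blank <- function(id) {
    r <- data.frame(model_id = id, stringsAsFactors = FALSE)
    for (cc in cols) r[[cc]] <- NA_real_
    r
  }
  lines <- readLines(path, warn = FALSE)
  if (grepl("\\.tsv$", path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"model_id" %in% names(tab)) stop("TSV needs a model_id column")
    out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      r <- blank(as.character(tab$model_id[i]))
      for (cc in intersect(cols, names(tab))) r[[cc]] <- tab[[cc]][i]
      r
    }))
    return(out)
  }
  listRows <- grep("^\\s*\".+\"\\s*\\{", lines, value = TRUE)
  if (length(listRows)) {
    out <- do.call(rbind, lapply(listRows, function(ln) {
      id <- sub("^\\s*\"([^\"]+)\".*$", "\\1", ln)
      id <- sub("^.*[:/]", "", id)
      id <- sub("\\.pdb.*$", "", id)
      sc <- as.numeric(sub("^.*\\{\\s*([-0-9.eE+]+)\\s*\\}.*$", "\\1", ln))
      r <- blank(id)
      r$haddock_score <- sc
      r
    }))
    return(out)
  }
  remark <- grep("^REMARK scores:", lines, value = TRUE)
  if (length(remark)) {
    r <- blank(sub("\\.pdb$", "", basename(path)))
    kv <- strsplit(sub("^REMARK scores:\\s*", "", remark[1]), "\\s+")[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=")[[1]]
      if (length(parts) == 2L && parts[1] %in% cols)
        r[[parts[1]]] <- as.numeric(parts[2])
    }
    return(r)
  }
  stop("no parsable score records in ", path)
}

#' Re-score and rank models
#'
#' Score is the weighted sum of the named components (or the parsed
#' `haddock_score` when `weights` is NULL); models are sorted ascending
#' (more negative is better) with a stable tie-break on input order, and
#' the top `n` are returned with a `rank` column.
#'
#' @param records score data.frame from [parseHaddockScores()].
#' @param weights named numeric vector of component weights, or NULL.
#' @param n number of best models to keep (default 10; the full pool when
#'   fewer are available).
#' @return ranked data.frame with columns of `records` plus `score` and
#'   `rank`.
#' @export
rescoreAndRank <- function(records, weights = NULL, n = 10L) {
  if (is.null(weights)) {
    if (any(is.na(records$haddock_score)))
      stop("haddock_score missing for some records and no weights given")
    score <- records$haddock_score
  } else {
    score <- rep(0, nrow(records))
    for (comp in names(weights)) {
      if (weights[[comp]] == 0) next
      if (!comp %in% names(records) || any(is.na(records[[comp]])))
        stop("component '", comp, "' missing under nonzero weight")
      score <- score + weights[[comp]] * records[[comp]]
    }
  }
  ord <- order(score)  # stable in R
  out <- records[ord, , drop = FALSE]
  out$score <- score[ord]
  out <- utils::head(out, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Restraint-energy population table
#'
#' Joins per-model restraint energies onto score records and groups the
#' models into 1-D populations by splitting the sorted energies at gaps
#' larger than `gapMin`.  A well-behaved restraint set yields a single
#' low-energy population; mismatched restraints produce additional
#' high-energy populations.
#'
#' @param records score data.frame with a `model_id` column.
#' @param eAir named numeric vector of restraint energies (names =
#'   model ids).
#' @param gapMin minimum energy gap (kcal mol^-1) separating populations
#'   (default 10).
#' @return list with `table` (data.frame `model_id`, `e_air`, `score`,
#'   `population`) and `populations` (data.frame `population`, `n`, `lo`,
#'   `hi`).
#' @export
populationTable <- function(records, eAir, gapMin = 10) {
  if (nrow(records) == 0L) stop("no score records")
  hit <- match(records$model_id, names(eAir))
  if (anyNA(hit))
    stop("no restraint energy for model(s): ",
         paste(records$model_id[is.na(hit)], collapse = ", "))
  tab <- data.frame(model_id = records$model_id,
                    e_air = as.numeric(eAir[hit]),
                    score = if ("score" %in% names(records))
                      records$score else records$haddock_score,
                    stringsAsFactors = FALSE)
  ord <- order(tab$e_air)
  e <- tab$e_air[ord]
  pop <- cumsum(c(1, diff(e) > gapMin))
  tab$population <- NA_integer_
  tab$population[ord] <- pop
  pops <- do.call(rbind, lapply(seq_len(max(pop)), function(k) {
    data.frame(population = k, n = sum(pop == k),
               lo = min(e[pop == k]), hi = max(e[pop == k]))
  }))
  list(table = tab, populations = pops)
}
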
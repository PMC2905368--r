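#' One-letter sequence of a chain
#'
#' @param s a [ZFStructure-class].
#' @param chain chain id; defaults to the only chain.
#' @return character vector of one-letter codes (amino acids or bases), one
#'   per residue in residue-number order.  Unknown residues become `"X"`.
#' @export
chainSequence <- function(s, chain = NULL) {
  a <- atomData(s, noHet = TRUE)
  if (is.null(chain)) {
    ids <- unique(a$chain)
    if (length(ids) != 1L) stop("specify a chain id (structure has ",
                                length(ids), ")")
    chain <- ids
  }
  a <- a[a$chain == chain, , drop = FALSE]
  res <- a[!duplicated(a$resno), c("resno", "resname")]
  res <- res[order(res$resno), ]
  code <- ifelse(res$resname %in% names(.AMINO3), .AMINO3[res$resname],
                 ifelse(res$resname %in% names(.NUC_NAMES),
                        .NUC_NAMES[res$resname], "X"))
  names(code) <- res$resno
  code
}

#' Merge two complementary DNA strands into one renumbered chain
#'
#' The two strands of a duplex are fused into a single chain and renumbered
#' 1..2n consecutively: strand A keeps its 5'->3' order as 1..n, strand B
#' follows, also 5'->3', as n+1..2n.  Base i therefore pairs base 2n+1-i.
#'
#' @param strandA,strandB single-chain DNA [ZFStructure-class] objects of
#'   equal length with Watson-Crick complementary sequences.
#' @param chainId chain id of the merged chain.
#' @return list with `structure` (the merged single-chain [ZFStructure-class])
#'   and `map` (data.frame `strand`, `oldResno`, `newResno`).
#' @export
mergeAndRenumberDNA <- function(strandA, strandB, chainId = "B") {
  seqA <- chainSequence(strandA)
  seqB <- chainSequence(strandB)
  if (length(seqA) != length(seqB))
    stop("strands differ in length (", length(seqA), " vs ",
         length(seqB), ")")
  expect <- strsplit(wcComplement(paste(seqA, collapse = "")), "")[[1]]
  mism <- which(seqB != expect)
  if (length(mism))
    stop("strands are not complementary: strand B position ", mism[1],
         " is ", seqB[mism[1]], ", expected ", expect[mism[1]])
  n <- length(seqA)
  renumber <- function(strand, offset, label) {
    a <- atomData(strand, noHet = TRUE)
    old <- sort(unique(a$resno))
    new <- offset + seq_along(old)
    a$resno <- new[match(a$resno, old)]
    a$chain <- chainId
    list(atoms = a,
         map = data.frame(strand = label, oldResno = old, newResno = new))
  }
  ra <- renumber(strandA, 0L, "A")
  rb <- renumber(strandB, n, "B")
  atoms <- rbind(ra$atoms, rb$atoms)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  roles <- stats::setNames("dna", chainId)
  list(structure = ZFStructure(atoms, chainRoles = roles,
                               source = "merged-duplex"),
       map = rbind(ra$map, rb$map))
}

#' Detect Cys2His2 zinc-finger domains in a protein chain
#'
#' Scans the chain sequence for the C-x(2,4)-C-x(12)-H-x(3,5)-H motif and
#' returns one [ZincFingerDomain-class] per non-overlapping match, ordered
#' N to C.  The recognition helix is placed from the second zinc-binding
#' Cys: its first residue (canonical position +1) sits `helixOffset`
#' residues downstream, which puts position -1 on the residue immediately
#' preceding the helix.  The default offset of 7 reproduces the canonical
#' DNA-contacting positions of the Zif268 family (-1 at Arg18/Arg46/Arg74).
#'
#' @param chain a single-chain protein [ZFStructure-class], or a character
#'   sequence (one-letter codes, optionally named by residue number).
#' @param minDomains error if fewer motifs than this are found (default 0:
#'   return what is found, possibly an empty list).
#' @param helixOffset residues between the second Cys and helix position +1.
#' @return list of [ZincFingerDomain-class] objects.
#' @export
annotateZincFingers <- function(chain, minDomains = 0L, helixOffset = 7L) {
  seqc <- if (is.character(chain)) {
    if (length(chain) == 1L) strsplit(chain, "")[[1]] else chain
  } else chainSequence(chain)
  resno <- if (!is.null(names(seqc)) && all(nzchar(names(seqc))))
    as.integer(names(seqc)) else seq_along(seqc)
  sq <- paste(seqc, collapse = "")
  m <- gregexpr("C.{2,4}C.{12}H.{3,5}H", sq, perl = TRUE)[[1]]
  if (m[1] == -1L) starts <- integer() else starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (length(starts) < minDomains)
    stop("found ", length(starts), " Cys2His2 motif(s), need ", minDomains,
         " (scan of C-x(2,4)-C-x(12)-H-x(3,5)-H over ", nchar(sq),
         " residues)")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + lens[k] - 1L)
    frag <- paste(seqc[idx], collapse = "")
    # recover the exact ligand positions the motif matched
    gm <- regexec("^C(.{2,4})C.{12}H(.{3,5})H$", frag)[[1]]
    g1 <- attr(gm, "match.length")[2]
    g2 <- attr(gm, "match.length")[3]
    cys <- starts[k] + c(0L, 1L + g1)
    his <- c(cys[2] + 13L, cys[2] + 14L + g2)
    helix1 <- cys[2] + helixOffset
    pos <- c(helix1 - 1L, helix1 + 0:5)
    names(pos) <- c("-1", paste0("+", 1:6))
    span <- range(c(idx, helix1 + 5L))
    out[[k]] <- new("ZincFingerDomain", index = k,
                    span = as.integer(resno[span]),
                    znLigands = as.integer(resno[c(cys, his)]),
                    helixSpan = as.integer(resno[c(helix1, idx[length(idx)])]),
                    helixPositions = stats::setNames(as.integer(resno[pos]),
                                                     names(pos)))
  }
  out
}

#' Zif268 DNA-binding domain sequence
#'
#' The three-finger Cys2His2 region of Zif268 (EGR1) in the conventional
#' 1-based numbering used throughout the package, under which the
#' recognition-helix position -1 residues are Arg18, Arg46 and Arg74.
#'
#' @return named character vector of one-letter codes (names = residue
#'   numbers 1..89).
#' @export
zif268Sequence <- function() {
  sq <- paste0("MERPYACPVESCDRRFSRSDELTRHIRIHTGQKPFQCRICMRNFSRSDHLTTHIR",
               "THTGEKPFACDICGRKFARSDERKRHTKIHLRQK")
  stats::setNames(strsplit(sq, "")[[1]], seq_len(nchar(sq)))
}

#' Zif268 zinc-finger domain annotations
#'
#' Convenience wrapper: [annotateZincFingers()] applied to
#' [zif268Sequence()], yielding the three fingers with recognition-helix
#' positions -1 at residues 18, 46 and 74.
#'
#' @return list of three [ZincFingerDomain-class] objects.
#' @export
zif268Domains <- function() {
  annotateZincFingers(zif268Sequence(), minDomains = 3L)
}

#' Curated Zif268-DNA residue-base interaction sets
#'
#' Three interaction tables for the Zif268-DNA complex interface, as used to
#' formulate docking restraints: set `"i"` is the complete hydrogen-bond plus
#' van der Waals contact list (7/5/6 pairs for fingers 1/2/3), set `"ii"`
#' the sequence-specific hydrogen bonds, and set `"iii"` the minimal
#' two-per-domain selection.  Base labels refer to the renumbered single
#' DNA chain (strand 1 then complement).
#'
#' @param set one of `"i"`, `"ii"`, `"iii"`.
#' @return data.frame with columns `domain`, `proteinRes`, `dnaBase`
#'   (numeric id) and `dnaLabel` (printed base letter + id).
#' @export
zif268AIRPairs <- function(set = c("iii", "i", "ii")) {
  set <- match.arg(set)
  tab <- switch(set,
    i = list(
      `1` = c(R18 = "G10", S19 = "T13", D20 = "T13", E21 = "G8",
              R24 = "G8", I28 = "G6", H25 = "G7"),
      `2` = c(R46 = "G7", D48 = "C17", H49 = "G6", H53 = "G4", T56 = "C3"),
      `3` = c(H74 = "G4", S75 = "C18", D76 = "A20", E77 = "G2",
              K79 = "C19", R80 = "G2")),
    ii = list(
      `1` = c(R18 = "G10", R24 = "G8"),
      `2` = c(R46 = "G7", D48 = "C17", H49 = "G6"),
      `3` = c(R74 = "G4", R80 = "G2")),
    iii = list(
      `1` = c(S19 = "T13", I28 = "G6"),
      `2` = c(D48 = "C17", T56 = "C3"),
      `3` = c(D76 = "A20", R80 = "G2")))
  rows <- lapply(names(tab), function(d) {
    p <- tab[[d]]
    data.frame(domain = as.integer(d),
               proteinRes = as.integer(sub("^[A-Z]", "", names(p))),
               dnaBase = as.integer(sub("^[A-Z]", "", unname(p))),
               dnaLabel = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
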
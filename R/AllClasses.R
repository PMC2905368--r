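#' @import methods
NULL

## Column layout shared by every atom table in the package.  Coordinates are
## in Angstrom; `het` marks HETATM records (zinc ions and other ligands).
.ATOM_COLS <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element", "het")

.AMINO3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.NUC_NAMES <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                A = "A", C = "C", G = "G", T = "T",
                ADE = "A", CYT = "C", GUA = "G", THY = "T")

#' Molecular structure as a validated atom table
#'
#' `ZFStructure` holds a chain -> residue -> atom hierarchy flattened into a
#' single atom table, plus a role (`"protein"`, `"dna"` or `"other"`) per
#' chain.  All geometry in the package operates on this class.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `element`, `het`.
#' @slot chainRoles named character vector mapping chain id to role.
#' @slot modelId integer model number (model 1 of multi-model files).
#' @slot source character tag: file path or generator name.
#'
#' @seealso [readPDB()], [writePDB()], [atomData()], [getChain()]
#' @export
setClass("ZFStructure",
         representation(atoms = "data.frame",
                        chainRoles = "character",
                        modelId = "integer",
                        source = "character"))

setValidity("ZFStructure", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atom table must have columns:",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(!nzchar(a$name))) return("empty atom name")
  ch <- unique(a$chain)
  if (!all(ch %in% names(object@chainRoles)))
    return("every chain needs a role in chainRoles")
  if (anyDuplicated(names(object@chainRoles)))
    return("duplicated chain id in chainRoles")
  if (!all(object@chainRoles %in% c("protein", "dna", "other")))
    return("chain roles must be 'protein', 'dna' or 'other'")
  TRUE
})

#' Construct a ZFStructure from an atom table
#'
#' @param atoms data.frame with the atom columns (see [ZFStructure-class]).
#' @param chainRoles named character vector chain id -> role; inferred from
#'   residue names when `NULL`.
#' @param modelId integer model id.
#' @param source provenance tag.
#' @return A [ZFStructure-class] object.
#' @export
ZFStructure <- function(atoms, chainRoles = NULL, modelId = 1L,
                        source = "constructed") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$element)) atoms$element <- guessElement(atoms$name)
  if (is.null(chainRoles)) chainRoles <- inferChainRoles(atoms)
  new("ZFStructure", atoms = atoms[, .ATOM_COLS], chainRoles = chainRoles,
      modelId = as.integer(modelId), source = source)
}

## Role of a chain from its residue names (HETATM-only chains -> "other").
inferChainRoles <- function(atoms) {
  ids <- unique(atoms$chain)
  roles <- vapply(ids, function(id) {
    rn <- unique(atoms$resname[atoms$chain == id & !atoms$het])
    if (!length(rn)) return("other")
    ndna <- sum(rn %in% names(.NUC_NAMES))
    nprot <- sum(rn %in% names(.AMINO3))
    if (ndna >= nprot && ndna > 0) "dna" else if (nprot > 0) "protein"
    else "other"
  }, character(1))
  names(roles) <- ids
  roles
}

## Element symbol from a PDB atom name ("C1'" -> "C", "OP1" -> "O").
guessElement <- function(name) {
  sym <- sub("^[0-9']*", "", name)
  substr(toupper(sym), 1L, 1L)
}

#' Cys2His2 zinc-finger domain annotation
#'
#' @slot index finger number (1..n, N to C terminus).
#' @slot span closed residue-number interval `c(from, to)` of the domain.
#' @slot znLigands residue numbers of the Cys, Cys, His, His zinc ligands.
#' @slot helixSpan closed interval of the recognition helix.
#' @slot helixPositions named integer vector mapping the canonical
#'   DNA-contacting positions (`"-1"`, `"+1"` ... `"+6"`) to residue numbers.
#' @export
setClass("ZincFingerDomain",
         representation(index = "integer", span = "integer",
                        znLigands = "integer", helixSpan = "integer",
                        helixPositions = "integer"))

setValidity("ZincFingerDomain", function(object) {
  if (length(object@span) != 2L || diff(object@span) < 0)
    return("span must be c(from, to) with from <= to")
  zl <- object@znLigands
  if (length(zl) != 4L || is.unsorted(zl))
    return("znLigands must be 4 increasing residue numbers (C,C,H,H)")
  if (any(zl < object@span[1] | zl > object@span[2]))
    return("zinc ligands outside domain span")
  hs <- object@helixSpan
  if (hs[1] < object@span[1] || hs[2] > object@span[2])
    return("helix span must lie within the domain span")
  hp <- object@helixPositions
  if (anyDuplicated(hp)) return("helixPositions must be injective")
  TRUE
})

#' A single ambiguous interaction restraint
#'
#' Restrains an active protein residue against one or more DNA bases (plus
#' optional passive selections) with a flat-bottom upper bound, satisfied
#' when the effective distance of the heavy-atom selections is below the
#' bound.
#'
#' @slot domainIndex which zinc finger the restraint belongs to.
#' @slot activeProtein active protein residue number (length 1).
#' @slot activeDna active DNA base number(s).
#' @slot passiveProtein passive (surface-neighbour) protein residues.
#' @slot passiveDna passive DNA bases.
#' @slot upperBound upper distance bound in Angstrom (default 2.0).
#' @export
setClass("AIR",
         representation(domainIndex = "integer", activeProtein = "integer",
                        activeDna = "integer", passiveProtein = "integer",
                        passiveDna = "integer", upperBound = "numeric"))

setValidity("AIR", function(object) {
  if (length(object@activeProtein) != 1L) return("exactly one active residue")
  if (length(object@activeDna) < 1L) return("active DNA selection empty")
  if (object@upperBound <= 0) return("upperBound must be positive")
  if (length(intersect(object@passiveProtein, object@activeProtein)) ||
      length(intersect(object@passiveDna, object@activeDna)))
    return("passive selections must be disjoint from active ones")
  TRUE
})

#' @rdname AIR-class
#' @param domainIndex,activeProtein,activeDna,passiveProtein,passiveDna,upperBound
#'   see slots.
#' @export
AIR <- function(domainIndex, activeProtein, activeDna,
                passiveProtein = integer(), passiveDna = integer(),
                upperBound = 2.0) {
  new("AIR", domainIndex = as.integer(domainIndex),
      activeProtein = as.integer(activeProtein),
      activeDna = as.integer(activeDna),
      passiveProtein = as.integer(passiveProtein),
      passiveDna = as.integer(passiveDna),
      upperBound = as.numeric(upperBound))
}

#' A set of ambiguous interaction restraints
#'
#' The restraints of all domains are carried together as one input, mirroring
#' how the per-domain restraints are summed into a single docking table.
#' In `"pairwise"` mode every restraint joins exactly one residue to one base
#' and passive selections are empty.
#'
#' @slot airs list of [AIR-class] objects.
#' @slot mode `"pairwise"` or `"non-pairwise"`.
#' @slot label free-text label (e.g. `"set iii"`).
#' @export
setClass("AIRSet",
         representation(airs = "list", mode = "character",
                        label = "character"))

setValidity("AIRSet", function(object) {
  if (!object@mode %in% c("pairwise", "non-pairwise"))
    return("mode must be 'pairwise' or 'non-pairwise'")
  ok <- vapply(object@airs, is, logical(1), class2 = "AIR")
  if (!all(ok)) return("airs must be a list of AIR objects")
  if (object@mode == "pairwise") {
    for (a in object@airs)
      if (length(a@activeDna) != 1L || length(a@passiveProtein) ||
          length(a@passiveDna))
        return("pairwise mode: one active base and no passive selections")
  }
  TRUE
})

#' @rdname AIRSet-class
#' @param airs,mode,label see slots.
#' @export
AIRSet <- function(airs = list(), mode = "pairwise", label = "") {
  new("AIRSet", airs = airs, mode = mode, label = label)
}

#' Fitted DNA helix axis
#'
#' @slot point centroid on the axis (Angstrom).
#' @slot direction unit vector along the axis, oriented 5' to 3' of strand 1.
#' @slot reference unit vector perpendicular to the axis; azimuth origin for
#'   projection views (projection of the first base-pair midpoint -> first
#'   strand-1 C1' vector).
#' @slot rmsResidual root-mean-square distance of the base-pair midpoints
#'   from the fitted line (Angstrom).
#' @export
setClass("HelixAxis",
         representation(point = "numeric", direction = "numeric",
                        reference = "numeric", rmsResidual = "numeric"))

setValidity("HelixAxis", function(object) {
  if (length(object@point) != 3L || length(object@direction) != 3L ||
      length(object@reference) != 3L)
    return("point, direction and reference must be 3-vectors")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    return("direction must be a unit vector")
  if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
  TRUE
})

#' @rdname HelixAxis-class
#' @param point,direction,reference,rmsResidual see slots.
#' @export
HelixAxis <- function(point, direction, reference = NULL, rmsResidual = 0) {
  direction <- direction / sqrt(sum(direction^2))
  if (is.null(reference)) reference <- perpUnit(direction)
  reference <- reference - sum(reference * direction) * direction
  reference <- reference / sqrt(sum(reference^2))
  new("HelixAxis", point = as.numeric(point),
      direction = as.numeric(direction), reference = as.numeric(reference),
      rmsResidual = as.numeric(rmsResidual))
}

## Any unit vector perpendicular to d.
perpUnit <- function(d) {
  v <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- v - sum(v * d) * d
  v / sqrt(sum(v^2))
}

#' 2-D projection of restraint residues about the DNA helix axis
#'
#' One point per restraint residue, as in the projection-view analysis used
#' to judge the geometric balance of a restraint set.
#'
#' @slot points data.frame with columns `azimuth` (degrees in \[0, 360)),
#'   `radius` (Angstrom), `domain`, `resno`.
#' @export
setClass("ProjectionView", representation(points = "data.frame"))

setValidity("ProjectionView", function(object) {
  p <- object@points
  need <- c("azimuth", "radius", "domain", "resno")
  if (!all(need %in% names(p)))
    return(paste("points needs columns:", paste(need, collapse = ", ")))
  if (nrow(p) && any(p$azimuth < 0 | p$azimuth >= 360))
    return("azimuth must lie in [0, 360)")
  TRUE
})

#' Geometric-balance report for a restraint set
#'
#' @slot perDomainCounts restraints per zinc finger.
#' @slot perDomainSpread circular spread (degrees) about each domain's
#'   circular-mean azimuth.
#' @slot balanced TRUE when counts are equal across domains and no residue
#'   strays from its domain cluster.
#' @slot oneSided TRUE when the whole set occupies a narrow azimuthal span
#'   (restraints on one side of the DNA only).
#' @slot offenders residue numbers outside their domain's main cluster.
#' @export
setClass("BalanceReport",
         representation(perDomainCounts = "integer",
                        perDomainSpread = "numeric",
                        balanced = "logical", oneSided = "logical",
                        offenders = "integer"))
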
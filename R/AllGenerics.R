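#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomData", function(x, ...) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("chainRoles", function(x) standardGeneric("chainRoles"))

#' @rdname accessors
#' @export
setGeneric("getChain", function(x, id) standardGeneric("getChain"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("airs", function(x) standardGeneric("airs"))

#' @rdname accessors
#' @export
setGeneric("airMode", function(x) standardGeneric("airMode"))

#' @rdname accessors
#' @export
setGeneric("airLabel", function(x) standardGeneric("airLabel"))

#' @rdname accessors
#' @export
setGeneric("helixPositions", function(x) standardGeneric("helixPositions"))

#' @rdname accessors
#' @export
setGeneric("domainSpan", function(x) standardGeneric("domainSpan"))

#' @rdname accessors
#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))

#' @rdname accessors
#' @export
setGeneric("axisPoint", function(x) standardGeneric("axisPoint"))

#' @rdname accessors
#' @export
setGeneric("projectionPoints", function(x) standardGeneric("projectionPoints"))

#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname accessors
setMethod("atomData", "ZFStructure", function(x, heavy = FALSE,
                                              noHet = FALSE) {
  a <- x@atoms
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  if (noHet) a <- a[!a$het, , drop = FALSE]
  a
})

#' @rdname accessors
setMethod("chainIds", "ZFStructure", function(x) names(x@chainRoles))

#' @rdname accessors
setMethod("chainRoles", "ZFStructure", function(x) x@chainRoles)

#' @rdname accessors
setMethod("getChain", "ZFStructure", function(x, id) {
  if (!id %in% names(x@chainRoles)) stop("no chain '", id, "'")
  ZFStructure(x@atoms[x@atoms$chain == id, , drop = FALSE],
              chainRoles = x@chainRoles[id], modelId = x@modelId,
              source = x@source)
})

#' @rdname accessors
setMethod("nAtoms", "ZFStructure", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("airs", "AIRSet", function(x) x@airs)

#' @rdname accessors
setMethod("airMode", "AIRSet", function(x) x@mode)

#' @rdname accessors
setMethod("airLabel", "AIRSet", function(x) x@label)

#' @rdname accessors
setMethod("helixPositions", "ZincFingerDomain", function(x) x@helixPositions)

#' @rdname accessors
setMethod("domainSpan", "ZincFingerDomain", function(x) x@span)

#' @rdname accessors
setMethod("axisDirection", "HelixAxis", function(x) x@direction)

#' @rdname accessors
setMethod("axisPoint", "HelixAxis", function(x) x@point)

#' @rdname accessors
setMethod("projectionPoints", "ProjectionView", function(x) x@points)

#' @rdname accessors
setMethod("isBalanced", "BalanceReport", function(x) x@balanced)

#' @describeIn accessors number of restraints in the set.
setMethod("length", "AIRSet", function(x) length(x@airs))

setMethod("show", "ZFStructure", function(object) {
  a <- object@atoms
  cat("ZFStructure (", object@source, ")\n", sep = "")
  for (id in names(object@chainRoles)) {
    sub <- a[a$chain == id, ]
    cat(sprintf("  chain %s [%s]: %d residues, %d atoms\n", id,
                object@chainRoles[[id]],
                length(unique(sub$resno)), nrow(sub)))
  }
})

setMethod("show", "ZincFingerDomain", function(object) {
  cat(sprintf(
    "ZincFingerDomain %d: span %d-%d, Zn ligands C%d/C%d/H%d/H%d, helix %d-%d\n",
    object@index, object@span[1], object@span[2],
    object@znLigands[1], object@znLigands[2], object@znLigands[3],
    object@znLigands[4], object@helixSpan[1], object@helixSpan[2]))
})

setMethod("show", "AIRSet", function(object) {
  cat(sprintf("AIRSet '%s' (%s): %d restraints\n", object@label,
              object@mode, length(object@airs)))
  if (length(object@airs)) {
    d <- vapply(object@airs, function(a) a@domainIndex, integer(1))
    cat("  per-domain counts:",
        paste(table(factor(d, levels = sort(unique(d)))), collapse = "/"),
        "\n")
  }
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf(
    "HelixAxis: direction (%.3f, %.3f, %.3f), rms residual %.3f A\n",
    object@direction[1], object@direction[2], object@direction[3],
    object@rmsResidual))
})

setMethod("show", "BalanceReport", function(object) {
  cat("BalanceReport: counts",
      paste(object@perDomainCounts, collapse = "/"),
      "| balanced:", object@balanced,
      "| one-sided:", object@oneSided, "\n")
  if (length(object@offenders))
    cat("  offenders (residues):",
        paste(object@offenders, collapse = ", "), "\n")
})
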
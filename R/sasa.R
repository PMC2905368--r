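## heavy-atom van der Waals radii (Angstrom) used for surface computation
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

## deterministic quasi-uniform points on the unit sphere (golden spiral)
sphericalPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley sphere sampling over heavy atoms: each atom's solvent
#' sphere (van der Waals radius + probe) is sampled at a fixed number of
#' deterministic quasi-uniform points; the accessible fraction is the share
#' of points not buried inside any neighbour's solvent sphere.  Hydrogens
#' and HETATM records (zinc ions) are excluded.  Deterministic for a fixed
#' configuration.
#'
#' @param s a [ZFStructure-class].
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param nPoints sample points per atom (default 960).
#' @param perAtom if TRUE return the per-atom area vector instead of the
#'   total.
#' @return total SASA in Angstrom^2 (or per-atom vector).
#' @export
sasa <- function(s, probe = 1.4, nPoints = 960L, perAtom = FALSE) {
  a <- atomData(s, heavy = TRUE, noHet = TRUE)
  unknown <- setdiff(unique(a$element), names(.VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- .VDW_RADII[a$element] + probe
  n <- nrow(xyz)
  pts <- sphericalPoints(nPoints)
  areas <- numeric(n)
  ## neighbour lists via one squared-distance pass (fixture-scale inputs)
  maxR <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (!length(nb)) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(surf[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj >= r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(free) / nPoints
  }
  if (perAtom) {
    names(areas) <- paste(a$chain, a$resno, a$name)
    attr(areas, "atoms") <- a[, c("chain", "resno", "name")]
    areas
  } else sum(areas)
}

## per-residue relative SASA: in-context SASA / isolated-residue SASA
relativeSASA <- function(s, chain, probe = 1.4, nPoints = 240L) {
  per <- sasa(s, probe = probe, nPoints = nPoints, perAtom = TRUE)
  meta <- attr(per, "atoms")
  keep <- meta$chain == chain
  ctx <- tapply(per[keep], meta$resno[keep], sum)
  a <- atomData(s, heavy = TRUE, noHet = TRUE)
  a <- a[a$chain == chain, , drop = FALSE]
  iso <- vapply(names(ctx), function(rn) {
    sub <- a[a$resno == as.integer(rn), , drop = FALSE]
    sasa(ZFStructure(sub, chainRoles = chainRoles(s)[chain]),
         probe = probe, nPoints = nPoints)
  }, numeric(1))
  rel <- as.numeric(ctx) / pmax(iso, 1e-9)
  names(rel) <- names(ctx)
  rel
}

#' Buried surface area of a protein-DNA complex
#'
#' `BSA = SASA(protein alone) + SASA(DNA alone) - SASA(complex)`: the
#' interface area hidden upon binding.  Zero for infinitely separated
#' chains, non-negative for any physical model.
#'
#' @param model complex [ZFStructure-class] with one protein and one DNA
#'   chain.
#' @param probe,nPoints see [sasa()].
#' @return BSA in Angstrom^2.
#' @export
bsa <- function(model, probe = 1.4, nPoints = 960L) {
  ch <- complexChains(model)
  sasa(getChain(model, ch$protein), probe, nPoints) +
    sasa(getChain(model, ch$dna), probe, nPoints) -
    sasa(model, probe, nPoints)
}
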
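#' Fit the DNA helix axis of a duplex
#'
#' Least-squares 3-D line through the base-pair midpoints (mean of the
#' paired C1' atoms), oriented 5' to 3' along strand 1.  The azimuth
#' reference vector stored with the axis is the perpendicular projection of
#' the vector from the first base-pair midpoint to the first strand-1 C1'.
#'
#' @param duplex merged-duplex DNA [ZFStructure-class] with >= 4 base pairs.
#' @return a [HelixAxis-class].
#' @export
fitHelixAxis <- function(duplex) {
  pairs <- basePairs(duplex)
  if (nrow(pairs) < 4) stop("need >= 4 base pairs to fit a helix axis")
  c1 <- c1pCoords(duplex)
  A <- c1[as.character(pairs$resnoA), , drop = FALSE]
  B <- c1[as.character(pairs$resnoB), , drop = FALSE]
  mids <- (A + B) / 2
  ctr <- colMeans(mids)
  d <- lineDirection(mids)
  if (sum((mids[nrow(mids), ] - mids[1, ]) * d) < 0) d <- -d
  resid <- sweep(mids, 2, ctr)
  perp <- resid - outer(as.numeric(resid %*% d), d)
  rms <- sqrt(mean(rowSums(perp^2)))
  ref <- A[1, ] - mids[1, ]
  ref <- ref - sum(ref * d) * d
  if (sqrt(sum(ref^2)) < 1e-8) ref <- perpUnit(d)
  HelixAxis(point = ctr, direction = d, reference = ref, rmsResidual = rms)
}

## cylindrical coordinates of points about an axis
cylindricalAbout <- function(xyz, axis) {
  xyz <- matrix(xyz, ncol = 3)
  d <- axis@direction
  ref <- axis@reference
  yref <- crossProd(d, ref)
  w <- sweep(xyz, 2, axis@point)
  wperp <- w - outer(as.numeric(w %*% d), d)
  radius <- sqrt(rowSums(wperp^2))
  az <- (atan2(as.numeric(wperp %*% yref),
               as.numeric(wperp %*% ref)) * 180 / pi) %% 360
  az[radius < 1e-9] <- 0  # on-axis points: azimuth 0 by convention
  data.frame(azimuth = az, radius = radius)
}

#' Project residues into the plane perpendicular to the helix axis
#'
#' Each residue is represented by its C-alpha atom (C1' for nucleotides)
#' projected onto the plane perpendicular to the axis; the azimuth is
#' measured about the axis from the stored reference vector.
#'
#' @param s a [ZFStructure-class] containing the residues.
#' @param axis a [HelixAxis-class].
#' @param resno residue numbers to project.
#' @param domain zinc-finger index per residue (recycled if length 1).
#' @param chain chain id; defaults to the (single) protein chain.
#' @return a [ProjectionView-class].
#' @export
projectResidues <- function(s, axis, resno, domain = NA_integer_,
                            chain = NULL) {
  roles <- chainRoles(s)
  if (is.null(chain)) {
    chain <- names(roles)[roles == "protein"]
    if (length(chain) != 1L) chain <- names(roles)[1]
  }
  anchor <- if (roles[[chain]] == "dna") "C1'" else "CA"
  a <- atomData(s, heavy = TRUE, noHet = TRUE)
  a <- a[a$chain == chain & a$name == anchor, , drop = FALSE]
  hit <- match(resno, a$resno)
  if (anyNA(hit))
    stop("residue ", resno[which(is.na(hit))[1]], " of chain ", chain,
         " has no ", anchor, " atom")
  cyl <- cylindricalAbout(as.matrix(a[hit, c("x", "y", "z")]), axis)
  domain <- rep_len(as.integer(domain), length(resno))
  new("ProjectionView",
      points = data.frame(azimuth = cyl$azimuth, radius = cyl$radius,
                          domain = domain, resno = as.integer(resno)))
}

#' Project the active residues of a restraint set
#'
#' Convenience wrapper: one projected point per restraint, using the
#' restraint's active protein residue, tagged with its domain index.
#'
#' @param set an [AIRSet-class].
#' @param protein protein [ZFStructure-class].
#' @param axis a [HelixAxis-class].
#' @return a [ProjectionView-class].
#' @export
projectAIRSet <- function(set, protein, axis) {
  if (!length(set)) stop("empty restraint set")
  resno <- vapply(airs(set), function(a) a@activeProtein, integer(1))
  dom <- vapply(airs(set), function(a) a@domainIndex, integer(1))
  projectResidues(protein, axis, resno, dom)
}

## circular helpers (degrees)
circDiffDeg <- function(a, b) ((a - b + 180) %% 360) - 180

circMeanDeg <- function(az) {
  r <- az * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

## span of occupied azimuth: 360 minus the largest empty circular gap
circSpanDeg <- function(az) {
  if (length(az) < 2) return(0)
  s <- sort(az %% 360)
  gaps <- diff(c(s, s[1] + 360))
  360 - max(gaps)
}

## occupied coverage after closing gaps smaller than gapTol
coverageDeg <- function(az, gapTol) {
  if (!length(az)) return(0)
  if (length(az) == 1L) return(0)
  s <- sort(az %% 360)
  gaps <- diff(c(s, s[1] + 360))
  360 - sum(gaps[gaps >= gapTol])
}

#' Balance-analysis configuration
#'
#' @param clusterHalfwidth maximum circular deviation (degrees) of a
#'   restraint residue from its domain's circular-mean azimuth before it is
#'   flagged as an offender (default 60).
#' @param minSpan minimum total azimuthal span (degrees) below which the set
#'   is flagged as sitting on one side of the DNA only (default 120).
#' @return a named list.
#' @export
balanceConfig <- function(clusterHalfwidth = 60, minSpan = 120) {
  stopifnot(clusterHalfwidth > 0, minSpan > 0)
  list(clusterHalfwidth = clusterHalfwidth, minSpan = minSpan)
}

#' Assess the geometric balance of a restraint set across domains
#'
#' A set is balanced when every domain carries the same number of restraints
#' and no projected residue strays from its domain's azimuthal cluster by
#' more than `clusterHalfwidth`.  An equivalent distribution of restraints
#' among the three fingers is what keeps rigid-body docking from biasing
#' the protein away from the wrap-around binding mode.
#'
#' @param set an [AIRSet-class].
#' @param view the matching [ProjectionView-class] (one point per restraint).
#' @param config a [balanceConfig()] list.
#' @return a [BalanceReport-class].
#' @export
assessDistribution <- function(set, view, config = balanceConfig()) {
  if (!length(set)) stop("empty restraint set")
  p <- projectionPoints(view)
  if (nrow(p) != length(set))
    stop("projection view must have one point per restraint")
  doms <- sort(unique(p$domain))
  counts <- vapply(doms, function(d) sum(p$domain == d), integer(1))
  spread <- numeric(length(doms))
  offenders <- integer()
  for (k in seq_along(doms)) {
    sub <- p[p$domain == doms[k], , drop = FALSE]
    mu <- circMeanDeg(sub$azimuth)
    dev <- abs(circDiffDeg(sub$azimuth, mu))
    spread[k] <- max(dev)
    offenders <- c(offenders,
                   sub$resno[dev > config$clusterHalfwidth])
  }
  oneSided <- circSpanDeg(p$azimuth) < config$minSpan
  balanced <- length(unique(counts)) == 1L && length(offenders) == 0L &&
    !oneSided
  new("BalanceReport", perDomainCounts = counts,
      perDomainSpread = spread, balanced = balanced,
      oneSided = oneSided, offenders = sort(unique(offenders)))
}
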
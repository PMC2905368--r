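#' Read a PDB file into a ZFStructure
#'
#' Parses ATOM and HETATM records (model 1 of multi-model files) into the
#' package's structure hierarchy.  Alternate locations are collapsed to the
#' highest-occupancy conformer (ties keep the first encountered).  HETATM
#' records such as zinc ions are retained as single-atom residues but are
#' excluded from every metric downstream.
#'
#' @param path path to a PDB-format file.
#' @return A [ZFStructure-class].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("no ATOM records in '", path, "'")
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = a$elety,
    resname = a$resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                     guessElement(a$elety), toupper(a$elesy)),
    het = a$type == "HETATM",
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  atoms <- collapseAltloc(atoms)
  atoms$occ <- NULL
  atoms$alt <- NULL
  ZFStructure(atoms, modelId = 1L, source = path)
}

## Keep the highest-occupancy alternate location per (chain, resno, name);
## ties keep the first conformer encountered in file order.
collapseAltloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$occ[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a ZFStructure to a PDB file
#'
#' Emits standard fixed-width ATOM/HETATM records with the structure's
#' 1-based residue numbering preserved, a TER record after each chain and a
#' terminal END.  Output is byte-stable for a fixed input.
#'
#' @param s a [ZFStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(s, path) {
  stopifnot(is(s, "ZFStructure"))
  a <- atomData(s)
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  serial <- 0L
  for (id in chainIds(s)) {
    sub <- a[a$chain == id, , drop = FALSE]
    if (nrow(sub) == 0L) stop("chain '", id, "' has no atoms")
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      rec <- if (sub$het[i]) "HETATM" else "ATOM  "
      nm <- sub$name[i]
      nm <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else
        sprintf(" %-3s", nm)
      writeLines(sprintf(
        "%s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, nm, sub$resname[i], id, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], 1, 0, sub$element[i]), con)
    }
    writeLines(sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                       sub$resname[nrow(sub)], id, sub$resno[nrow(sub)]),
               con)
    serial <- serial + 1L
  }
  writeLines("END", con)
  invisible(path)
}
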
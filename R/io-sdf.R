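# Ligand-pose I/O: SDF V2000 (read/write, via ChemmineR) and MOL2 (read, via
# bio3d). Pose identifiers are taken from the POSE_ID property when present,
# else from the record title; duplicates are auto-suffixed.

#' Read docking poses from an SDF or MOL2 file
#'
#' @param path input file.
#' @param format "sdf" or "mol2".
#' @param compoundId compound label to stamp on every pose (default "").
#' @param source provenance tag stored on each pose.
#' @return list of \linkS4class{LigandPose} objects, input order preserved.
#' @details SDF records must be 3D: a record whose coordinates are all zero
#'   in z (a flat, 2D-style block) is rejected with its record index. MOL2
#'   partial charges are kept when present; otherwise charges are assigned by
#'   \code{\link{assignCharges}}.
#' @export
readPoses <- function(path, format = c("sdf", "mol2"), compoundId = "",
                      source = "docking") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sdf") {
    sdfs <- ChemmineR::read.SDFset(path)
    if (!length(sdfs)) stop("no records in SDF file ", path)
    poses <- vector("list", length(sdfs))
    ids <- character(length(sdfs))
    for (k in seq_along(sdfs)) {
      sdf <- sdfs[[k]]
      mol <- sdfToMolecule(sdf, k)
      db <- ChemmineR::datablock(sdf)
      id <- if ("POSE_ID" %in% names(db)) unname(db[["POSE_ID"]]) else
        trimws(ChemmineR::sdfid(sdfs[k]))
      if (!nzchar(id)) id <- paste0("p", k)
      ids[k] <- id
      cid <- if ("COMPOUND_ID" %in% names(db)) unname(db[["COMPOUND_ID"]]) else
        compoundId
      poses[[k]] <- newLigandPose(id, mol, compoundId = cid, source = source)
    }
  } else {
    mol2 <- bio3d::read.mol2(path)
    if (is.data.frame(mol2$atom)) mol2 <- list(mol2)
    if (!length(mol2)) stop("no records in MOL2 file ", path)
    poses <- vector("list", length(mol2))
    ids <- character(length(mol2))
    for (k in seq_along(mol2)) {
      m <- mol2[[k]]
      at <- m$atom
      if (!nrow(at)) stop("record ", k, " has no atoms")
      element <- normalizeElement(sub("\\..*$", "", at$elena))
      # SYBYL atom types carry the element before the dot; some files put the
      # element in elena directly
      bad <- !(element %in% SUPPORTED_ELEMENTS)
      if (any(bad)) element[bad] <- elementFromAtomName(at$elena[bad])
      xyz <- cbind(at$x, at$y, at$z)
      if (any(!is.finite(xyz))) stop("missing coordinates in record ", k)
      bnd <- m$bond
      bonds <- data.frame(i = as.integer(bnd$origin), j = as.integer(bnd$target),
                          order = suppressWarnings(as.integer(bnd$type)))
      bonds$order[is.na(bonds$order)] <- 1L  # ar/am types
      charge <- at$charge
      if (all(!is.finite(charge)) || all(charge == 0)) charge <- NULL
      mol <- newMolecule(if (!is.null(m$name)) m$name else paste0("mol", k),
                         xyz, element, bonds, charge = charge)
      id <- if (!is.null(m$name) && nzchar(m$name)) m$name else paste0("p", k)
      ids[k] <- id
      poses[[k]] <- newLigandPose(id, mol, compoundId = compoundId, source = source)
    }
  }
  # uniquify pose ids, preserving order
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
    for (k in seq_along(poses)) poses[[k]]@poseId <- ids[k]
  }
  poses
}

sdfToMolecule <- function(sdf, recIndex) {
  ab <- ChemmineR::atomblock(sdf)
  if (!nrow(ab)) stop("record ", recIndex, " has no atoms")
  xyz <- ab[, 1:3, drop = FALSE]
  if (any(!is.finite(xyz))) stop("missing coordinates in record ", recIndex)
  if (nrow(xyz) > 1L && all(xyz[, 3L] == 0)) {
    stop("record ", recIndex, " looks 2D (all z coordinates are zero)")
  }
  element <- normalizeElement(sub("_.*$", "", rownames(ab)))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (nrow(bb)) {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  } else data.frame(i = integer(), j = integer(), order = integer())
  title <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
  newMolecule(if (nzchar(title)) title else paste0("mol", recIndex),
              xyz, element, bonds)
}

#' Write ligand poses to an SDF V2000 file
#'
#' The pose id is written both as the record title and as a
#' \code{POSE_ID} property; the compound id as \code{COMPOUND_ID}.
#'
#' @param poses list of \linkS4class{LigandPose}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePoses <- function(poses, path) {
  if (inherits(poses, "LigandPose")) poses <- list(poses)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    mol <- p@molecule
    at <- mol@atoms
    b <- mol@bonds
    writeLines(c(p@poseId, "  PoseSAR", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    if (nrow(b)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order), con)
    }
    writeLines("M  END", con)
    writeLines(c("> <POSE_ID>", p@poseId, ""), con)
    if (nzchar(p@compoundId)) {
      writeLines(c("> <COMPOUND_ID>", p@compoundId, ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
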
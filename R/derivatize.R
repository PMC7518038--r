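# Post-docking derivatization: building 3D analog poses of a congeneric
# series on the coordinates of a reference docking pose. A substituent is
# placed by (1) deleting the branch currently attached at the position,
# (2) positioning the fragment link atom along the former bond vector at the
# standard bond length for the element pair, (3) aligning the fragment's
# open-valence direction, and (4) scanning the dihedral about the new bond
# for the minimum steric-clash score against receptor + remaining ligand.
# The construction is fully deterministic: fixed torsion grid, ties broken
# by the smallest angle, core coordinates bitwise unchanged.

# Open-valence direction of a substituent fragment: the ideal
# missing-valence direction at the link atom given its existing neighbors
# and hybridization (a cone position for singly-bonded sp3 links; the roll
# ambiguity about the new bond is exactly what the torsion scan explores).
fragmentOpenDirection <- function(sub) {
  frag <- sub@fragment
  n <- nrow(frag@atoms)
  adj <- adjacencyList(frag@bonds, n)
  nb <- adj[[sub@linkAtom]]
  if (!length(nb)) return(c(1, 0, 0))
  xyz <- coords(frag)
  dirs <- lapply(nb, function(j) unitVec(xyz[j, ] - xyz[sub@linkAtom, ]))
  hyb <- hybridization(frag@atoms$element, frag@bonds, n)[sub@linkAtom]
  unitVec(idealHDirections(dirs, hyb, 1L)[[1L]])
}

# Attachment bond length for a core (aromatic C) -- link-atom bond.
attachmentLength <- function(sub) {
  tab <- attachmentBondLengths()
  el <- sub@fragment@atoms$element[sub@linkAtom]
  if (el == "C") {
    hyb <- hybridization(sub@fragment@atoms$element, sub@fragment@bonds,
                         nrow(sub@fragment@atoms))[sub@linkAtom]
    key <- if (hyb == "sp") "C.sp" else "C.sp3"
  } else key <- el
  if (!(key %in% names(tab))) {
    stop("no attachment bond length tabulated for link element ", el)
  }
  unname(tab[[key]])
}

#' Place one substituent on a posed scaffold
#'
#' @param pose a \linkS4class{LigandPose} carrying the reference molecule.
#' @param attachment one row of a scaffold map's attachment table (list or
#'   single-row data.frame with core_atom and replaced_hydrogen).
#' @param substituent a \linkS4class{Substituent}.
#' @param receptor the \linkS4class{Receptor} used for the clash scan.
#' @param torsionSteps number of evenly spaced dihedral angles scanned
#'   (default 12).
#' @param clashCeiling per-placement hard ceiling on the minimum clash score;
#'   a placement above it is flagged via the \code{"clash_flag"} attribute,
#'   never silently dropped.
#' @return the derivatized \linkS4class{Molecule}, with attribute
#'   \code{"index_map"} (old index -> new index for all retained atoms, NA
#'   for deleted ones) and \code{"clash_flag"}.
#' @export
placeSubstituent <- function(pose, attachment, substituent, receptor,
                             torsionSteps = 12L, clashCeiling = 1e3) {
  stopifnot(torsionSteps >= 1L)
  mol <- if (inherits(pose, "LigandPose")) pose@molecule else pose
  core <- attachment$core_atom
  repl <- attachment$replaced_hydrogen
  at <- mol@atoms
  n <- nrow(at)
  if (repl < 1L || repl > n) stop("replaced atom index out of range")
  adj <- adjacencyList(mol@bonds, n)
  if (!(core %in% adj[[repl]])) {
    stop("replaced atom ", repl, " is not bonded to core atom ", core)
  }
  branch <- branchAtoms(adj, repl, blocked = core)
  branchIsH <- length(branch) == 1L && at$element[repl] == "H"
  if (substituent@label == "H") {
    if (any(substituent@fragment@atoms$element != "H")) {
      stop("substituent labelled H has a non-hydrogen fragment")
    }
    if (branchIsH) {
      out <- mol  # identity: already a bare hydrogen at this position
      im <- seq_len(n)
      attr(out, "index_map") <- im
      attr(out, "clash_flag") <- FALSE
      return(out)
    }
  }
  u <- unitVec(c(at$x[repl], at$y[repl], at$z[repl]) -
               c(at$x[core], at$y[core], at$z[core]))
  pcore <- c(at$x[core], at$y[core], at$z[core])
  # fragment geometry: translate link atom onto the target position, align
  # its open-valence direction onto -u (so the open valence points at core)
  frag <- substituent@fragment
  fxyz <- coords(frag)
  link <- substituent@linkAtom
  blen <- attachmentLength(substituent)
  target <- pcore + blen * u
  open <- fragmentOpenDirection(substituent)
  R <- alignRotation(open, -u)
  fxyz <- sweep(fxyz, 2L, fxyz[link, ]) %*% t(R)
  fxyz <- sweep(fxyz, 2L, target, "+")
  # torsion scan about the core-link axis (only meaningful for >1 atom)
  clashFlag <- FALSE
  if (nrow(fxyz) > 1L && torsionSteps > 1L) {
    keepLig <- setdiff(seq_len(n), c(branch, core))
    env <- rbind(coords(receptor),
                 as.matrix(at[keepLig, c("x", "y", "z"), drop = FALSE]))
    envVdw <- c(receptor@atoms$vdw, at$vdw[keepLig])
    # pre-filter environment atoms within 10 A of the attachment point
    d2 <- colSums((t(env) - target)^2)
    sel <- d2 <= 100
    env <- env[sel, , drop = FALSE]
    envVdw <- envVdw[sel]
    scanIdx <- setdiff(seq_len(nrow(fxyz)), link)
    angles <- 2 * pi * (seq_len(torsionSteps) - 1L) / torsionSteps
    if (nrow(env)) {
      scores <- clash_scan_cpp(fxyz[scanIdx, , drop = FALSE],
                               frag@atoms$vdw[scanIdx],
                               env, envVdw, target, u, angles, 1e4)
      best <- which.min(scores)  # which.min takes the first (smallest angle)
      clashFlag <- scores[best] >= clashCeiling
      Rt <- rotationMatrix(u, angles[best])
      fxyz[scanIdx, ] <- sweep(sweep(fxyz[scanIdx, , drop = FALSE], 2L, target) %*%
                                 t(Rt), 2L, target, "+")
    }
  }
  # assemble: retained ligand atoms (branch deleted) + fragment atoms
  keep <- setdiff(seq_len(n), branch)
  im <- rep(NA_integer_, n)
  im[keep] <- seq_along(keep)
  newAtoms <- at[keep, , drop = FALSE]
  fragAtoms <- frag@atoms
  fragAtoms$x <- fxyz[, 1L]; fragAtoms$y <- fxyz[, 2L]; fragAtoms$z <- fxyz[, 3L]
  newAtoms <- rbind(newAtoms, fragAtoms)
  rownames(newAtoms) <- NULL
  fragOff <- length(keep)
  b <- mol@bonds
  keepBond <- !(b$i %in% branch) & !(b$j %in% branch)
  newBonds <- b[keepBond, , drop = FALSE]
  newBonds$i <- im[newBonds$i]; newBonds$j <- im[newBonds$j]
  fb <- frag@bonds
  if (nrow(fb)) {
    fb$i <- fb$i + fragOff; fb$j <- fb$j + fragOff
    newBonds <- rbind(newBonds, fb)
  }
  newBonds <- rbind(newBonds,
                    data.frame(i = im[core], j = link + fragOff, order = 1L))
  rownames(newBonds) <- NULL
  out <- methods::new("Molecule", name = mol@name, atoms = newAtoms,
                      bonds = newBonds)
  attr(out, "index_map") <- im
  attr(out, "clash_flag") <- clashFlag
  out
}

#' Expand one reference pose into the full analog series
#'
#' For every non-reference compound in the table, replaces the branch at each
#' attachment position of the scaffold map with the compound's substituent,
#' producing one derived pose per analog (pose_id
#' \code{"<reference>:<compound>"}). The reference pose itself is passed
#' through unchanged. Core atom coordinates are bitwise invariant.
#'
#' @param pose reference \linkS4class{LigandPose}.
#' @param scaffold a \linkS4class{ScaffoldMap} on the reference molecule.
#' @param records compound table; the pose's \code{compoundId} (or
#'   \code{referenceId}) marks the reference row.
#' @param library named list of \linkS4class{Substituent} objects.
#' @param receptor \linkS4class{Receptor} for the clash scans.
#' @param torsionSteps dihedral grid size per placement.
#' @param referenceId reference compound id (default: the pose's).
#' @return list of \linkS4class{LigandPose} (reference first, analogs in
#'   table order); each derived pose's \code{meta$core_atoms} maps the
#'   scaffold core into the derived molecule.
#' @export
expandPose <- function(pose, scaffold, records, library, receptor,
                       torsionSteps = 12L, referenceId = NULL) {
  if (is.null(referenceId) || !nzchar(referenceId)) referenceId <- pose@compoundId
  labs <- unique(unlist(records[, c("R6", "R7", "R8", "R3p", "R4p")]))
  unknown <- setdiff(labs, names(library))
  if (length(unknown)) {
    stop("substituent label(s) not in library: ", paste(unknown, collapse = ", "))
  }
  att <- scaffold@attachments
  refPose <- pose
  refPose@meta$core_atoms <- scaffold@coreAtoms
  out <- list(refPose)
  analogs <- records[as.character(records$compound_id) != as.character(referenceId), ,
                     drop = FALSE]
  for (r in seq_len(nrow(analogs))) {
    rec <- analogs[r, ]
    mol <- pose@molecule
    curAtt <- att
    flagged <- FALSE
    coreIdx <- scaffold@coreAtoms
    for (ai in seq_len(nrow(curAtt))) {
      pos <- curAtt$position[ai]
      lab <- rec[[pos]]
      mol2 <- placeSubstituent(pose = mol,
                               attachment = curAtt[ai, ],
                               substituent = library[[lab]],
                               receptor = receptor,
                               torsionSteps = torsionSteps)
      flagged <- flagged || isTRUE(attr(mol2, "clash_flag"))
      im <- attr(mol2, "index_map")
      coreIdx <- im[coreIdx]
      # remap the core atoms and the not-yet-processed attachment rows
      # through the index map (they are retained atoms, never in the branch)
      curAtt$core_atom <- im[curAtt$core_atom]
      later <- seq_len(nrow(curAtt)) > ai
      curAtt$replaced_hydrogen[later] <- im[curAtt$replaced_hydrogen[later]]
      mol <- mol2
    }
    mol@name <- paste0(rec$name)
    dp <- newLigandPose(paste0(pose@poseId, ":", rec$compound_id), mol,
                        compoundId = rec$compound_id,
                        source = "derivatization",
                        meta = list(core_atoms = coreIdx,
                                    clash_flag = flagged))
    out[[length(out) + 1L]] <- dp
  }
  out
}
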
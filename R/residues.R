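# Amino-acid construction from internal-coordinate templates. Used by the
# synthetic pocket generator (pseudo-residues are real amino acids so that
# interaction detection and mutation work unmodified) and by the mutation
# operator. Geometry uses standard bond lengths and ideal angles; hydrogens
# are completed algorithmically.

# Each template: heavy atoms beyond the backbone as z-matrix rows
# (name, element, refs a/b/c by name, r (A), theta, phi (degrees)), bonds by
# name with order, and names of atoms that must not receive hydrogens
# (e.g. a carboxylate oxygen).
.residue_templates <- list(
  GLY = list(atoms = NULL, bonds = NULL, noH = character()),
  ALA = list(
    atoms = data.frame(
      name = "CB", element = "C", a = "C", b = "N", c = "CA",
      r = 1.53, theta = 110.5, phi = -122, stringsAsFactors = FALSE),
    bonds = data.frame(from = "CA", to = "CB", order = 1L),
    noH = character()),
  GLN = list(
    atoms = data.frame(
      name = c("CB", "CG", "CD", "OE1", "NE2"),
      element = c("C", "C", "C", "O", "N"),
      a = c("C", "N", "CA", "CB", "CB"),
      b = c("N", "CA", "CB", "CG", "CG"),
      c = c("CA", "CB", "CG", "CD", "CD"),
      r = c(1.53, 1.52, 1.52, 1.23, 1.33),
      theta = c(110.5, 114, 112, 121, 116),
      phi = c(-122, 180, 180, 0, 180), stringsAsFactors = FALSE),
    bonds = data.frame(from = c("CA", "CB", "CG", "CD", "CD"),
                       to = c("CB", "CG", "CD", "OE1", "NE2"),
                       order = c(1L, 1L, 1L, 2L, 1L)),
    noH = character()),
  ASP = list(
    atoms = data.frame(
      name = c("CB", "CG", "OD1", "OD2"),
      element = c("C", "C", "O", "O"),
      a = c("C", "N", "CA", "CA"),
      b = c("N", "CA", "CB", "CB"),
      c = c("CA", "CB", "CG", "CG"),
      r = c(1.53, 1.52, 1.25, 1.25),
      theta = c(110.5, 114, 118, 118),
      phi = c(-122, 180, 0, 180), stringsAsFactors = FALSE),
    bonds = data.frame(from = c("CA", "CB", "CG", "CG"),
                       to = c("CB", "CG", "OD1", "OD2"),
                       order = c(1L, 1L, 2L, 1L)),
    noH = "OD2"),  # carboxylate stays deprotonated
  LEU = list(
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2"),
      element = c("C", "C", "C", "C"),
      a = c("C", "N", "CA", "CA"),
      b = c("N", "CA", "CB", "CB"),
      c = c("CA", "CB", "CG", "CG"),
      r = c(1.53, 1.53, 1.53, 1.53),
      theta = c(110.5, 116, 110, 110),
      phi = c(-122, 180, 180, 60), stringsAsFactors = FALSE),
    bonds = data.frame(from = c("CA", "CB", "CG", "CG"),
                       to = c("CB", "CG", "CD1", "CD2"),
                       order = c(1L, 1L, 1L, 1L)),
    noH = character()),
  PHE = list(
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      element = rep("C", 7L),
      a = c("C", "N", "CA", "CA", "CB", "CB", "CG"),
      b = c("N", "CA", "CB", "CB", "CG", "CG", "CD1"),
      c = c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1"),
      r = c(1.53, 1.51, 1.39, 1.39, 1.39, 1.39, 1.39),
      theta = c(110.5, 114, 120, 120, 120, 120, 120),
      phi = c(-122, 180, 90, -90, 180, 180, 0), stringsAsFactors = FALSE),
    bonds = data.frame(
      from = c("CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      to = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG"),
      order = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)),
    noH = character()),
  TYR = list(
    atoms = data.frame(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      element = c(rep("C", 7L), "O"),
      a = c("C", "N", "CA", "CA", "CB", "CB", "CG", "CD1"),
      b = c("N", "CA", "CB", "CB", "CG", "CG", "CD1", "CE1"),
      c = c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1", "CZ"),
      r = c(1.53, 1.51, 1.39, 1.39, 1.39, 1.39, 1.39, 1.36),
      theta = c(110.5, 114, 120, 120, 120, 120, 120, 120),
      phi = c(-122, 180, 90, -90, 180, 180, 0, 180), stringsAsFactors = FALSE),
    bonds = data.frame(
      from = c("CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CZ"),
      to = c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG", "OH"),
      order = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L)),
    noH = character())
)

# Ring atom names per aromatic residue (used by interaction detection).
.residue_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

# Formally charged side-chain atoms (for salt-bridge detection).
.residue_charged <- list(
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1),
  LYS = list(atoms = "NZ", sign = +1),
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = +1)
)

# Build one residue at the origin: N at (0,0,0), CA along +x, C in the xy
# plane. Returns xyz, element, atom names and bonds (1-based by index).
buildResidue <- function(resname) {
  tpl <- .residue_templates[[resname]]
  if (is.null(tpl)) stop("no template for residue ", resname)
  names0 <- c("N", "CA", "C", "O")
  element <- c("N", "C", "C", "O")
  pN <- c(0, 0, 0)
  pCA <- c(1.458, 0, 0)
  thNCAC <- 111 * pi / 180
  pC <- pCA + 1.525 * c(-cos(thNCAC), sin(thNCAC), 0)
  xyz <- rbind(pN, pCA, pC)
  xyz <- rbind(xyz, placeAtomZ(pN, pCA, pC, 1.23, 120.5, 0))  # O
  bonds <- data.frame(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L),
                      order = c(1L, 1L, 2L))
  if (!is.null(tpl$atoms)) {
    for (r in seq_len(nrow(tpl$atoms))) {
      row <- tpl$atoms[r, ]
      ia <- match(row$a, names0); ib <- match(row$b, names0)
      ic <- match(row$c, names0)
      xyz <- rbind(xyz, placeAtomZ(xyz[ia, ], xyz[ib, ], xyz[ic, ],
                                   row$r, row$theta, row$phi))
      names0 <- c(names0, row$name)
      element <- c(element, row$element)
    }
    bonds <- rbind(bonds, data.frame(
      i = match(tpl$bonds$from, names0),
      j = match(tpl$bonds$to, names0),
      order = tpl$bonds$order))
  }
  rownames(xyz) <- NULL
  # hydrogens everywhere except explicitly excluded atoms
  exclude <- match(tpl$noH, names0)
  only <- setdiff(seq_along(element), exclude)
  comp <- completeHydrogens(xyz, element, bonds, only = only)
  nNew <- length(comp$parent)
  if (nNew) {
    hn <- character(nNew)
    cnt <- list()
    for (k in seq_len(nNew)) {
      pn <- names0[comp$parent[k]]
      stem <- if (pn == "N") "H" else if (pn == "CA") "HA" else
        paste0("H", substring(pn, 2L))
      cnt[[stem]] <- (if (is.null(cnt[[stem]])) 0L else cnt[[stem]]) + 1L
      hn[k] <- paste0(stem, cnt[[stem]])
    }
    names0 <- c(names0, hn)
  }
  list(xyz = comp$xyz, element = comp$element, names = names0,
       bonds = comp$bonds)
}

# Rigid-place a built residue: the anchor atom lands on `target`, the
# anchor-from-CA direction aligns with `inward`, and (optionally) the body
# is rolled about the inward axis so that either the plane normal of
# `ringAtoms` matches `ringNormal`, or `pointAtom` comes as close as
# possible to `pointTarget`.
placeResidue <- function(res, anchor, target, inward, ringAtoms = NULL,
                         ringNormal = NULL, pointAtom = NULL,
                         pointTarget = NULL, awayAtom = NULL,
                         awayFrom = NULL) {
  ia <- match(anchor, res$names)
  ica <- match("CA", res$names)
  v <- res$xyz[ia, ] - res$xyz[ica, ]
  R1 <- alignRotation(v, inward)
  xyz <- res$xyz %*% t(R1)
  xyz <- sweep(xyz, 2L, target - xyz[ia, ], "+")
  axis <- unitVec(inward)
  rollTo <- function(cur, want) {
    # rotate about the axis line through `target` taking direction `cur`
    # (projected off-axis) onto `want`
    pn <- cur - sum(cur * axis) * axis
    pt <- want - sum(want * axis) * axis
    if (vecNorm(pn) < 1e-6 || vecNorm(pt) < 1e-6) return(xyz)
    pn <- unitVec(pn); pt <- unitVec(pt)
    ang <- atan2(sum(crossProd(pn, pt) * axis), sum(pn * pt))
    sweep(sweep(xyz, 2L, target) %*% t(rotationMatrix(axis, ang)), 2L,
          target, "+")
  }
  if (!is.null(ringAtoms) && !is.null(ringNormal)) {
    idx <- match(ringAtoms, res$names)
    xyz <- rollTo(planeNormal(xyz[idx, , drop = FALSE]), ringNormal)
    if (!is.null(awayAtom) && !is.null(awayFrom)) {
      # the ring-normal constraint leaves a 180-degree flip free; take the
      # solution that keeps `awayAtom` farther from `awayFrom`
      ib <- match(awayAtom, res$names)
      flipped <- sweep(sweep(xyz, 2L, target) %*%
                         t(rotationMatrix(axis, pi)), 2L, target, "+")
      if (vecNorm(flipped[ib, ] - awayFrom) > vecNorm(xyz[ib, ] - awayFrom)) {
        xyz <- flipped
      }
    }
  } else if (!is.null(pointAtom) && !is.null(pointTarget)) {
    ip <- match(pointAtom, res$names)
    xyz <- rollTo(xyz[ip, ] - target, pointTarget - target)
  }
  res$xyz <- xyz
  res
}

# Convert built residues to a Receptor atom table.
residuesToReceptor <- function(resList, chain, subunitLabels = character()) {
  rows <- list()
  for (k in seq_along(resList)) {
    res <- resList[[k]]
    xyz <- res$xyz
    q <- assignCharges(xyz, res$element, res$bonds)
    rows[[k]] <- data.frame(
      chain = chain[k], resno = k, insert = "", reskey = as.character(k),
      resid = res$resname, elety = res$names, element = res$element,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1.0, charge = q,
      vdw = elementProperty(res$element, "vdw"),
      is_hydrogen = res$element == "H", stringsAsFactors = FALSE
    )
  }
  methods::new("Receptor", atoms = do.call(rbind, rows),
               subunitLabels = subunitLabels)
}
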
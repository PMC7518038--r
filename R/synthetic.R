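# Synthetic fixture generator: a small rigid pocket built from real
# amino-acid pseudo-residues (H-bond donor, acidic, aromatic, aliphatic
# roles), a planar fused-ring scaffold with five attachment positions, decoy
# pose ensembles around a planted true pose, and activities linear in the
# true-pose binding energy with Gaussian noise. Everything is deterministic
# under the spec seed, so the full protocol is testable without downloads.

#' Synthetic study specification
#'
#' @param seed integer RNG seed.
#' @param nPoses number of poses in the ensemble (planted + decoys).
#' @param nAnalogs number of analog compounds beside the reference.
#' @param noiseSd Gaussian noise on generated activities, log units.
#' @param slope log units per kcal/mol linking activity to true-pose binding
#'   energy; must be negative (lower energy, higher potency).
#' @param pocketSize number of pocket pseudo-residues (10-30).
#' @param decoySpread translation scale of decoy perturbations, Angstrom.
#' @return a list with class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(seed = 1L, nPoses = 20L, nAnalogs = 8L,
                          noiseSd = 0.2, slope = -0.2, pocketSize = 12L,
                          decoySpread = 2.0) {
  stopifnot(noiseSd >= 0, slope < 0, nPoses >= 2L,
            pocketSize >= 10L, pocketSize <= 30L)
  structure(list(seed = as.integer(seed), nPoses = as.integer(nPoses),
                 nAnalogs = as.integer(nAnalogs), noiseSd = noiseSd,
                 slope = slope, pocketSize = as.integer(pocketSize),
                 decoySpread = decoySpread),
            class = "SyntheticSpec")
}

# Run expr under a private RNG stream, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(expr)
}

# n unit directions at `angleDeg` from uOpen, spaced equally around it.
tripodDirections <- function(uOpen, angleDeg = 109.47, n = 3L) {
  u <- unitVec(uOpen)
  perp <- pickPerpendicular(u)
  first <- as.numeric(rotationMatrix(perp, angleDeg * pi / 180) %*% u)
  lapply(seq_len(n) - 1L, function(k) {
    as.numeric(rotationMatrix(u, 2 * pi * k / max(1L, n)) %*% first)
  })
}

# Build one substituent fragment with the link atom first and the open
# valence along -x.
buildFragment <- function(label) {
  uOpen <- c(-1, 0, 0)
  back <- -uOpen  # direction from link atom toward its substituents
  mk <- function(xyz, element, bonds) {
    mol <- newMolecule(label, xyz, element, bonds)
    methods::new("Substituent", label = label, fragment = mol, linkAtom = 1L)
  }
  if (label == "H") {
    return(mk(rbind(c(0, 0, 0)), "H",
              data.frame(i = integer(), j = integer(), order = integer())))
  }
  if (label %in% c("F", "Cl", "Br")) {
    return(mk(rbind(c(0, 0, 0)), label,
              data.frame(i = integer(), j = integer(), order = integer())))
  }
  if (label == "Me") {
    d <- tripodDirections(back, 109.47, 3L)
    xyz <- rbind(c(0, 0, 0), t(vapply(d, function(v) 1.09 * v, numeric(3L))))
    return(mk(xyz, c("C", "H", "H", "H"),
              data.frame(i = 1L, j = 2:4, order = 1L)))
  }
  if (label == "NH2") {
    d <- tripodDirections(back, 107, 2L)
    xyz <- rbind(c(0, 0, 0), t(vapply(d, function(v) 1.01 * v, numeric(3L))))
    return(mk(xyz, c("N", "H", "H"), data.frame(i = 1L, j = 2:3, order = 1L)))
  }
  if (label == "CN") {
    return(mk(rbind(c(0, 0, 0), 1.16 * back), c("C", "N"),
              data.frame(i = 1L, j = 2L, order = 3L)))
  }
  if (label == "CCH") {
    return(mk(rbind(c(0, 0, 0), 1.20 * back, (1.20 + 1.06) * back),
              c("C", "C", "H"),
              data.frame(i = c(1L, 2L), j = c(2L, 3L), order = c(3L, 1L))))
  }
  if (label == "OMe") {
    dC <- tripodDirections(back, 111, 1L)[[1L]]
    pC <- 1.43 * dC
    xyz <- rbind(c(0, 0, 0), pC)
    el <- c("O", "C")
    bonds <- data.frame(i = 1L, j = 2L, order = 1L)
    comp <- completeHydrogens(xyz, el, bonds, only = 2L)
    return(mk(comp$xyz, comp$element, comp$bonds))
  }
  if (label == "tBu") {
    d <- tripodDirections(back, 109.47, 3L)
    xyz <- rbind(c(0, 0, 0), t(vapply(d, function(v) 1.53 * v, numeric(3L))))
    el <- c("C", "C", "C", "C")
    bonds <- data.frame(i = 1L, j = 2:4, order = 1L)
    comp <- completeHydrogens(xyz, el, bonds, only = 2:4)
    return(mk(comp$xyz, comp$element, comp$bonds))
  }
  if (label == "COOEt") {
    ang <- function(deg) c(cos((180 - deg) * pi / 180),
                           sin((180 - deg) * pi / 180), 0)
    pC <- c(0, 0, 0)
    pO1 <- 1.23 * ang(121)                        # carbonyl O
    pO2 <- 1.34 * c(ang(111)[1L], -ang(111)[2L], 0)  # ester O
    pC1 <- placeAtomZ(pO1, pC, pO2, 1.45, 115, 180)  # CH2
    pC2 <- placeAtomZ(pC, pO2, pC1, 1.52, 110, 180)  # CH3
    xyz <- rbind(pC, pO1, pO2, pC1, pC2)
    el <- c("C", "O", "O", "C", "C")
    bonds <- data.frame(i = c(1L, 1L, 3L, 4L), j = c(2L, 3L, 4L, 5L),
                        order = c(2L, 1L, 1L, 1L))
    comp <- completeHydrogens(xyz, el, bonds, only = 4:5)
    return(mk(comp$xyz, comp$element, comp$bonds))
  }
  stop("no fragment constructor for label ", label)
}

#' Built-in substituent fragment library
#'
#' Ideal-geometry 3D fragments for the canonical R-group labels (H, Me, OMe,
#' Cl, Br, F, tBu, CCH, CN, COOEt, NH2), each with the link atom first and
#' one open valence.
#'
#' @return named list of \linkS4class{Substituent} objects.
#' @export
substituentLibrary <- function() {
  labels <- c("H", "Me", "OMe", "Cl", "Br", "F", "tBu", "CCH", "CN",
              "COOEt", "NH2")
  out <- lapply(labels, buildFragment)
  names(out) <- labels
  out
}

# Planar fused-bicyclic scaffold (quinolinone-like): ten ring atoms (one
# ring nitrogen carrying H, one ring carbon carrying a carbonyl oxygen) with
# five CH positions designated R6, R7, R8, R3p, R4p. Built in the z = 0
# plane; the toy system applies a generic rigid transform afterwards.
buildToyScaffold <- function() {
  h <- 1.2124  # 1.4 * cos(30 deg)
  a <- rbind(c(h, 0.7), c(0, 1.4), c(-h, 0.7), c(-h, -0.7), c(0, -1.4),
             c(h, -0.7))
  c2 <- c(2 * h, 0)
  b1 <- c2 + c(h, 0.7); b2 <- c2 + c(0, 1.4)
  b5 <- c2 + c(0, -1.4); b6 <- c2 + c(h, -0.7)
  heavy <- rbind(a, b1, b2, b5, b6)               # 1..6 = a1..a6, 7 b1, 8 b2(N), 9 b5, 10 b6
  oc <- b1 + 1.23 * unitVec(b1 - c2)              # 11: carbonyl O on b1
  heavy <- rbind(heavy, oc)
  element <- c(rep("C", 7L), "N", "C", "C", "O")
  bonds <- data.frame(
    i     = c(1L, 2L, 3L, 4L, 5L, 6L, 1L, 8L, 7L, 10L, 9L, 7L),
    j     = c(2L, 3L, 4L, 5L, 6L, 1L, 8L, 7L, 10L, 9L, 6L, 11L),
    order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 2L, 1L, 2L)
  )
  # hydrogens: ring N (8), CH at 2,3,4,5,9,10 -- placed radially in plane
  xyz <- cbind(heavy, 0)
  hAt <- function(i, center) {
    p <- xyz[i, 1:2]
    d <- unitVec(c(p - center, 0))
    xyz[i, ] + c(1.09, 1.01)[(element[i] == "N") + 1L] * d
  }
  c1 <- c(0, 0)
  hs <- rbind(
    hAt(8L, c2),   # 12 H on ring N (donor)
    hAt(10L, c2),  # 13 H on b6 (non-attachment CH)
    hAt(2L, c1),   # 14 R6
    hAt(3L, c1),   # 15 R7
    hAt(4L, c1),   # 16 R8
    hAt(5L, c1),   # 17 R3p
    hAt(9L, c2)    # 18 R4p
  )
  xyz <- rbind(xyz, hs)
  element <- c(element, rep("H", 7L))
  bonds <- rbind(bonds, data.frame(
    i = c(8L, 10L, 2L, 3L, 4L, 5L, 9L), j = 12:18, order = 1L))
  mol <- newMolecule("toy-scaffold", xyz, element, bonds)
  map <- methods::new("ScaffoldMap",
    coreAtoms = 1:13,
    attachments = data.frame(
      position = c("R6", "R7", "R8", "R3p", "R4p"),
      core_atom = c(2L, 3L, 4L, 5L, 9L),
      replaced_hydrogen = c(14L, 15L, 16L, 17L, 18L),
      stringsAsFactors = FALSE))
  list(molecule = mol, map = map)
}

# Fixed generic rigid transform applied to the whole toy system so that no
# coordinate plane is axis-aligned (also guards the 2D-SDF detector).
.toy_transform <- function(xyz) {
  R <- rotationMatrix(c(1, 2, 3), 0.35)
  sweep(xyz %*% t(R), 2L, c(12, 7, -5), "+")
}

#' Build the synthetic toy system
#'
#' A pocket of \code{pocketSize} pseudo-residues (a glutamine H-bond donor, an
#' aspartate, two stacking aromatics, a tyrosine wall and aliphatic filler)
#' enclosing a planted pose of the planar scaffold, plus the scaffold map,
#' substituent library and an analog table (activities unset until
#' \code{\link{generateActivities}}).
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param blockingGln place the glutamine donor too close to the ligand so
#'   that it sterically penalizes the planted pose (used to emulate the
#'   mutant-potency scenario where truncating the side chain improves
#'   binding). Default FALSE.
#' @return list with receptor, planted (a \linkS4class{LigandPose}),
#'   scaffold, library, records.
#' @export
makeToySystem <- function(spec = syntheticSpec(), blockingGln = FALSE) {
  sc <- buildToyScaffold()
  lig <- sc$molecule
  lxyz <- coords(lig)
  c1 <- c(0, 0, 0); c2 <- c(2 * 1.2124, 0, 0)
  pO <- lxyz[11L, ]
  uO <- unitVec(pO - c2)
  dGln <- 2.95
  wallU <- unitVec(lxyz[4L, ] - c1)  # in-plane direction through the R8 carbon
  ligCtr <- c(1.2, 0, 0)
  radial <- function(res, anchor, d, R) {
    d <- unitVec(d)
    list(res = res, anchor = anchor, target = ligCtr + R * d, inward = -d)
  }
  # the glutamine arm axis is tilted 120 degrees off the N...O axis so that
  # one (sp2, in-plane) amide hydrogen points straight at the acceptor
  vGln <- as.numeric(rotationMatrix(c(0, 0, 1), 2 * pi / 3) %*% uO)
  placements <- list(
    list(res = "GLN", anchor = "NE2", target = pO + dGln * uO, inward = vGln,
         point = "HE21", pointTarget = pO),
    list(res = "ASP", anchor = "OD1",
         target = lxyz[9L, ] + 6.2 * c(0, -1, 0), inward = c(0, 1, 0)),
    list(res = "TYR", anchor = "CZ", target = c(-0.8, 0.2, 3.6),
         inward = c(-1, 0, 0), ring = TRUE, normal = c(0, 0, 1), away = "N"),
    list(res = "PHE", anchor = "CZ", target = c(4.2, 0.2, -3.9),
         inward = c(1, 0, 0), ring = TRUE, normal = c(0, 0, 1), away = "N"),
    # hydrophobic wall facing the R8 position, ring edge-on in the ligand
    # plane (phenylalanine: no para hydroxyl pointing into the pocket)
    list(res = "PHE", anchor = "CZ", target = lxyz[4L, ] + 5.6 * wallU,
         inward = -wallU, ring = TRUE, normal = c(0, 0, 1), away = "N"),
    # aliphatic/filler residues placed radially (anchor at radius R from the
    # ligand centroid, body extending outward); the directions are a fixed
    # clash-free arrangement around the functional residues
    radial("LEU", "CG", c(0.540, 0.833, 0.122), 7.2),
    radial("LEU", "CG", c(0.868, -0.340, -0.362), 8.2),
    radial("LEU", "CG", c(-0.624, 0.680, 0.386), 8.2),
    radial("ALA", "CB", c(0.811, -0.520, 0.266), 6.3),
    radial("ALA", "CB", c(-0.505, -0.615, -0.606), 6.3),
    radial("GLY", "C", c(-0.364, -0.790, 0.494), 6.3),
    radial("LEU", "CG", c(-0.411, 0.838, -0.358), 8.2)
  )
  if (spec$pocketSize > length(placements)) {
    extra <- spec$pocketSize - length(placements)
    for (k in seq_len(extra)) {
      th <- 2 * pi * (k - 0.5) / extra
      tgt <- c(2.4 + 9.5 * cos(th), 9.5 * sin(th), 3.5 * sin(2 * th))
      placements[[length(placements) + 1L]] <-
        list(res = "ALA", anchor = "CB", target = tgt,
             inward = unitVec(c(2.4, 0, 0) - tgt))
    }
  } else if (spec$pocketSize < length(placements)) {
    placements <- placements[seq_len(max(5L, spec$pocketSize))]
  }
  resList <- lapply(placements, function(p) {
    res <- buildResidue(p$res)
    res <- placeResidue(res, p$anchor, p$target, p$inward,
                        ringAtoms = if (isTRUE(p$ring))
                          .residue_rings[[p$res]][[1L]] else NULL,
                        ringNormal = p$normal,
                        pointAtom = p$point, pointTarget = p$pointTarget,
                        awayAtom = p$away, awayFrom = ligCtr)
    res$resname <- p$res
    res
  })
  # split residues over two chains to mimic a two-subunit interface:
  # principal face (chain C) = stacking aromatics + walls, complementary
  # face (chain D) = donor + acidic + the rest
  chains <- rep("D", length(resList))
  chains[c(3L, 5L, 6L, 9L)] <- "C"
  chains <- chains[seq_along(resList)]
  receptor <- residuesToReceptor(resList, chains,
                                 subunitLabels = c(C = "alpha1+", D = "beta3-"))
  # apply the global transform to receptor and ligand together
  rxyz <- .toy_transform(coords(receptor))
  coords(receptor) <- rxyz
  coords(lig) <- .toy_transform(coords(lig))
  planted <- newLigandPose("planted", lig, compoundId = "1",
                           source = "synthetic",
                           meta = list(core_atoms = sc$map@coreAtoms))
  # relax the hand-built ligand in the fixed pocket so the planted pose is a
  # genuine local minimum of the scoring function (decoys are then rigid
  # perturbations away from it)
  planted <- relaxLigand(receptor, planted)
  # clash check on construction (the deterministic layout must be clash-free)
  dmin <- minInterDistance(receptor, planted)
  if (dmin <= 2.2) {
    stop("toy pocket construction produced a clash (min distance ",
         round(dmin, 2), " A)")
  }
  if (blockingGln) {
    # the mutant-potency scenario: keep the ligand pose optimized for the
    # normal pocket, but slide the glutamine donor in so its side chain
    # sterically penalizes that pose (truncation to alanine relieves it)
    resB <- buildResidue("GLN")
    resB <- placeResidue(resB, "NE2", pO + 2.45 * uO, vGln,
                         pointAtom = "HE21", pointTarget = pO)
    resB$resname <- "GLN"
    resB$xyz <- .toy_transform(resB$xyz)
    a <- receptor@atoms
    sel <- a$resid == "GLN" & a$reskey == "1"
    a$x[sel] <- resB$xyz[, 1L]
    a$y[sel] <- resB$xyz[, 2L]
    a$z[sel] <- resB$xyz[, 3L]
    receptor <- methods::new("Receptor", atoms = a,
                             subunitLabels = receptor@subunitLabels)
  }
  records <- toyCompoundTable(spec$nAnalogs)
  list(receptor = receptor, planted = planted, scaffold = sc$map,
       library = substituentLibrary(), records = records)
}

#' In-situ ligand minimization against a rigid receptor
#'
#' Minimizes the ligand's energy in the field of the receptor with every
#' receptor atom held fixed (conjugate gradient, deterministic). This is the
#' re-optimization step used after an in-silico point mutation, and the way
#' the synthetic generator settles its planted pose.
#'
#' @param receptor a \linkS4class{Receptor}; \code{pose} a
#'   \linkS4class{LigandPose}.
#' @param gradientTol,maxIterations convergence controls.
#' @return the pose with relaxed ligand coordinates.
#' @export
relaxLigand <- function(receptor, pose, gradientTol = 0.05,
                        maxIterations = 400L) {
  mol <- pose@molecule
  cs <- combineSystem(receptor, mol)
  sys <- assembleSystem(cs$xyz, cs$charge, cs$element, cs$top)
  nrec <- cs$nrec
  fgrad <- function(x) {
    r <- ff_eval_cpp(x, sys, TRUE)
    g <- r$grad
    g[seq_len(nrec), ] <- 0
    list(total = r$total, grad = g)
  }
  res <- cgMinimize(cs$xyz, fgrad, maxIterations, gradientTol)
  coords(mol) <- res$xyz[nrec + seq_len(nrow(mol@atoms)), , drop = FALSE]
  pose@molecule <- mol
  pose
}

# Minimum heavy-atom distance between receptor and pose.
minInterDistance <- function(receptor, pose) {
  r <- coords(receptor)[!receptor@atoms$is_hydrogen, , drop = FALSE]
  l <- coords(pose)[!pose@molecule@atoms$is_hydrogen, , drop = FALSE]
  min(vapply(seq_len(nrow(l)), function(i) {
    sqrt(min(rowSums(sweep(r, 2L, l[i, ])^2)))
  }, 0))
}

# Fixed analog definitions for the toy series (reference = compound 1,
# unsubstituted). Combinations probe the hydrophobic wall (R8) and the
# donor/acceptor end (R4p).
toyCompoundTable <- function(nAnalogs = 8L) {
  combos <- list(
    c(R8 = "CCH"), c(R8 = "OMe"), c(R4p = "OMe"), c(R6 = "Br"),
    c(R6 = "CN"), c(R8 = "Me"), c(R4p = "Br"), c(R8 = "Cl", R4p = "Me"),
    c(R4p = "NH2"), c(R6 = "OMe"), c(R8 = "Br"), c(R3p = "Br")
  )
  n <- min(nAnalogs, length(combos))
  rows <- lapply(seq_len(n), function(k) {
    row <- data.frame(compound_id = k + 1L, name = paste0("TOY-", k + 1L),
                      R6 = "H", R7 = "H", R8 = "H", R3p = "H", R4p = "H",
                      pEC50_a1b3 = NA_real_, pKi_a1g2 = NA_real_,
                      stringsAsFactors = FALSE)
    for (pos in names(combos[[k]])) row[[pos]] <- combos[[k]][[pos]]
    row
  })
  rbind(data.frame(compound_id = 1L, name = "TOY-REF", R6 = "H", R7 = "H",
                   R8 = "H", R3p = "H", R4p = "H", pEC50_a1b3 = NA_real_,
                   pKi_a1g2 = NA_real_, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Generate decoy poses around a planted pose
#'
#' Seeded random rigid perturbations (rotations up to 180 degrees about the
#' ligand centroid, translations up to \code{spread}), rejected on hard
#' clash with the receptor (heavy-atom distance below 2.2 A) or on falling
#' within 1 A RMSD of the planted pose. Roughly a fifth of the decoys form a
#' "flipped" family: the scaffold rotated 180 degrees about the pocket
#' normal before jittering (a second-binding-mode stand-in).
#'
#' @param planted the true \linkS4class{LigandPose}.
#' @param receptor the pocket.
#' @param n number of decoys.
#' @param spread translation scale, Angstrom.
#' @param seed RNG seed.
#' @return list of \code{n} \linkS4class{LigandPose} objects (p2, p3, ...).
#' @export
makeDecoys <- function(planted, receptor, n, spread = 2.0, seed = 1L) {
  stopifnot(n >= 1L)
  lxyz <- coords(planted)
  ctr <- colMeans(lxyz)
  normal <- unitVec(planeNormal(lxyz[!planted@molecule@atoms$is_hydrogen, ]))
  nFlip <- ceiling(n / 5)
  withSeed(seed, {
    out <- vector("list", n)
    attempts <- 0L
    k <- 0L
    while (k < n) {
      if (attempts >= 10L * n) {
        stop("could not place ", n, " clash-free decoys in ", 10L * n,
             " attempts")
      }
      attempts <- attempts + 1L
      flip <- k < nFlip
      axis <- stats::rnorm(3L)
      if (flip) {
        ang <- stats::runif(1L, 0, 20 * pi / 180)
        R <- rotationMatrix(axis, ang) %*% rotationMatrix(normal, pi)
        tr <- stats::rnorm(3L)
        tr <- tr / vecNorm(tr) * stats::runif(1L)^(1 / 3) * min(spread, 0.8)
      } else {
        ang <- stats::runif(1L, 0, pi)
        R <- rotationMatrix(axis, ang)
        tr <- stats::rnorm(3L)
        tr <- tr / vecNorm(tr) * stats::runif(1L)^(1 / 3) * spread
      }
      xyz <- applyRigid(lxyz, R, tr, center = ctr)
      mol <- planted@molecule
      coords(mol) <- xyz
      cand <- newLigandPose(paste0("p", k + 2L), mol,
                            compoundId = planted@compoundId,
                            source = "synthetic",
                            meta = planted@meta)
      if (minInterDistance(receptor, cand) <= 2.0) next
      if (rmsdNoFit(xyz, lxyz) <= 1.0) next
      k <- k + 1L
      out[[k]] <- cand
    }
    out
  })
}

#' Fill activities from true-pose binding energies
#'
#' Implements the linearity assumption behind the SAR congruency statistic:
#' pEC50_i = intercept + slope * dG_i + Normal(0, noiseSd), with dG_i the
#' binding energy of analog i built on the planted (true) pose.
#'
#' @param records analog table (see \code{\link{makeToySystem}}).
#' @param energies named numeric vector of true-pose binding energies,
#'   names = compound ids.
#' @param slope negative, log units per kcal/mol; \code{noiseSd} log units.
#' @param seed RNG seed; \code{intercept} chosen to center activities at 5.5
#'   when NULL.
#' @return records with pEC50_a1b3 filled.
#' @export
generateActivities <- function(records, energies, slope = -0.2,
                               noiseSd = 0.2, seed = 1L, intercept = NULL) {
  ids <- as.character(records$compound_id)
  miss <- setdiff(ids, names(energies))
  if (length(miss)) stop("energies missing for compound(s): ",
                         paste(miss, collapse = ", "))
  e <- as.numeric(energies[ids])
  if (is.null(intercept)) intercept <- 5.5 - slope * mean(e)
  withSeed(seed, {
    records$pEC50_a1b3 <- intercept + slope * e +
      stats::rnorm(length(e), 0, noiseSd)
  })
  records
}
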
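# Surrogate binding-energy scorer. The functional form (documented in the
# methods vignette) combines Lennard-Jones 12-6, screened Coulomb with a
# distance-dependent dielectric eps(r) = 4r, a pairwise Born-style
# desolvation penalty, a directional hydrogen-bond term, and valence terms
# (harmonic bonds/angles, cosine torsions). It reproduces the *contract* of
# an MM-GBSA-style rescoring stage (energy decomposition, local minimization,
# ligand strain), not the absolute energies of any production force field.

FF_DEFAULTS <- list(
  r_on = 10.0, r_off = 12.0,      # switching window, Angstrom
  scale14 = 0.5,                   # 1-4 nonbonded scaling
  bond_k = 300,                    # kcal/mol/A^2
  angle_k = 60,                    # kcal/mol/rad^2
  tor_V3 = 0.25, tor_V2 = 2.0,     # kcal/mol
  solv_k = 0.05, solv_sigma = 3.5, # desolvation prefactor / width
  hb_eps = 2.5, hb_r0 = 2.9        # H-bond well depth / optimum D...A
)

# Topology of one covalent unit: bonds with equilibrium values, angles,
# torsions, exclusion pairs, hydrogen-bond donors/acceptors.
buildTopology <- function(xyz, element, bonds) {
  n <- nrow(xyz)
  hyb <- hybridization(element, bonds, n)
  adj <- adjacencyList(bonds, n)
  # bonds
  if (nrow(bonds)) {
    obs <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                         xyz[bonds$j, , drop = FALSE])^2))
    r0 <- equilibriumBondLength(element[bonds$i], element[bonds$j], obs)
  } else r0 <- numeric()
  # angles: i-j-k for every pair of neighbors of j
  ai <- integer(); aj <- integer(); akk <- integer()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep(j, ncol(cmb))); akk <- c(akk, cmb[2L, ])
    }
  }
  th0 <- rep(109.47, length(aj))
  th0[hyb[aj] == "sp2"] <- 120
  th0[hyb[aj] == "sp"] <- 180
  th0 <- th0 * pi / 180
  # torsions about each bond j-k
  ti <- integer(); tj <- integer(); tk <- integer(); tl <- integer()
  tV <- numeric(); tn <- numeric(); tph <- numeric()
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      j <- bonds$i[b]; k <- bonds$j[b]
      if (hyb[j] == "sp" || hyb[k] == "sp") next
      planar <- bonds$order[b] >= 2L || (hyb[j] == "sp2" && hyb[k] == "sp2")
      ii <- setdiff(adj[[j]], k); ll <- setdiff(adj[[k]], j)
      if (!length(ii) || !length(ll)) next
      npaths <- length(ii) * length(ll)
      for (a in ii) for (d in ll) {
        if (a == d) next
        ti <- c(ti, a); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, d)
        if (planar) {
          tV <- c(tV, FF_DEFAULTS$tor_V2 / npaths); tn <- c(tn, 2); tph <- c(tph, pi)
        } else {
          tV <- c(tV, FF_DEFAULTS$tor_V3 / npaths); tn <- c(tn, 3); tph <- c(tph, 0)
        }
      }
    }
  }
  # exclusions (1-2, 1-3) and scaled (1-4) pairs
  e12 <- cbind(bonds$i, bonds$j)
  e13 <- if (length(aj)) cbind(ai, akk) else cbind(integer(), integer())
  e14 <- if (length(tj)) cbind(ti, tl) else cbind(integer(), integer())
  # donors/acceptors
  don_d <- integer(); don_h <- integer()
  for (i in seq_len(n)) {
    if (element[i] %in% c("N", "O", "S")) {
      hs <- adj[[i]][element[adj[[i]]] == "H"]
      for (h in hs) { don_d <- c(don_d, i); don_h <- c(don_h, h) }
    }
  }
  acc <- which(element == "O" |
               (element == "N" & !vapply(seq_len(n), function(i)
                 any(element[adj[[i]]] == "H"), TRUE) &
                vapply(adj, length, 0L) <= 2L))
  list(n = n, element = element, hyb = hyb,
       bonds = data.frame(i = bonds$i, j = bonds$j, r0 = r0,
                          k = rep(FF_DEFAULTS$bond_k, nrow(bonds))),
       angles = data.frame(i = ai, j = aj, k = akk, th0 = th0,
                           kf = rep(FF_DEFAULTS$angle_k, length(aj))),
       torsions = data.frame(i = ti, j = tj, k = tk, l = tl,
                             V = tV, nper = tn, phase = tph),
       excl = rbind(e12, e13), s14 = e14,
       donors = data.frame(d = don_d, h = don_h), acceptors = acc)
}

moleculeTopology <- function(mol) {
  buildTopology(coords(mol), mol@atoms$element, mol@bonds)
}

receptorTopology <- function(receptor) {
  xyz <- coords(receptor)
  el <- receptor@atoms$element
  buildTopology(xyz, el, inferBonds(xyz, el))
}

# Shift a topology's atom indices by `off` (when concatenating units).
shiftTopology <- function(top, off) {
  top$bonds[, c("i", "j")] <- top$bonds[, c("i", "j")] + off
  top$angles[, c("i", "j", "k")] <- top$angles[, c("i", "j", "k")] + off
  top$torsions[, c("i", "j", "k", "l")] <- top$torsions[, c("i", "j", "k", "l")] + off
  if (nrow(top$excl)) top$excl <- top$excl + off
  if (nrow(top$s14)) top$s14 <- top$s14 + off
  top$donors <- top$donors + off
  top$acceptors <- top$acceptors + off
  top
}

mergeTopologies <- function(a, b) {
  list(n = a$n + b$n, element = c(a$element, b$element),
       bonds = rbind(a$bonds, b$bonds), angles = rbind(a$angles, b$angles),
       torsions = rbind(a$torsions, b$torsions),
       excl = rbind(a$excl, b$excl), s14 = rbind(a$s14, b$s14),
       donors = rbind(a$donors, b$donors),
       acceptors = c(a$acceptors, b$acceptors))
}

# Assemble the ff system list consumed by ff_eval_cpp (0-based indices).
# Intermolecular hydrogen-bond candidate triples are enumerated here from
# the starting geometry (within 5.5 A).
assembleSystem <- function(xyz, charge, element, top,
                           restraintK = NULL, restraintRef = NULL) {
  n <- nrow(xyz)
  pr <- build_pairs_cpp(xyz, FF_DEFAULTS$r_off + 2.0,
                        as.integer(top$excl[, 1L] - 1L),
                        as.integer(top$excl[, 2L] - 1L),
                        as.integer(top$s14[, 1L] - 1L),
                        as.integer(top$s14[, 2L] - 1L),
                        FF_DEFAULTS$scale14)
  # hydrogen-bond triples: donor-H x acceptor, D != A, not excluded,
  # D...A within 5.5 A at assembly time
  hd <- integer(); hh <- integer(); ha <- integer()
  if (nrow(top$donors) && length(top$acceptors)) {
    exclKey <- character()
    if (nrow(top$excl)) {
      exclKey <- paste(pmin(top$excl[, 1L], top$excl[, 2L]),
                       pmax(top$excl[, 1L], top$excl[, 2L]))
    }
    for (r in seq_len(nrow(top$donors))) {
      d <- top$donors$d[r]; h <- top$donors$h[r]
      for (a in top$acceptors) {
        if (a == d) next
        if (paste(min(d, a), max(d, a)) %in% exclKey) next
        dd <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dd <= 5.5) { hd <- c(hd, d); hh <- c(hh, h); ha <- c(ha, a) }
      }
    }
  }
  if (is.null(restraintK)) restraintK <- rep(0, n)
  if (is.null(restraintRef)) restraintRef <- xyz
  eps <- elementProperty(element, "eps")
  eps[top$donors$h] <- 0  # polar hydrogens carry no Lennard-Jones well
  list(
    charge = charge,
    sigma = elementProperty(element, "sigma"),
    eps = eps,
    pair_i = as.integer(pr$i), pair_j = as.integer(pr$j),
    pair_scale = as.numeric(pr$scale),
    bond_i = as.integer(top$bonds$i - 1L), bond_j = as.integer(top$bonds$j - 1L),
    bond_r0 = as.numeric(top$bonds$r0), bond_k = as.numeric(top$bonds$k),
    ang_i = as.integer(top$angles$i - 1L), ang_j = as.integer(top$angles$j - 1L),
    ang_k = as.integer(top$angles$k - 1L), ang_th0 = as.numeric(top$angles$th0),
    ang_kf = as.numeric(top$angles$kf),
    tor_i = as.integer(top$torsions$i - 1L), tor_j = as.integer(top$torsions$j - 1L),
    tor_k = as.integer(top$torsions$k - 1L), tor_l = as.integer(top$torsions$l - 1L),
    tor_V = as.numeric(top$torsions$V), tor_n = as.numeric(top$torsions$nper),
    tor_phase = as.numeric(top$torsions$phase),
    hb_d = as.integer(hd - 1L), hb_h = as.integer(hh - 1L),
    hb_a = as.integer(ha - 1L),
    restraint_k = as.numeric(restraintK), restraint_ref = restraintRef,
    r_on = FF_DEFAULTS$r_on, r_off = FF_DEFAULTS$r_off,
    solv_k = FF_DEFAULTS$solv_k, solv_sigma = FF_DEFAULTS$solv_sigma,
    hb_eps = FF_DEFAULTS$hb_eps, hb_r0 = FF_DEFAULTS$hb_r0
  )
}

# Internal: combined coordinates/charges/elements + topology for a
# receptor-ligand pair (either may be NULL). Receptor topology may be
# supplied precomputed to avoid repeated bond inference when scoring many
# poses against the same receptor.
combineSystem <- function(receptor = NULL, molecule = NULL, recTop = NULL) {
  if (is.null(receptor) && is.null(molecule)) {
    stop("at least one of receptor/molecule must be given")
  }
  parts <- list()
  if (!is.null(receptor)) {
    if (is.null(recTop)) recTop <- receptorTopology(receptor)
    parts$rec <- list(xyz = coords(receptor), q = receptor@atoms$charge,
                      el = receptor@atoms$element, top = recTop)
  }
  if (!is.null(molecule)) {
    parts$lig <- list(xyz = coords(molecule), q = molecule@atoms$charge,
                      el = molecule@atoms$element, top = moleculeTopology(molecule))
  }
  if (length(parts) == 2L) {
    off <- nrow(parts$rec$xyz)
    top <- mergeTopologies(parts$rec$top, shiftTopology(parts$lig$top, off))
    xyz <- rbind(parts$rec$xyz, parts$lig$xyz)
    q <- c(parts$rec$q, parts$lig$q)
    el <- c(parts$rec$el, parts$lig$el)
  } else {
    p <- parts[[1L]]
    top <- p$top; xyz <- p$xyz; q <- p$q; el <- p$el
  }
  list(xyz = xyz, charge = q, element = el, top = top,
       nrec = if (is.null(receptor)) 0L else nrow(parts$rec$xyz))
}

#' Total potential energy of a system
#'
#' Evaluates the surrogate force field for a receptor, a molecule, or a
#' receptor-ligand complex (kcal/mol). Deterministic for fixed input.
#'
#' @param receptor a \linkS4class{Receptor} or NULL.
#' @param molecule a \linkS4class{Molecule}, \linkS4class{LigandPose} or NULL.
#' @return numeric energy with attribute \code{"components"} (vdw, elec,
#'   solv, hbond, bonded, restraint).
#' @export
systemEnergy <- function(receptor = NULL, molecule = NULL) {
  if (inherits(molecule, "LigandPose")) molecule <- molecule@molecule
  cs <- combineSystem(receptor, molecule)
  sys <- assembleSystem(cs$xyz, cs$charge, cs$element, cs$top)
  res <- ff_eval_cpp(cs$xyz, sys, FALSE)
  out <- res$total
  attr(out, "components") <- res$components
  out
}

#' Binding energy of a pose (energy decomposition)
#'
#' dG_bind = G_complex - G_receptor - G_ligand, all three terms evaluated
#' with the same force field on the given geometries (no minimization here;
#' see \code{\link{minimizeComplex}}).
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param pose a \linkS4class{LigandPose} in the receptor frame.
#' @param recTop,recEnergy optional precomputed receptor topology and energy
#'   (used by \code{\link{scorePoses}} to avoid recomputation).
#' @return an \linkS4class{EnergyReport}.
#' @export
bindingEnergy <- function(receptor, pose, recTop = NULL, recEnergy = NULL) {
  mol <- if (inherits(pose, "LigandPose")) pose@molecule else pose
  if (is.null(recTop)) recTop <- receptorTopology(receptor)
  if (is.null(recEnergy)) {
    csr <- combineSystem(receptor = receptor, recTop = recTop)
    er <- ff_eval_cpp(csr$xyz, assembleSystem(csr$xyz, csr$charge, csr$element,
                                              csr$top), FALSE)
    recEnergy <- er
  }
  csl <- combineSystem(molecule = mol)
  el <- ff_eval_cpp(csl$xyz, assembleSystem(csl$xyz, csl$charge, csl$element,
                                            csl$top), FALSE)
  csc <- combineSystem(receptor, mol, recTop = recTop)
  ec <- ff_eval_cpp(csc$xyz, assembleSystem(csc$xyz, csc$charge, csc$element,
                                            csc$top), FALSE)
  dG <- ec$total - recEnergy$total - el$total
  comp <- ec$components - recEnergy$components - el$components
  methods::new("EnergyReport",
               dGbind = dG,
               components = c(vdw = unname(comp["vdw"]),
                              elec = unname(comp["elec"]),
                              solv = unname(comp["solv"]),
                              hbond = unname(comp["hbond"])),
               ligandStrain = NA_real_, iterations = 0,
               finalGradient = NA_real_, minimized = FALSE)
}
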
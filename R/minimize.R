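# Restrained local minimization of receptor-ligand complexes, ligand strain,
# and batch scoring. The optimizer is a Polak-Ribiere conjugate-gradient
# with Armijo backtracking; it terminates when the largest gradient component
# drops below the tolerance or the iteration budget is exhausted. Accepted
# steps always decrease the energy, so the energy trace is non-increasing by
# construction.

#' Minimization parameter constructor
#'
#' @param maxIterations iteration cap (default 2500).
#' @param gradientTol convergence threshold on the largest gradient
#'   component, kcal/mol/A (default 0.05).
#' @param restraintK harmonic restraint on atoms outside the mobile set,
#'   kcal/mol/A^2 (default 200).
#' @param freeShell radius around ligand heavy atoms within which residue
#'   side chains are mobile, Angstrom (default 5).
#' @return a \linkS4class{MinimizationParams}.
#' @export
minimizationParams <- function(maxIterations = 2500, gradientTol = 0.05,
                               restraintK = 200, freeShell = 5.0) {
  methods::new("MinimizationParams", maxIterations = maxIterations,
               gradientTol = gradientTol, restraintK = restraintK,
               freeShell = freeShell)
}

# Conjugate-gradient driver over an energy/gradient closure.
# fgrad(xyz) -> list(total, grad). Returns list(xyz, iterations, trace,
# final_gradient, converged).
cgMinimize <- function(xyz, fgrad, maxIterations, gradientTol) {
  cur <- fgrad(xyz)
  if (!is.finite(cur$total)) stop("non-finite energy at starting geometry")
  g <- cur$grad
  d <- -g
  trace <- cur$total
  alpha <- 1e-3
  iter <- 0L
  gmax <- max(abs(g))
  while (gmax > gradientTol && iter < maxIterations) {
    # Armijo backtracking along d
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }  # reset to steepest descent
    step <- alpha
    accepted <- FALSE
    for (ls in 1:40) {
      xnew <- xyz + step * d
      enew <- tryCatch(fgrad(xnew), error = function(e) NULL)
      if (!is.null(enew) && is.finite(enew$total) &&
          enew$total <= cur$total + 1e-4 * step * gd) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      if (max(abs(d + g)) < 1e-12) break  # steepest descent failed: stop
      d <- -g
      alpha <- alpha / 4
      if (alpha < 1e-14) break
      next
    }
    iter <- iter + 1L
    gnew <- enew$grad
    beta <- max(0, sum(gnew * (gnew - g)) / max(sum(g * g), 1e-30))
    d <- -gnew + beta * d
    xyz <- xnew
    g <- gnew
    cur <- enew
    trace <- c(trace, cur$total)
    gmax <- max(abs(g))
    alpha <- min(step * 2, 1.0)
  }
  list(xyz = xyz, iterations = iter, trace = trace,
       final_gradient = gmax, converged = gmax <= gradientTol)
}

# Mobile set per the protocol contract: ligand atoms plus side-chain atoms of
# residues having any atom within freeShell of a ligand heavy atom. Decided
# once from the starting geometry. Returns restraint force constants per
# combined-system atom (0 = mobile).
.backbone_names <- c("N", "CA", "C", "O", "H", "HA", "H1", "H2", "H3",
                     "OXT", "HN", "HA2", "HA3")

mobileRestraints <- function(receptor, mol, freeShell, restraintK) {
  ra <- receptor@atoms
  rxyz <- coords(receptor)
  lxyz <- coords(mol)[!mol@atoms$is_hydrogen, , drop = FALSE]
  # distance of every receptor atom to the nearest ligand heavy atom
  mind <- apply(rxyz, 1L, function(p) {
    sqrt(min(colSums((t(lxyz) - p)^2)))
  })
  key <- paste(ra$chain, ra$reskey)
  shellRes <- unique(key[mind <= freeShell])
  sidechain <- !(ra$elety %in% .backbone_names)
  mobile <- (key %in% shellRes) & sidechain
  k <- c(ifelse(mobile, 0, restraintK), rep(0, nrow(mol@atoms)))
  k
}

#' Minimize a receptor-ligand complex under positional restraints
#'
#' The ligand and the side chains of residues within \code{freeShell} of any
#' ligand heavy atom move freely; every other atom is harmonically restrained
#' to its starting position with \code{restraintK}. Terminates when the
#' largest gradient component falls below \code{gradientTol} or after
#' \code{maxIterations} accepted steps.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param pose a \linkS4class{LigandPose}.
#' @param params a \linkS4class{MinimizationParams}.
#' @param coreAtoms optional scaffold atom indices used for the RMSD-to-start
#'   bookkeeping (defaults to the pose's \code{meta$core_atoms}, else all
#'   ligand heavy atoms).
#' @return list with \code{pose} (minimized), \code{receptor} (minimized),
#'   \code{report} (an \linkS4class{EnergyReport} for the minimized
#'   geometry, with iterations/gradient/strain filled in),
#'   \code{scaffold_rmsd} and the energy \code{trace}.
#' @export
minimizeComplex <- function(receptor, pose, params = minimizationParams(),
                            coreAtoms = NULL) {
  methods::validObject(params)
  mol <- pose@molecule
  if (is.null(coreAtoms)) coreAtoms <- pose@meta$core_atoms
  if (is.null(coreAtoms)) coreAtoms <- which(!mol@atoms$is_hydrogen)
  recTop <- receptorTopology(receptor)
  cs <- combineSystem(receptor, mol, recTop = recTop)
  rk <- mobileRestraints(receptor, mol, params@freeShell, params@restraintK)
  sys <- assembleSystem(cs$xyz, cs$charge, cs$element, cs$top,
                        restraintK = rk, restraintRef = cs$xyz)
  it <- 0L
  fgrad <- function(x) {
    it <<- it
    r <- ff_eval_cpp(x, sys, TRUE)
    list(total = r$total, grad = r$grad)
  }
  res <- tryCatch(
    cgMinimize(cs$xyz, fgrad, params@maxIterations, params@gradientTol),
    error = function(e) stop("minimization failed: ", conditionMessage(e))
  )
  nrec <- cs$nrec
  newRec <- receptor
  coords(newRec) <- res$xyz[seq_len(nrec), , drop = FALSE]
  newMol <- mol
  coords(newMol) <- res$xyz[nrec + seq_len(nrow(mol@atoms)), , drop = FALSE]
  newPose <- pose
  newPose@molecule <- newMol
  srmsd <- rmsdNoFit(coords(mol)[coreAtoms, , drop = FALSE],
                     coords(newMol)[coreAtoms, , drop = FALSE])
  rep0 <- bindingEnergy(newRec, newPose, recTop = NULL)
  rep0@iterations <- res$iterations
  rep0@finalGradient <- res$final_gradient
  rep0@minimized <- TRUE
  rep0@ligandStrain <- ligandStrain(newPose, gradientTol = params@gradientTol,
                                    maxIterations = params@maxIterations)
  list(pose = newPose, receptor = newRec, report = rep0,
       scaffold_rmsd = srmsd, trace = res$trace)
}

#' Ligand strain energy
#'
#' Difference between the ligand energy at its bound geometry and the energy
#' of the same ligand minimized free of the receptor, starting from the
#' bound geometry. Non-negative up to convergence tolerance.
#'
#' @param pose a \linkS4class{LigandPose} or \linkS4class{Molecule} at the
#'   bound geometry.
#' @param gradientTol,maxIterations free-minimization controls.
#' @return strain in kcal/mol.
#' @export
ligandStrain <- function(pose, gradientTol = 0.05, maxIterations = 2500) {
  mol <- if (inherits(pose, "LigandPose")) pose@molecule else pose
  cs <- combineSystem(molecule = mol)
  sys <- assembleSystem(cs$xyz, cs$charge, cs$element, cs$top)
  fgrad <- function(x) {
    r <- ff_eval_cpp(x, sys, TRUE)
    list(total = r$total, grad = r$grad)
  }
  e0 <- ff_eval_cpp(cs$xyz, sys, FALSE)$total
  res <- cgMinimize(cs$xyz, fgrad, maxIterations, gradientTol)
  emin <- ff_eval_cpp(res$xyz, sys, FALSE)$total
  e0 - emin
}

#' Score a pose ensemble against one receptor
#'
#' Computes the binding energy of every pose (optionally after restrained
#' minimization) and returns the long-format energy table consumed by
#' \code{\link{assessPoses}}.
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param poses list of \linkS4class{LigandPose}.
#' @param minimize logical; run \code{\link{minimizeComplex}} first.
#' @param params minimization parameters.
#' @param strain include ligand strain (adds a free ligand minimization per
#'   pose; reported both raw and strain-corrected).
#' @return data.frame with columns pose_id, compound_id, dG_bind, vdw, elec,
#'   solv, hbond, strain, dG_strain_corrected, scaffold_rmsd, iterations,
#'   final_gradient.
#' @export
scorePoses <- function(receptor, poses, minimize = FALSE,
                       params = minimizationParams(), strain = minimize) {
  recTop <- receptorTopology(receptor)
  csr <- combineSystem(receptor = receptor, recTop = recTop)
  recE <- ff_eval_cpp(csr$xyz, assembleSystem(csr$xyz, csr$charge,
                                              csr$element, csr$top), FALSE)
  rows <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    srmsd <- 0; iters <- 0; fgrad <- NA_real_; st <- NA_real_
    clash <- FALSE
    if (minimize) {
      mres <- minimizeComplex(receptor, p, params)
      rep0 <- mres$report
      srmsd <- mres$scaffold_rmsd
      iters <- rep0@iterations; fgrad <- rep0@finalGradient
      st <- rep0@ligandStrain
    } else {
      # a derivatized decoy can place a rigid substituent on top of a
      # receptor atom; such poses are flagged with a hard clash score
      # rather than aborting the whole campaign
      rep0 <- tryCatch(
        bindingEnergy(receptor, p, recTop = recTop, recEnergy = recE),
        error = function(e) {
          if (!grepl("overlapping", conditionMessage(e))) stop(e)
          clash <<- TRUE
          methods::new("EnergyReport", dGbind = 1e4,
                       components = c(vdw = 1e4, elec = 0, solv = 0,
                                      hbond = 0))
        })
      if (strain && !clash) st <- ligandStrain(p)
    }
    rows[[k]] <- data.frame(
      pose_id = p@poseId, compound_id = p@compoundId,
      dG_bind = rep0@dGbind,
      vdw = rep0@components[["vdw"]], elec = rep0@components[["elec"]],
      solv = rep0@components[["solv"]], hbond = rep0@components[["hbond"]],
      strain = st,
      dG_strain_corrected = if (is.na(st)) NA_real_ else rep0@dGbind + st,
      scaffold_rmsd = srmsd, iterations = iters, final_gradient = fgrad,
      clash = clash,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
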
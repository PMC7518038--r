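# Central S4 classes. Atom records live in data.frames inside the container
# classes (one row per atom); indices are 1-based throughout the package and
# converted to native serials only at the file-format boundaries.

.validMoleculeAtoms <- function(atoms) {
  need <- c("element", "x", "y", "z", "charge", "vdw", "is_hydrogen")
  if (!all(need %in% names(atoms))) {
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(atoms)) {
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
      return("atom coordinates must be finite")
    }
    if (any(!(atoms$element %in% SUPPORTED_ELEMENTS))) {
      return(paste("unsupported element(s):",
                   paste(setdiff(unique(atoms$element), SUPPORTED_ELEMENTS),
                         collapse = ", ")))
    }
    if (any(atoms$vdw <= 0)) return("vdw_radius must be > 0")
  }
  TRUE
}

#' Molecule: atoms plus bonds
#'
#' A small-molecule container: an ordered atom table (element, coordinates in
#' Angstrom, partial charge in elementary units, van der Waals radius,
#' hydrogen flag) and a bond table (1-based atom indices and integer order).
#'
#' @slot name molecule title.
#' @slot atoms data.frame with columns element, x, y, z, charge, vdw,
#'   is_hydrogen.
#' @slot bonds data.frame with columns i, j, order.
#' @export
setClass("Molecule",
  representation(name = "character", atoms = "data.frame", bonds = "data.frame"),
  prototype(name = "", atoms = data.frame(), bonds = data.frame()),
  validity = function(object) {
    msg <- .validMoleculeAtoms(object@atoms)
    if (!isTRUE(msg)) return(msg)
    b <- object@bonds
    if (nrow(b)) {
      n <- nrow(object@atoms)
      if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n)) {
        return("bond indices out of range")
      }
      if (any(b$i == b$j)) return("self-bonds are not allowed")
    }
    TRUE
  }
)

#' Receptor: annotated protein structure
#'
#' Atom table with residue/chain annotation. Residues are identified by
#' (chain, reskey) where reskey is the residue number with any insertion code
#' appended as text.
#'
#' @slot atoms data.frame with columns chain, resno, insert, reskey, resid,
#'   elety, element, x, y, z, occ, charge, vdw, is_hydrogen.
#' @slot subunitLabels optional named character vector mapping chain id to a
#'   subunit label (e.g. "alpha1+", "beta3-").
#' @export
setClass("Receptor",
  representation(atoms = "data.frame", subunitLabels = "character"),
  prototype(atoms = data.frame(), subunitLabels = character()),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "insert", "reskey", "resid", "elety",
              "element", "x", "y", "z", "charge", "vdw", "is_hydrogen")
    if (!all(need %in% names(a))) {
      return(paste("receptor atom table must have columns:",
                   paste(need, collapse = ", ")))
    }
    if (nrow(a)) {
      if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
        return("receptor coordinates must be finite")
      }
      std <- a$resid %in% names(.residue_templates)
      if (any(std)) {
        key <- paste(a$chain, a$reskey)
        for (kk in unique(key[std])) {
          sel <- key == kk & !a$is_hydrogen
          have <- a$elety[sel]
          if (!all(c("N", "CA", "C", "O") %in% have)) {
            return(paste("residue", kk, "lacks backbone atoms N/CA/C/O"))
          }
        }
      }
    }
    TRUE
  }
)

#' LigandPose: a ligand geometry in the receptor frame
#'
#' @slot poseId pose identifier (unique within an ensemble).
#' @slot compoundId compound identifier from the activity table.
#' @slot molecule the posed \linkS4class{Molecule}.
#' @slot source provenance tag ("docking", "derivatization", "synthetic", ...).
#' @slot meta free-form bookkeeping list (e.g. core atom indices).
#' @export
setClass("LigandPose",
  representation(poseId = "character", compoundId = "character",
                 molecule = "Molecule", source = "character", meta = "list"),
  prototype(poseId = "", compoundId = "", source = "", meta = list())
)

#' ScaffoldMap: the invariant core and its attachment points
#'
#' @slot coreAtoms 1-based indices of the invariant scaffold atoms in the
#'   reference molecule.
#' @slot attachments data.frame with columns position (R6/R7/R8/R3p/R4p),
#'   core_atom, replaced_hydrogen. \code{replaced_hydrogen} is the first atom
#'   of the branch replaced during derivatization (a hydrogen for a bare
#'   scaffold; the substituent root when the reference compound already
#'   carries a group at the position).
#' @export
setClass("ScaffoldMap",
  representation(coreAtoms = "integer", attachments = "data.frame"),
  validity = function(object) {
    if (!length(object@coreAtoms)) return("core_atoms must be non-empty")
    if (anyDuplicated(object@coreAtoms)) return("core_atoms must be unique")
    at <- object@attachments
    need <- c("position", "core_atom", "replaced_hydrogen")
    if (!all(need %in% names(at))) {
      return("attachments need columns position, core_atom, replaced_hydrogen")
    }
    if (nrow(at)) {
      if (!all(at$position %in% c("R6", "R7", "R8", "R3p", "R4p"))) {
        return("attachment positions must be R6, R7, R8, R3p or R4p")
      }
      if (!all(at$core_atom %in% object@coreAtoms)) {
        return("every attachment core_atom must be a core atom")
      }
      if (any(at$replaced_hydrogen %in% object@coreAtoms)) {
        return("replaced atoms cannot be core atoms")
      }
    }
    TRUE
  }
)

#' Substituent: an R-group fragment with one open valence
#'
#' @slot label canonical substituent label (H, Me, OMe, Cl, Br, F, tBu, CCH,
#'   CN, COOEt, NH2).
#' @slot fragment fragment geometry as a \linkS4class{Molecule}.
#' @slot linkAtom index of the fragment atom that bonds to the scaffold.
#' @export
setClass("Substituent",
  representation(label = "character", fragment = "Molecule", linkAtom = "integer"),
  validity = function(object) {
    if (object@linkAtom < 1L || object@linkAtom > nrow(object@fragment@atoms)) {
      return("link_atom out of range")
    }
    TRUE
  }
)

#' MinimizationParams: restrained local minimization settings
#'
#' Defaults follow the protocol this package implements: at most 2500
#' iterations, convergence when the largest gradient component drops to
#' 0.05 kcal/mol/A, a 200 kcal/mol/A^2 positional restraint on atoms outside
#' the mobile set, and a 5 Angstrom free shell around the ligand.
#'
#' @export
setClass("MinimizationParams",
  representation(maxIterations = "numeric", gradientTol = "numeric",
                 restraintK = "numeric", freeShell = "numeric"),
  prototype(maxIterations = 2500, gradientTol = 0.05,
            restraintK = 200, freeShell = 5.0),
  validity = function(object) {
    v <- c(object@maxIterations, object@gradientTol,
           object@restraintK, object@freeShell)
    if (any(!is.finite(v)) || any(v <= 0)) {
      return("all minimization parameters must be positive")
    }
    TRUE
  }
)

#' EnergyReport: binding-energy decomposition for one complex
#'
#' @slot dGbind binding energy, kcal/mol (G_complex - G_receptor - G_ligand).
#' @slot components named numeric: vdw, elec, solv, hbond (kcal/mol).
#' @slot ligandStrain kcal/mol (bound-geometry minus freely minimized ligand).
#' @slot iterations minimization iterations actually taken.
#' @slot finalGradient largest gradient component at exit, kcal/mol/A.
#' @slot minimized whether the geometry was minimized before scoring.
#' @export
setClass("EnergyReport",
  representation(dGbind = "numeric", components = "numeric",
                 ligandStrain = "numeric", iterations = "numeric",
                 finalGradient = "numeric", minimized = "logical"),
  prototype(dGbind = NA_real_, components = c(vdw = 0, elec = 0, solv = 0, hbond = 0),
            ligandStrain = NA_real_, iterations = 0, finalGradient = NA_real_,
            minimized = FALSE)
)
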
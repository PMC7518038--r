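# Generics and accessor/show methods for the core classes.

#' @rdname Molecule-class
#' @param x,object a PoseSAR object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname Molecule-class
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname Molecule-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname Molecule-class
#' @param value replacement value.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))
#' @rdname Molecule-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname LigandPose-class
#' @export
setGeneric("poseId", function(x) standardGeneric("poseId"))
#' @rdname LigandPose-class
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname LigandPose-class
#' @export
setGeneric("poseMolecule", function(x) standardGeneric("poseMolecule"))

#' @rdname Receptor-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname Receptor-class
#' @export
setGeneric("subunitLabels", function(x) standardGeneric("subunitLabels"))

#' @describeIn Molecule-class atom table accessor.
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)
#' @describeIn Molecule-class bond table accessor.
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)
#' @describeIn Molecule-class coordinates as an n x 3 matrix.
#' @export
setMethod("coords", "Molecule", function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})
#' @describeIn Molecule-class replace coordinates.
#' @export
setMethod("coords<-", "Molecule", function(x, value) {
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]; x@atoms$y <- value[, 2L]; x@atoms$z <- value[, 3L]
  x
})
#' @describeIn Molecule-class number of atoms.
#' @export
setMethod("nAtoms", "Molecule", function(x) nrow(x@atoms))

#' @describeIn Receptor-class atom table accessor.
#' @export
setMethod("atoms", "Receptor", function(x) x@atoms)
#' @describeIn Receptor-class coordinates as an n x 3 matrix.
#' @export
setMethod("coords", "Receptor", function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})
#' @describeIn Receptor-class replace coordinates.
#' @export
setMethod("coords<-", "Receptor", function(x, value) {
  stopifnot(nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]; x@atoms$y <- value[, 2L]; x@atoms$z <- value[, 3L]
  x
})
#' @describeIn Receptor-class number of atoms.
#' @export
setMethod("nAtoms", "Receptor", function(x) nrow(x@atoms))
#' @describeIn Receptor-class one row per residue (chain, reskey, resid,
#'   n_atoms).
#' @export
setMethod("residues", "Receptor", function(x) {
  a <- x@atoms
  if (!nrow(a)) {
    return(data.frame(chain = character(), reskey = character(),
                      resid = character(), n_atoms = integer()))
  }
  key <- paste(a$chain, a$reskey, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], reskey = a$reskey[idx],
             resid = a$resid[idx],
             n_atoms = as.integer(table(factor(key, levels = key[idx]))),
             stringsAsFactors = FALSE)
})
#' @describeIn Receptor-class chain-to-subunit label map.
#' @export
setMethod("subunitLabels", "Receptor", function(x) x@subunitLabels)

#' @describeIn LigandPose-class pose identifier.
#' @export
setMethod("poseId", "LigandPose", function(x) x@poseId)
#' @describeIn LigandPose-class compound identifier.
#' @export
setMethod("compoundId", "LigandPose", function(x) x@compoundId)
#' @describeIn LigandPose-class the posed molecule.
#' @export
setMethod("poseMolecule", "LigandPose", function(x) x@molecule)
#' @describeIn LigandPose-class pose coordinates.
#' @export
setMethod("coords", "LigandPose", function(x) coords(x@molecule))
#' @describeIn LigandPose-class number of atoms in the posed molecule.
#' @export
setMethod("nAtoms", "LigandPose", function(x) nrow(x@molecule@atoms))

setMethod("show", "Molecule", function(object) {
  cat("Molecule", sQuote(object@name), ":", nrow(object@atoms), "atoms (",
      sum(!object@atoms$is_hydrogen), "heavy ),", nrow(object@bonds), "bonds\n")
})
setMethod("show", "Receptor", function(object) {
  r <- residues(object)
  cat("Receptor:", nrow(object@atoms), "atoms,", nrow(r), "residues,",
      length(unique(object@atoms$chain)), "chain(s)\n")
  if (length(object@subunitLabels)) {
    cat("  subunits:", paste(names(object@subunitLabels),
                             object@subunitLabels, sep = "=", collapse = ", "), "\n")
  }
})
setMethod("show", "LigandPose", function(object) {
  cat("LigandPose", sQuote(object@poseId), "compound", object@compoundId,
      "(", nrow(object@molecule@atoms), "atoms, source:", object@source, ")\n")
})
setMethod("show", "EnergyReport", function(object) {
  cat(sprintf("EnergyReport: dG_bind = %.3f kcal/mol (vdw %.2f, elec %.2f, solv %.2f, hbond %.2f)\n",
              object@dGbind, object@components[["vdw"]], object@components[["elec"]],
              object@components[["solv"]], object@components[["hbond"]]))
  cat(sprintf("  strain = %.3f, iterations = %d, final gradient = %.4f, minimized = %s\n",
              object@ligandStrain, as.integer(object@iterations),
              object@finalGradient, object@minimized))
})
setMethod("show", "ScaffoldMap", function(object) {
  cat("ScaffoldMap:", length(object@coreAtoms), "core atoms,",
      nrow(object@attachments), "attachment points (",
      paste(object@attachments$position, collapse = ", "), ")\n")
})

#' Construct a Molecule
#'
#' Builds a \linkS4class{Molecule} from coordinates, elements and bonds.
#' Charges default to the rule-based assignment of \code{\link{assignCharges}}
#' when not supplied; van der Waals radii come from the packaged element table.
#'
#' @param name molecule title.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param element character vector of element symbols.
#' @param bonds data.frame with columns i, j, order (1-based indices).
#' @param charge optional numeric vector of partial charges.
#' @return a \linkS4class{Molecule}.
#' @export
newMolecule <- function(name, xyz, element, bonds, charge = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (is.null(charge)) charge <- assignCharges(xyz, element, bonds)
  atoms <- data.frame(
    element = element, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    charge = charge, vdw = elementProperty(element, "vdw"),
    is_hydrogen = element == "H", stringsAsFactors = FALSE
  )
  methods::new("Molecule", name = name, atoms = atoms,
               bonds = as.data.frame(bonds))
}

#' Construct a LigandPose
#'
#' @param poseId pose identifier; \code{molecule} a \linkS4class{Molecule};
#'   \code{compoundId} compound label; \code{source} provenance tag;
#'   \code{meta} bookkeeping list.
#' @return a \linkS4class{LigandPose}.
#' @export
newLigandPose <- function(poseId, molecule, compoundId = "", source = "docking",
                          meta = list()) {
  methods::new("LigandPose", poseId = as.character(poseId), molecule = molecule,
               compoundId = as.character(compoundId), source = source, meta = meta)
}
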
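# Receptor I/O. Parsing and writing of PDB records is delegated to bio3d;
# this layer adds the dialect decisions: single-model enforcement, altloc
# resolution by highest occupancy (then alphabetical), element inference from
# atom-name columns, insertion codes appended to the residue number, and
# rule-based charge assignment.

#' Read a receptor structure from a single-model PDB file
#'
#' @param path PDB file with ATOM/HETATM records, single model.
#' @param subunitLabels optional named character vector mapping chain ids to
#'   subunit labels (e.g. \code{c(C = "alpha1+", D = "beta3-")}).
#' @return a \linkS4class{Receptor}.
#' @details ANISOU/TER records are ignored. Alternate locations are resolved
#'   per atom by keeping the highest-occupancy conformer (ties broken
#'   alphabetically by altloc id). Elements are taken from the element column
#'   when present, otherwise inferred from the atom name.
#' @export
readReceptor <- function(path, subunitLabels = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nmodel <- sum(startsWith(lines, "MODEL "))
  if (nmodel > 1L) {
    stop("multi-model PDB not supported: file declares ", nmodel, " models")
  }
  reclines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(reclines)) stop("no ATOM/HETATM records in ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      stop("unparseable PDB near line ", reclines[1L], ": ",
           conditionMessage(e))
    }
  )
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1.0
  # altloc resolution: per (chain, resno, insert, elety) keep the conformer
  # with the highest occupancy; ties broken alphabetically by altloc id.
  if (any(nzchar(a$alt))) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(a$eleno), , drop = FALSE]
  }
  element <- a$elesy
  miss <- is.na(element) | !nzchar(trimws(element))
  if (any(miss)) element[miss] <- elementFromAtomName(a$elety[miss])
  element <- normalizeElement(trimws(element))
  bad <- !(element %in% SUPPORTED_ELEMENTS)
  if (any(bad)) {
    stop("unsupported element(s) in PDB: ",
         paste(unique(element[bad]), collapse = ", "),
         " (atom serial ", a$eleno[which(bad)[1L]], ")")
  }
  xyz <- cbind(a$x, a$y, a$z)
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert,
    reskey = paste0(a$resno, a$insert), resid = a$resid, elety = a$elety,
    element = element, x = a$x, y = a$y, z = a$z, occ = a$o,
    charge = 0, vdw = elementProperty(element, "vdw"),
    is_hydrogen = element == "H", stringsAsFactors = FALSE
  )
  b <- inferBonds(xyz, element)
  atoms$charge <- assignCharges(xyz, element, b)
  methods::new("Receptor", atoms = atoms, subunitLabels = subunitLabels)
}

# Element from a PDB atom-name column: strip digits/primes, handle the
# two-letter halogens, first letter otherwise.
elementFromAtomName <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  out <- substr(nm, 1L, 1L)
  out[startsWith(nm, "CL")] <- "Cl"
  out[startsWith(nm, "BR")] <- "Br"
  out
}

normalizeElement <- function(el) {
  el <- paste0(toupper(substr(el, 1L, 1L)), tolower(substr(el, 2L, 10L)))
  el
}

#' Write a receptor to a PDB file
#'
#' @param receptor a \linkS4class{Receptor}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReceptor <- function(receptor, path) {
  a <- receptor@atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, ""),
    o = a$occ, b = rep(0, nrow(a)), elesy = toupper(a$element)
  )
  invisible(path)
}

# Extract one residue's atom rows (helper shared by mutation and SIFt code).
residueRows <- function(receptor, chain, reskey) {
  a <- receptor@atoms
  which(a$chain == chain & a$reskey == as.character(reskey))
}
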
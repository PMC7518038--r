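# Tabular I/O: congeneric compound/activity tables (CSV), scaffold maps
# (JSON), substituent libraries (SDF), and externally computed energies (CSV).

.canonical_labels <- c(
  h = "H", me = "Me", ome = "OMe", cl = "Cl", br = "Br", f = "F",
  tbu = "tBu", cch = "CCH", cn = "CN", cooet = "COOEt", nh2 = "NH2"
)

#' Normalize substituent labels
#'
#' Case-insensitive normalization to the canonical spelling (e.g. "Ome" and
#' "OME" both become "OMe"). Unknown labels are returned unchanged.
#' @param label character vector of labels.
#' @return normalized character vector.
#' @export
normalizeLabel <- function(label) {
  key <- tolower(trimws(label))
  out <- unname(.canonical_labels[key])
  unname(ifelse(is.na(out), trimws(label), out))
}

#' Load a congeneric compound/activity table
#'
#' Reads a CSV with columns \code{compound_id, name, R6, R7, R8, R3p, R4p,
#' pEC50_a1b3, pKi_a1g2} (the last may be blank). Substituent labels are
#' normalized; missing activities are stored as \code{NA}, never as zero.
#' Extra columns (e.g. precomputed delta columns) are carried through.
#'
#' @param path CSV file with a header row.
#' @return data.frame, one row per compound.
#' @export
loadCompoundTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(pKi_a1g2 = "character"))
  if (!nrow(tab)) stop("empty compound table: ", path)
  need <- c("compound_id", "name", "R6", "R7", "R8", "R3p", "R4p",
            "pEC50_a1b3", "pKi_a1g2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("compound table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(tab$compound_id[duplicated(tab$compound_id)]),
               collapse = ", "))
  }
  for (cc in c("R6", "R7", "R8", "R3p", "R4p")) {
    tab[[cc]] <- normalizeLabel(tab[[cc]])
  }
  tab$pKi_a1g2[tab$pKi_a1g2 %in% c("", "-", "−", "NA")] <- NA
  for (cc in c("pEC50_a1b3", "pKi_a1g2")) {
    val <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- is.na(val) & !is.na(tab[[cc]]) & nzchar(as.character(tab[[cc]]))
    if (any(bad)) {
      stop("non-numeric activity in column ", cc, ", row ", which(bad)[1L])
    }
    tab[[cc]] <- val
  }
  out <- is.finite(tab$pEC50_a1b3) &
    (tab$pEC50_a1b3 <= 3 | tab$pEC50_a1b3 >= 9)
  if (any(out)) {
    stop("pEC50 outside the plausible (3, 9) range for compound ",
         tab$compound_id[which(out)[1L]])
  }
  tab
}

#' The packaged pyrazoloquinolinone potency table
#'
#' Convenience accessor for the 19-compound PQ series with measured
#' pEC50 (alpha1/beta3 interface) and pKi (alpha1/gamma2 interface) values
#' shipped with the package.
#' @return data.frame with 19 rows.
#' @export
pqTable <- function() {
  loadCompoundTable(system.file("extdata", "pq_table1.csv",
                                package = "PoseSAR", mustWork = TRUE))
}

#' Read a scaffold map from JSON
#'
#' The on-disk format uses 0-based atom indices
#' (\code{{"core_atoms": [...], "attachments": [{"position": "R8",
#' "core_atom": i, "replaced_hydrogen": j}]}}); indices are converted to
#' 1-based on read.
#'
#' @param path JSON file.
#' @return a \linkS4class{ScaffoldMap}.
#' @export
readScaffoldMap <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  att <- as.data.frame(js$attachments)
  methods::new("ScaffoldMap",
               coreAtoms = as.integer(js$core_atoms) + 1L,
               attachments = data.frame(
                 position = att$position,
                 core_atom = as.integer(att$core_atom) + 1L,
                 replaced_hydrogen = as.integer(att$replaced_hydrogen) + 1L,
                 stringsAsFactors = FALSE))
}

#' Write a scaffold map to JSON (0-based indices on disk)
#'
#' @param map a \linkS4class{ScaffoldMap}; \code{path} output file.
#' @return \code{path}, invisibly.
#' @export
writeScaffoldMap <- function(map, path) {
  obj <- list(
    core_atoms = map@coreAtoms - 1L,
    attachments = data.frame(
      position = map@attachments$position,
      core_atom = map@attachments$core_atom - 1L,
      replaced_hydrogen = map@attachments$replaced_hydrogen - 1L
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a substituent fragment library from SDF
#'
#' Each record must carry \code{LABEL} and \code{LINK_ATOM} properties
#' (1-based link atom index; the link atom has the open valence). A minimal
#' V2000 reader is used here because fragment records can be single atoms
#' (a bare halogen), which some general-purpose SDF readers reject.
#'
#' @param path SDF file.
#' @return named list of \linkS4class{Substituent} objects.
#' @export
loadSubstituents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) stop("no records in substituent SDF ", path)
  out <- list()
  start <- 1L
  for (k in seq_along(ends)) {
    rec <- lines[start:(ends[k] - 1L)]
    start <- ends[k] + 1L
    counts <- rec[4L]
    na <- as.integer(substr(counts, 1L, 3L))
    nb <- as.integer(substr(counts, 4L, 6L))
    if (is.na(na) || na < 1L) stop("record ", k, ": bad counts line")
    atomLines <- rec[4L + seq_len(na)]
    xyz <- t(vapply(atomLines, function(l) {
      as.numeric(c(substr(l, 1L, 10L), substr(l, 11L, 20L),
                   substr(l, 21L, 30L)))
    }, numeric(3L)))
    element <- normalizeElement(trimws(substr(atomLines, 31L, 34L)))
    bonds <- if (nb > 0L) {
      bl <- rec[4L + na + seq_len(nb)]
      data.frame(i = as.integer(substr(bl, 1L, 3L)),
                 j = as.integer(substr(bl, 4L, 6L)),
                 order = as.integer(substr(bl, 7L, 9L)))
    } else data.frame(i = integer(), j = integer(), order = integer())
    prop <- function(name) {
      idx <- grep(paste0("^> *<", name, ">"), rec)
      if (!length(idx)) return(NA_character_)
      trimws(rec[idx[1L] + 1L])
    }
    label <- prop("LABEL")
    if (is.na(label)) stop("record ", k, " lacks LABEL property")
    label <- normalizeLabel(label)
    link <- as.integer(prop("LINK_ATOM"))
    if (is.na(link)) stop("record ", k, " lacks LINK_ATOM property")
    mol <- newMolecule(label, xyz, element, bonds)
    out[[label]] <- methods::new("Substituent", label = label, fragment = mol,
                                 linkAtom = link)
  }
  out
}

#' Import externally computed binding energies
#'
#' Bypass for the surrogate scorer: a CSV with columns \code{pose_id,
#' compound_id, dG_bind} (e.g. real MM-GBSA output) becomes the energy table
#' consumed by \code{\link{assessPoses}}.
#'
#' @param path CSV file.
#' @return data.frame with columns pose_id, compound_id, dG_bind.
#' @export
importScores <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pose_id", "compound_id", "dG_bind")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("score table lacks columns: ",
                         paste(miss, collapse = ", "))
  blank <- is.na(tab$dG_bind) | !nzchar(as.character(tab$dG_bind))
  if (any(blank)) stop("blank dG_bind in row ", which(blank)[1L])
  tab$dG_bind <- as.numeric(tab$dG_bind)
  key <- paste(tab$pose_id, tab$compound_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (pose_id, compound_id) key: ", gsub("\r", ", ", d))
  }
  tab[, need]
}

#' Export an energy table to CSV
#'
#' @param energies data.frame as produced by \code{\link{scorePoses}}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
exportScores <- function(energies, path) {
  utils::write.csv(energies, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
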